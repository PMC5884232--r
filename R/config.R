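# Pipeline configuration: every tunable of the pipeline, grouped by stage,
# with the documented defaults. Unknown keys are rejected so that a typo in a
# config file cannot silently fall back to a default.

#' Default pipeline configuration
#'
#' Returns the full nested list of tunables with their defaults. Pass
#' overrides as a nested list (e.g. from [read_config()]); unknown keys are
#' rejected, missing keys keep their defaults.
#'
#' @param overrides nested list merged over the defaults.
#' @return Nested configuration list of class `mtj_config`.
#' @export
mtj_config <- function(overrides = NULL) {
  cfg <- list(
    version = 1L,
    phase = list(
      # bank tuned to B-mode content: nothing below the speckle PSF scale
      # (~6 px at 0.11 mm/px), largest scale ~2x the 2.5 mm band FWHM
      n_scales = 5L,
      n_orientations = 6L,
      min_wavelength_px = 6,
      scale_multiplier = 2.1,
      sigma_on_f = 0.55,
      k_noise = 2,
      epsilon = 1e-4,
      cutoff = 0.5,
      gain = 10,
      taper_px = 16,
      orientation_range_deg = c(-10, 10)
    ),
    radon = list(
      delta_theta_deg = 0.5,
      delta_rho_px = 1,
      theta_range_deg = c(-10, 10)  # band direction from horizontal
    ),
    segmentation = list(
      t_d_mm = 2.5,
      removal_width_mm = 2,
      stop_fraction = 0.5,
      n_lines_max = 3L,
      max_dtheta_deg = 20,
      comparison = "keep_high",
      roi = NULL  # c(x_min, x_max, y_min, y_max); NULL = full frame
    ),
    tracking = list(
      presmooth_sigma = 1,
      subsample_step = 3L,
      mask_update_every = 1L,
      refine_passes = 1L,
      reference_frame = 0L,
      distal_axis = c(1, 0)
    )
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, path = "")
  structure(cfg, class = "mtj_config")
}

merge_config <- function(defaults, overrides, path) {
  if (!is.list(overrides)) stop("config overrides must be a named list")
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], full)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys of [mtj_config()].
#' @return Validated `mtj_config` with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  mtj_config(yaml::read_yaml(path))
}

#' Write a configuration to a YAML file
#' @param config an `mtj_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_digest <- function(config) {
  # short digest of the serialized config, for log lines
  txt <- yaml::as.yaml(unclass(config))
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %% 0xffffffff)
}
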