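# Sequence-level MTJ tracking: segmentation-masked affine Lucas-Kanade flow,
# point advection, line refit and intersection per frame pair.

#' Signed displacement series of an MTJ trajectory
#'
#' Projects the motion of the MTJ relative to its reference-frame position
#' onto the distal axis and converts to millimetres. Positive values mean the
#' MTJ moved distally (toward the tendon side of the image).
#'
#' @param positions n x 2 matrix of per-frame (x, y) MTJ pixel positions.
#' @param reference_frame 0-based index of the frame whose position defines
#'   zero displacement (the paper anchors it at the 0-degree ankle angle).
#' @param mm_per_pixel calibration.
#' @param distal_axis 2-vector pointing distally in image coordinates;
#'   normalized internally.
#' @return Numeric vector of signed displacements in mm; exactly 0 at the
#'   reference frame.
#' @export
displacement_series <- function(positions, reference_frame = 0L,
                                mm_per_pixel = 0.11, distal_axis = c(1, 0)) {
  positions <- matrix(as.numeric(positions), ncol = 2L)
  ref <- reference_frame + 1L
  if (ref < 1L || ref > nrow(positions)) {
    stop("reference_frame ", reference_frame, " outside the sequence")
  }
  axis <- distal_axis / sqrt(sum(distal_axis^2))
  drop(sweep(positions, 2L, positions[ref, ]) %*% axis) * mm_per_pixel
}

# Segment one frame: oriented phase map -> line detection -> Gamma_T ->
# Gamma_MTJ. Returns NULL invisibly for the mask when detection fails.
segment_frame <- function(frame, bank, config) {
  ph <- config$phase; sg <- config$segmentation; rd <- config$radon
  pm <- oriented_phase_symmetry(
    frame, bank,
    orientation_range = ph$orientation_range_deg,
    epsilon = ph$epsilon, k_noise = ph$k_noise,
    cutoff = ph$cutoff, gain = ph$gain, taper_px = ph$taper_px)
  lines <- detect_lines_revoting(
    pm, roi = sg$roi, band_theta_range = rd$theta_range_deg,
    n_lines_max = sg$n_lines_max, removal_width_mm = sg$removal_width_mm,
    mm_per_pixel = frame$mm_per_pixel, stop_fraction = sg$stop_fraction,
    delta_theta = rd$delta_theta_deg, delta_rho = rd$delta_rho_px,
    max_dtheta_deg = sg$max_dtheta_deg)
  list(phase_map = pm, lines = lines)
}

#' Segment the effective MTJ region of a single frame
#'
#' Runs the full segmentation stage (oriented phase congruency, localized
#' Radon line detection with revoting, distance banding, Otsu thresholding)
#' on one frame and returns all intermediate products.
#'
#' @param frame an [image_frame()].
#' @param config an [mtj_config()].
#' @param bank optional pre-built [build_loggabor_bank()] for the frame shape.
#' @return List with `phase_map`, `lines`, `gamma_t`, `gamma_mtj`.
#' @export
segment_mtj_region <- function(frame, config = mtj_config(), bank = NULL) {
  if (is.null(bank)) bank <- bank_from_config(dim(frame$pixels), config)
  seg <- segment_frame(frame, bank, config)
  if (length(seg$lines) == 0L) stop("no aponeurosis line detected in the frame")
  gamma_t <- tendinous_region(dim(frame$pixels), seg$lines,
                              t_d_mm = config$segmentation$t_d_mm,
                              mm_per_pixel = frame$mm_per_pixel)
  gamma_mtj <- effective_mtj_region(seg$phase_map, gamma_t,
                                    comparison = config$segmentation$comparison)
  c(seg, list(gamma_t = gamma_t, gamma_mtj = gamma_mtj))
}

bank_from_config <- function(shape, config) {
  ph <- config$phase
  build_loggabor_bank(shape, n_scales = ph$n_scales,
                      n_orientations = ph$n_orientations,
                      min_wavelength = ph$min_wavelength_px,
                      scale_multiplier = ph$scale_multiplier,
                      sigma_on_f = ph$sigma_on_f)
}

#' Track the MTJ through an image sequence
#'
#' For every consecutive frame pair: segments the effective MTJ region on the
#' earlier frame (every `tracking$mask_update_every` pairs), fits the global
#' affine flow over that region, advects the aponeurosis points, refits both
#' aponeurosis lines and takes their intersection as the MTJ. When the
#' intersection leaves the frame the position is still reported — the fitted
#' lines linearly extrapolate the aponeurosis paths — and `in_roi` is FALSE.
#'
#' With `unmasked = TRUE` the flow is fitted over the whole frame instead
#' (the traditional whole-region Lucas-Kanade baseline), skipping
#' segmentation entirely.
#'
#' @param frames list of [image_frame()]s (>= 2), identical shapes.
#' @param init_points a [tracked_points()] giving >= 2 seed points per
#'   aponeurosis on the first frame.
#' @param config an [mtj_config()].
#' @param unmasked fit the flow over the whole frame instead of the
#'   segmented MTJ region.
#' @param verbose emit per-stage log messages.
#' @return An `mtj_trajectory`: a data.frame with columns `frame`, `time_s`,
#'   `mtj_x_px`, `mtj_y_px`, `theta1_deg`, `rho1_px`, `theta2_deg`,
#'   `rho2_px`, `in_roi`, `displacement_mm`, plus attributes
#'   `mm_per_pixel`, `reference_frame`, `distal_axis`, `masked`.
#' @export
track_sequence <- function(frames, init_points, config = mtj_config(),
                           unmasked = FALSE, verbose = FALSE) {
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames")
  shape <- dim(frames[[1L]]$pixels)
  for (f in frames) {
    if (!all(dim(f$pixels) == shape)) stop("frames have mixed shapes")
  }
  center <- image_center(shape)
  tk <- config$tracking
  bank <- if (unmasked) NULL else bank_from_config(shape, config)

  points <- init_points
  mtj <- matrix(NA_real_, n, 2L)
  lines1 <- matrix(NA_real_, n, 2L)
  lines2 <- matrix(NA_real_, n, 2L)
  in_roi <- rep(NA, n)

  l_sup <- fit_aponeurosis_line(points$superficial, center)
  l_deep <- fit_aponeurosis_line(points$deep, center)
  mtj[1L, ] <- intersect_lines(l_sup, l_deep, center)
  lines1[1L, ] <- c(l_sup$theta_deg, l_sup$rho_px)
  lines2[1L, ] <- c(l_deep$theta_deg, l_deep$rho_px)
  in_roi[1L] <- point_in_frame(mtj[1L, ], shape)

  mask <- NULL
  n_done <- n
  for (t in 2:n) {
    if (!unmasked) {
      recompute <- is.null(mask) || ((t - 2L) %% tk$mask_update_every == 0L)
      if (recompute) {
        seg <- try(segment_mtj_region(frames[[t - 1L]], config, bank), silent = TRUE)
        if (inherits(seg, "try-error")) {
          warning("segmentation failed on frame ", t - 2L,
                  "; keeping the previous mask")
        } else {
          mask <- seg$gamma_mtj
        }
        if (is.null(mask)) stop("segmentation failed on the first frame pair")
      }
    }
    grad <- spatiotemporal_gradients(frames[[t - 1L]], frames[[t]],
                                     presmooth_sigma = tk$presmooth_sigma)
    flow <- try(fit_affine_flow(grad, mask, tk$subsample_step), silent = TRUE)
    if (inherits(flow, "try-error")) {
      warning("affine fit failed between frames ", t - 2L, " and ", t - 1L,
              "; trajectory truncated at frame ", t - 2L)
      n_done <- t - 1L
      break
    }
    for (pass in seq_len(tk$refine_passes)) {
      flow <- refine_flow(frames[[t - 1L]], frames[[t]], flow, mask,
                          center, tk)
    }
    points <- advect_points(points, flow, center)
    l_sup <- fit_aponeurosis_line(points$superficial, center)
    l_deep <- fit_aponeurosis_line(points$deep, center)
    xy <- try(intersect_lines(l_sup, l_deep, center), silent = TRUE)
    if (inherits(xy, "try-error")) {
      warning("aponeuroses (near-)parallel at frame ", t - 1L,
              "; carrying the previous MTJ position forward")
      mtj[t, ] <- mtj[t - 1L, ]
      lines1[t, ] <- lines1[t - 1L, ]
      lines2[t, ] <- lines2[t - 1L, ]
    } else {
      mtj[t, ] <- xy
      lines1[t, ] <- c(l_sup$theta_deg, l_sup$rho_px)
      lines2[t, ] <- c(l_deep$theta_deg, l_deep$rho_px)
    }
    in_roi[t] <- point_in_frame(mtj[t, ], shape)
    if (verbose && (t %% 50L == 0L)) {
      message("tracked frame ", t - 1L, "/", n - 1L)
    }
  }

  keep <- seq_len(n_done)
  disp <- displacement_series(mtj[keep, , drop = FALSE],
                              reference_frame = tk$reference_frame,
                              mm_per_pixel = frames[[1L]]$mm_per_pixel,
                              distal_axis = tk$distal_axis)
  out <- data.frame(
    frame = keep - 1L,
    time_s = vapply(frames[keep], function(f) f$timestamp_s, numeric(1L)),
    mtj_x_px = mtj[keep, 1L],
    mtj_y_px = mtj[keep, 2L],
    theta1_deg = lines1[keep, 1L],
    rho1_px = lines1[keep, 2L],
    theta2_deg = lines2[keep, 1L],
    rho2_px = lines2[keep, 2L],
    in_roi = in_roi[keep],
    displacement_mm = disp
  )
  structure(out,
            mm_per_pixel = frames[[1L]]$mm_per_pixel,
            reference_frame = tk$reference_frame,
            distal_axis = tk$distal_axis,
            masked = !unmasked,
            class = c("mtj_trajectory", "data.frame"))
}

point_in_frame <- function(xy, shape) {
  is.finite(xy[1L]) && is.finite(xy[2L]) &&
    xy[1L] >= 0 && xy[1L] <= shape[2L] - 1L &&
    xy[2L] >= 0 && xy[2L] <= shape[1L] - 1L
}

# One warp-and-refit pass: resample the later frame back through the fitted
# flow and add the residual flow estimate. The linearized single-step fit
# carries a velocity-dependent multiplicative bias that accumulates over long
# sequences; one refinement pass removes it (set tracking$refine_passes = 0
# for the plain single-step fit).
refine_flow <- function(frame_t, frame_t1, flow, mask, center, tk) {
  px1 <- frame_pixels(frame_t1)
  g <- center_grid(dim(px1))
  v <- flow_velocity(flow, cbind(as.vector(g$x), as.vector(g$y)))
  warped <- bilinear_sample(px1,
                            as.vector(g$x) + center[1L] + v[, 1L],
                            as.vector(g$y) + center[2L] + v[, 2L])
  warped <- matrix(warped, nrow(px1), ncol(px1))
  grad <- spatiotemporal_gradients(frame_pixels(frame_t), warped,
                                   presmooth_sigma = tk$presmooth_sigma)
  resid <- try(fit_affine_flow(grad, mask, tk$subsample_step), silent = TRUE)
  if (inherits(resid, "try-error")) return(flow)
  affine_flow(flow$vxt + resid$vxt, flow$vyt + resid$vyt,
              flow$d + resid$d, flow$r + resid$r,
              flow$s1 + resid$s1, flow$s2 + resid$s2)
}

#' @export
print.mtj_trajectory <- function(x, ...) {
  masked <- attr(x, "masked")
  flow_lbl <- if (is.null(masked)) "" else if (masked) ", masked flow" else ", unmasked flow"
  cat(sprintf("<mtj_trajectory: %d frames%s, displacement %.2f .. %.2f mm>\n",
              nrow(x), flow_lbl,
              min(x$displacement_mm), max(x$displacement_mm)))
  NextMethod()
}
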