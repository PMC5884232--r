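# Sequence readers/writers and trajectory/mask/line export.

to_gray <- function(arr, what = "frame") {
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      warning("RGB ", what, " reduced to grayscale by luma conversion")
      return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
    }
    return(arr[, , 1L])
  }
  arr
}

#' Read an ultrasound image sequence
#'
#' Reads either a multi-page TIFF stack (pages in file order) or a directory
#' of single-frame PNG/TIFF images (lexicographic filename order). Pixel
#' values are normalized to floating point \[0, 1\] regardless of bit depth;
#' RGB frames are reduced by luma conversion with a warning.
#'
#' @param path a TIFF file or a directory of frames.
#' @param mm_per_pixel,fps calibration attached to every frame.
#' @return List of [image_frame()]s in order.
#' @export
read_sequence <- function(path, mm_per_pixel = 0.11, fps = 40) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("no PNG or TIFF frames found in directory: ", path,
           " (BMP is not supported)")
    }
    mats <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      to_gray(img, basename(f))
    })
  } else {
    if (!file.exists(path)) stop("unreadable input: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, to_gray)
  }
  shapes <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1L))
  if (length(unique(shapes)) != 1L) {
    stop("frames have mixed shapes: ", paste(unique(shapes), collapse = ", "))
  }
  lapply(seq_along(mats), function(i) {
    image_frame(mats[[i]], mm_per_pixel, i - 1L, fps)
  })
}

#' Write a sequence as a multi-page TIFF
#'
#' @param frames list of [image_frame()]s (or matrices) with values in
#'   \[0, 1\].
#' @param path output .tif path.
#' @param bits_per_sample 8, 16 or 32 (32 stores IEEE float).
#' @export
write_sequence <- function(frames, path, bits_per_sample = 16L) {
  mats <- lapply(frames, function(f) {
    m <- frame_pixels(f)
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(mats, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Export a phase map as 32-bit float TIFF
#' @param phase_map a `phase_map`.
#' @param path output .tif path.
#' @export
write_phase_map <- function(phase_map, path) {
  tiff::writeTIFF(phase_map$values, path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a region mask as 8-bit PNG (0/255)
#' @param mask a `region_mask` or logical matrix.
#' @param path output .png path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Export detected lines as CSV
#' @param lines list of [detected_line()].
#' @param path output .csv path.
#' @export
write_lines_csv <- function(lines, path) {
  df <- data.frame(
    theta_deg = vapply(lines, function(l) l$theta_deg, numeric(1L)),
    rho_px = vapply(lines, function(l) l$rho_px, numeric(1L)),
    strength = vapply(lines, function(l) l$strength, numeric(1L)),
    rank = vapply(lines, function(l) as.integer(l$rank), integer(1L))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an MTJ trajectory to CSV
#'
#' Columns: frame, time_s, mtj_x_px, mtj_y_px, theta1_deg, rho1_px,
#' theta2_deg, rho2_px, in_roi, displacement_mm; floats are written with 6
#' significant digits.
#'
#' @param trajectory an `mtj_trajectory` from [track_sequence()].
#' @param path output .csv path.
#' @export
write_trajectory <- function(trajectory, path) {
  if (nrow(trajectory) < 1L) stop("empty trajectory")
  df <- as.data.frame(trajectory)
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "frame"
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#' @param path .csv path.
#' @return data.frame with the trajectory column contract.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("unreadable trajectory file: ", path)
  utils::read.csv(path)
}

#' Read first-frame aponeurosis seed points
#'
#' CSV with columns `aponeurosis` (superficial/deep), `x_px`, `y_px`, at
#' least two points per aponeurosis.
#'
#' @param path .csv path.
#' @return A [tracked_points()].
#' @export
read_init_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("aponeurosis", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("init file must have columns: ", paste(need, collapse = ", "))
  }
  sup <- df[df$aponeurosis == "superficial", c("x_px", "y_px")]
  deep <- df[df$aponeurosis == "deep", c("x_px", "y_px")]
  tracked_points(as.matrix(sup), as.matrix(deep), provenance = "manual_init")
}

#' Write phantom ground truth to CSV
#' @param truth a `phantom_truth`.
#' @param path output .csv path.
#' @export
write_truth_csv <- function(truth, path) {
  df <- data.frame(
    frame = seq_len(nrow(truth$mtj_xy_true)) - 1L,
    mtj_x_true = truth$mtj_xy_true[, 1L],
    mtj_y_true = truth$mtj_xy_true[, 2L],
    theta1 = truth$line1[, 1L], rho1 = truth$line1[, 2L],
    theta2 = truth$line2[, 1L], rho2 = truth$line2[, 2L]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
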