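#' Construct an ultrasound image frame
#'
#' Wraps a grayscale pixel matrix together with its physical calibration and
#' temporal position in the sequence. Pixels are stored as a numeric matrix
#' with rows running down the image (y) and columns running right (x);
#' geometry throughout the package uses 0-based pixel indices with
#' x = column and y = row.
#'
#' @param pixels numeric matrix of non-negative, finite intensities;
#'   at least 16 rows and 16 columns (the log-Gabor bank needs a
#'   non-trivial spectrum).
#' @param mm_per_pixel physical pixel size in millimetres (isotropic).
#' @param frame_index 0-based index of the frame within its sequence.
#' @param fps acquisition frame rate, frames per second; used only to derive
#'   the timestamp.
#' @return An object of class `image_frame` with fields `pixels`,
#'   `mm_per_pixel`, `frame_index` and `timestamp_s`.
#' @export
image_frame <- function(pixels, mm_per_pixel = 0.11, frame_index = 0L, fps = 40) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("frame must be at least 16 x 16 pixels (got ",
         nrow(pixels), " x ", ncol(pixels), ")")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("frame intensities must be finite and non-negative")
  }
  if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a positive number")
  }
  structure(
    list(
      pixels = pixels,
      mm_per_pixel = mm_per_pixel,
      frame_index = as.integer(frame_index),
      timestamp_s = as.integer(frame_index) / fps,
      fps = fps
    ),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %d x %d px, %.4g mm/px, frame %d (t = %.3f s)>\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
              x$frame_index, x$timestamp_s))
  invisible(x)
}

# Accept either an image_frame or a bare matrix wherever only pixels matter.
frame_pixels <- function(x) {
  if (inherits(x, "image_frame")) x$pixels else as.matrix(x)
}

# Center-relative coordinate grids for a (rows, cols) shape.
# x = column - (cols-1)/2, y = row - (rows-1)/2 (0-based indices).
center_grid <- function(shape) {
  rows <- shape[1L]; cols <- shape[2L]
  cx <- (cols - 1) / 2
  cy <- (rows - 1) / 2
  list(
    x = matrix(rep(seq_len(cols) - 1 - cx, each = rows), rows, cols),
    y = matrix(rep(seq_len(rows) - 1 - cy, times = cols), rows, cols),
    cx = cx, cy = cy
  )
}

# Image center in 0-based pixel coordinates (x, y).
image_center <- function(shape) {
  c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2)
}
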