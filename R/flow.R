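# Global affine Lucas-Kanade optical flow over a masked region.
#
# The velocity field is affine in position:
#   Vx = x*(d + s1) + y*(s2 - r) + vxt
#   Vy = x*(s2 + r) + y*(d - s1) + vyt
# with translation (vxt, vyt), dilation rate d, rotation rate r and the two
# shear rates s1, s2; coordinates are centre-relative pixels. The six
# parameters are fitted by least squares from the brightness-constancy
# constraint ix*Vx + iy*Vy + it = 0 over the selected pixels.

# Separable Gaussian smoothing with edge replication. `sigma` may be a
# length-2 vector (row/y direction, column/x direction) for anisotropic
# smoothing; a zero disables that axis.
gaussian_smooth <- function(mat, sigma) {
  if (is.null(sigma)) return(mat)
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  smooth_cols <- function(m, s) {
    if (s <= 0) return(m)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(r + 1L):(r + nrow(m)), ], nrow(m), ncol(m))
  }
  t(smooth_cols(t(smooth_cols(mat, sigma[1L])), sigma[2L]))
}

#' Spatiotemporal image gradients of a frame pair
#'
#' Optionally Gaussian-presmooths both frames, then forms the spatial
#' derivatives by central differences on the mean of the two smoothed frames
#' and the temporal derivative as their difference. The 1-pixel border, where
#' central differences are undefined, is excluded from `valid_mask`.
#'
#' @param frame_t,frame_t1 consecutive [image_frame()]s (or matrices) of
#'   identical shape.
#' @param presmooth_sigma Gaussian sigma in pixels (default 1; 0 disables).
#' @return Object of class `gradient_field` with `ix`, `iy`, `it`,
#'   `valid_mask`.
#' @export
spatiotemporal_gradients <- function(frame_t, frame_t1, presmooth_sigma = 1) {
  a <- frame_pixels(frame_t)
  b <- frame_pixels(frame_t1)
  if (!all(dim(a) == dim(b))) stop("frame shapes differ")
  a <- gaussian_smooth(a, presmooth_sigma)
  b <- gaussian_smooth(b, presmooth_sigma)
  m <- (a + b) / 2
  rows <- nrow(m); cols <- ncol(m)
  ix <- matrix(0, rows, cols)
  iy <- matrix(0, rows, cols)
  ix[, 2:(cols - 1L)] <- (m[, 3:cols] - m[, 1:(cols - 2L)]) / 2
  iy[2:(rows - 1L), ] <- (m[3:rows, ] - m[1:(rows - 2L), ]) / 2
  valid <- matrix(FALSE, rows, cols)
  valid[2:(rows - 1L), 2:(cols - 1L)] <- TRUE
  structure(list(ix = ix, iy = iy, it = b - a, valid_mask = valid),
            class = "gradient_field")
}

#' Construct affine flow parameters
#' @param vxt,vyt translation at the origin (px/frame).
#' @param d,r,s1,s2 dilation, rotation and shear rates (per frame).
#' @return Object of class `affine_flow`.
#' @export
affine_flow <- function(vxt = 0, vyt = 0, d = 0, r = 0, s1 = 0, s2 = 0) {
  p <- c(vxt = unname(vxt), vyt = unname(vyt), d = unname(d),
         r = unname(r), s1 = unname(s1), s2 = unname(s2))
  if (!all(is.finite(p))) stop("affine flow parameters must be finite")
  structure(as.list(p), class = "affine_flow")
}

#' @export
print.affine_flow <- function(x, ...) {
  cat(sprintf(
    "<affine_flow vxt = %.4g, vyt = %.4g, d = %.4g, r = %.4g, s1 = %.4g, s2 = %.4g>\n",
    x$vxt, x$vyt, x$d, x$r, x$s1, x$s2))
  invisible(x)
}

#' Evaluate the affine velocity field at points
#'
#' @param flow an [affine_flow()].
#' @param xy n x 2 matrix of centre-relative (x, y) positions.
#' @return n x 2 matrix of (Vx, Vy).
#' @export
flow_velocity <- function(flow, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  x <- xy[, 1L]; y <- xy[, 2L]
  cbind(x * (flow$d + flow$s1) + y * (flow$s2 - flow$r) + flow$vxt,
        x * (flow$s2 + flow$r) + y * (flow$d - flow$s1) + flow$vyt)
}

#' Least-squares fit of the global affine flow over a region
#'
#' Builds one brightness-constancy equation per selected pixel and solves the
#' overdetermined 6-parameter system by QR least squares. Pixels are those of
#' `mask` that carry valid gradients, subsampled on a regular grid every
#' `subsample_step` pixels in both axes to cut the cost of the fit. For
#' conditioning, the fit is performed in coordinates relative to the centroid
#' of the selected pixels and the parameters are then re-expressed at the
#' image centre, which is the origin used throughout the package.
#'
#' @param grad a [spatiotemporal_gradients()] result.
#' @param mask a `region_mask`, logical matrix, or NULL for the whole frame.
#' @param subsample_step grid step in pixels (default 3).
#' @return An [affine_flow()].
#' @export
fit_affine_flow <- function(grad, mask = NULL, subsample_step = 3L) {
  shape <- dim(grad$ix)
  m <- if (is.null(mask)) {
    matrix(TRUE, shape[1L], shape[2L])
  } else if (inherits(mask, "region_mask")) mask$mask else mask
  if (!all(dim(m) == shape)) stop("mask shape does not match gradients")
  step <- max(1L, as.integer(subsample_step))
  gridsel <- matrix(FALSE, shape[1L], shape[2L])
  gridsel[seq(1L, shape[1L], by = step), seq(1L, shape[2L], by = step)] <- TRUE
  sel <- which(m & grad$valid_mask & gridsel)
  if (length(sel) < 6L) {
    stop("too few pixels in the masked region (", length(sel),
         ") to fit 6 affine parameters")
  }
  g <- center_grid(shape)
  x <- g$x[sel]; y <- g$y[sel]
  ix <- grad$ix[sel]; iy <- grad$iy[sel]; it <- grad$it[sel]
  xm <- mean(x); ym <- mean(y)
  xc <- x - xm; yc <- y - ym
  a <- cbind(ix, iy,
             ix * xc + iy * yc,   # d
             -ix * yc + iy * xc,  # r
             ix * xc - iy * yc,   # s1
             ix * yc + iy * xc)   # s2
  qra <- qr(a)
  if (qra$rank < 6L) {
    stop("degenerate texture: affine flow system is rank-deficient (rank ",
         qra$rank, ")")
  }
  beta <- qr.coef(qra, -it)
  vxt <- beta[1L] - xm * (beta[3L] + beta[5L]) - ym * (beta[6L] - beta[4L])
  vyt <- beta[2L] - xm * (beta[6L] + beta[4L]) - ym * (beta[3L] - beta[5L])
  affine_flow(vxt, vyt, beta[3L], beta[4L], beta[5L], beta[6L])
}

#' Tracked aponeurosis points
#'
#' @param superficial,deep n x 2 matrices of (x, y) pixel positions (n >= 2).
#' @param provenance "manual_init" or "advected".
#' @return Object of class `tracked_points`.
#' @export
tracked_points <- function(superficial, deep, provenance = "manual_init") {
  superficial <- matrix(as.numeric(superficial), ncol = 2L)
  deep <- matrix(as.numeric(deep), ncol = 2L)
  if (nrow(superficial) < 2L || nrow(deep) < 2L) {
    stop("need at least 2 points per aponeurosis")
  }
  structure(list(superficial = superficial, deep = deep,
                 provenance = provenance),
            class = "tracked_points")
}

#' Advect tracked points by an affine flow
#'
#' Each point p moves to p + V(p), with the velocity evaluated at the point's
#' centre-relative position.
#'
#' @param points a [tracked_points()] in pixel coordinates.
#' @param flow an [affine_flow()].
#' @param center (x, y) origin of the flow field (the image centre).
#' @return Advected `tracked_points` with provenance "advected".
#' @export
advect_points <- function(points, flow, center = c(0, 0)) {
  move <- function(xy) {
    rel <- sweep(xy, 2L, center)
    xy + flow_velocity(flow, rel)
  }
  tracked_points(move(points$superficial), move(points$deep),
                 provenance = "advected")
}

#' Total-least-squares line through points
#'
#' Fits the normal-form line minimizing the orthogonal residuals (principal
#' axis of the point scatter); the RMS residual is reported in the strength
#' field.
#'
#' @param points n x 2 matrix of (x, y) pixel positions, n >= 2, not all
#'   coincident.
#' @param center (x, y) origin for the (theta, rho) parameterization.
#' @return A [detected_line()].
#' @export
fit_aponeurosis_line <- function(points, center = c(0, 0)) {
  xy <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(xy) < 2L) stop("need at least 2 points")
  rel <- sweep(xy, 2L, center)
  mu <- colMeans(rel)
  cen <- sweep(rel, 2L, mu)
  cv <- crossprod(cen) / nrow(cen)
  if (sum(diag(cv)) < 1e-24) stop("points are coincident; line undefined")
  ev <- eigen(cv, symmetric = TRUE)
  normal <- ev$vectors[, 2L]  # eigenvector of the smaller eigenvalue
  theta <- atan2(normal[2L], normal[1L]) * 180 / pi
  rho <- sum(normal * mu)
  rms <- sqrt(mean((cen %*% normal)^2))
  detected_line(theta, rho, strength = rms)
}
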