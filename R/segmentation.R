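# Aponeurosis detection and effective MTJ region segmentation.
#
# Lines are parameterized in normal form: theta_deg is the angle of the line
# normal from the x-axis (counter-clockwise, y down the rows), rho_px the
# signed distance from the image centre, so points (x, y) on the line satisfy
# x*cos(theta) + y*sin(theta) = rho in centre-relative coordinates.

#' Construct a detected line
#'
#' @param theta_deg normal angle in degrees; normalized into \[-90, 90) with
#'   rho negated when needed.
#' @param rho_px signed distance from the image centre in pixels.
#' @param strength accumulator value at the Radon peak (or RMS residual for
#'   lines fitted from points).
#' @param rank 1-based extraction order.
#' @return Object of class `detected_line`.
#' @export
detected_line <- function(theta_deg, rho_px, strength = NA_real_, rank = NA_integer_) {
  theta <- ((theta_deg + 90) %% 180) - 90
  if (abs(theta - theta_deg) > 1e-9) {
    # crossing the branch flips the normal, so the signed distance flips too
    flips <- round((theta_deg - theta) / 180)
    if (flips %% 2 != 0) rho_px <- -rho_px
  }
  structure(list(theta_deg = theta, rho_px = rho_px,
                 strength = strength, rank = as.integer(rank)),
            class = "detected_line")
}

#' @export
print.detected_line <- function(x, ...) {
  cat(sprintf("<line theta = %.2f deg, rho = %.2f px, strength = %.4g, rank = %s>\n",
              x$theta_deg, x$rho_px, x$strength,
              ifelse(is.na(x$rank), "-", x$rank)))
  invisible(x)
}

#' Perpendicular distance from a point to a line
#'
#' @param line a [detected_line()].
#' @param point numeric (x, y), centre-relative pixels by default.
#' @param center optional (x, y) origin to subtract first, for points given
#'   in absolute pixel indices.
#' @return Distance in pixels (non-negative).
#' @export
line_point_distance <- function(line, point, center = c(0, 0)) {
  th <- line$theta_deg * pi / 180
  abs((point[1L] - center[1L]) * cos(th) +
      (point[2L] - center[2L]) * sin(th) - line$rho_px)
}

#' Intersection of two lines in normal form
#'
#' Solves the 2x2 linear system of the two line equations. The intersection
#' may lie outside the frame; this is how the MTJ position is linearly
#' extrapolated once it leaves the field of view.
#'
#' @param a,b [detected_line()] objects.
#' @param center (x, y) added to the centre-relative solution, so passing the
#'   image centre yields 0-based pixel coordinates.
#' @param angle_tol_deg minimum angular separation (modulo 180) below which
#'   the lines are treated as parallel.
#' @return Numeric (x, y).
#' @export
intersect_lines <- function(a, b, center = c(0, 0), angle_tol_deg = 0.5) {
  dth <- abs(((a$theta_deg - b$theta_deg) + 90) %% 180 - 90)
  if (dth < angle_tol_deg) {
    stop("lines are (near-)parallel: |delta theta| = ",
         format(dth, digits = 3), " deg < ", angle_tol_deg, " deg")
  }
  ta <- a$theta_deg * pi / 180
  tb <- b$theta_deg * pi / 180
  m <- matrix(c(cos(ta), cos(tb), sin(ta), sin(tb)), 2L, 2L)
  xy <- solve(m, c(a$rho_px, b$rho_px))
  c(xy[1L] + center[1L], xy[2L] + center[2L])
}

check_roi <- function(roi, shape) {
  if (is.null(roi)) roi <- c(0, shape[2L] - 1L, 0, shape[1L] - 1L)
  roi <- as.numeric(roi)
  if (length(roi) != 4L || roi[1L] > roi[2L] || roi[3L] > roi[4L] ||
      roi[1L] < 0 || roi[3L] < 0 ||
      roi[2L] > shape[2L] - 1L || roi[4L] > shape[1L] - 1L) {
    stop("roi must be c(x_min, x_max, y_min, y_max) inside the frame")
  }
  roi
}

#' Localized Radon transform of a phase map
#'
#' Votes every ROI pixel's phase value into the (theta, rho) accumulator
#' along `rho = x cos(theta) + y sin(theta)` (centre-relative coordinates),
#' splitting each vote linearly between the two nearest rho bins. Only angles
#' inside `theta_range` are accumulated, which is what localizes the
#' transform to the near-horizontal band orientations of tendinous tissue.
#'
#' @param phase_map a `phase_map` or plain numeric matrix of vote weights.
#' @param roi c(x_min, x_max, y_min, y_max) in 0-based pixels; default the
#'   full frame.
#' @param theta_range c(min, max) NORMAL angles in degrees.
#' @param delta_theta,delta_rho bin widths in degrees and pixels.
#' @return Object of class `radon_accumulator` with fields `votes` (theta
#'   bins x rho bins), `theta_deg`, `rho_px`, `roi`.
#' @export
localized_radon <- function(phase_map, roi = NULL, theta_range = c(80, 100),
                            delta_theta = 0.5, delta_rho = 1) {
  w <- if (inherits(phase_map, "phase_map")) phase_map$values else as.matrix(phase_map)
  shape <- dim(w)
  roi <- check_roi(roi, shape)
  if (theta_range[1L] >= theta_range[2L]) stop("theta_range must have min < max")
  thetas <- seq(theta_range[1L], theta_range[2L], by = delta_theta)
  if (length(thetas) < 1L) stop("empty theta grid")

  g <- center_grid(shape)
  rowsel <- (roi[3L] + 1L):(roi[4L] + 1L)
  colsel <- (roi[1L] + 1L):(roi[2L] + 1L)
  wv <- as.vector(w[rowsel, colsel])
  xs <- as.vector(g$x[rowsel, colsel])
  ys <- as.vector(g$y[rowsel, colsel])
  keep <- wv > 0
  wv <- wv[keep]; xs <- xs[keep]; ys <- ys[keep]

  # rho range: farthest ROI corner from the image centre
  cx <- c(roi[1L], roi[2L]) - g$cx
  cy <- c(roi[3L], roi[4L]) - g$cy
  rmax <- sqrt(max(cx^2) + max(cy^2))
  n_rho <- 2L * ceiling(rmax / delta_rho) + 3L
  rho0 <- -((n_rho - 1L) / 2) * delta_rho
  rhos <- rho0 + (seq_len(n_rho) - 1L) * delta_rho

  votes <- matrix(0, length(thetas), n_rho)
  if (length(wv) > 0L) {
    for (it in seq_along(thetas)) {
      th <- thetas[it] * pi / 180
      t <- (xs * cos(th) + ys * sin(th) - rho0) / delta_rho
      i0 <- floor(t)
      fr <- t - i0
      i0 <- as.integer(i0) + 1L
      acc <- numeric(n_rho + 1L)
      s1 <- rowsum(wv * (1 - fr), i0)
      acc[as.integer(rownames(s1))] <- acc[as.integer(rownames(s1))] + s1[, 1L]
      s2 <- rowsum(wv * fr, i0 + 1L)
      acc[as.integer(rownames(s2))] <- acc[as.integer(rownames(s2))] + s2[, 1L]
      votes[it, ] <- acc[seq_len(n_rho)]
    }
  }
  structure(list(votes = votes, theta_deg = thetas, rho_px = rhos,
                 roi = roi, delta_theta = delta_theta, delta_rho = delta_rho),
            class = "radon_accumulator")
}

#' Detect aponeurosis lines by Radon peak extraction with revoting
#'
#' Repeatedly takes the strongest accumulator peak as the next line, then
#' removes the phase-map contribution of every pixel within
#' `removal_width_mm` of that line before voting again, so a thick band
#' cannot spawn several near-duplicate lines. After the first line, the
#' (theta, rho) search is restricted to an angular window around it — the
#' second aponeurosis is known to run within a few degrees of the first.
#'
#' @param phase_map `phase_map` or matrix of vote weights.
#' @param roi ROI rectangle as in [localized_radon()].
#' @param band_theta_range c(lo, hi) BAND directions in degrees from
#'   horizontal; converted internally to normal angles (normal = band + 90).
#' @param n_lines_max maximum number of lines to extract.
#' @param removal_width_mm pixels within this distance of an accepted line
#'   stop voting in later iterations.
#' @param mm_per_pixel calibration used to convert the removal width.
#' @param stop_fraction extraction stops when a peak drops below this
#'   fraction of the first peak.
#' @param delta_theta,delta_rho accumulator bin widths.
#' @param max_dtheta_deg half-width of the angular search window around the
#'   first line for subsequent lines.
#' @return List of [detected_line()] in extraction order (possibly empty).
#' @export
detect_lines_revoting <- function(phase_map, roi = NULL,
                                  band_theta_range = c(-10, 10),
                                  n_lines_max = 3L, removal_width_mm = 2,
                                  mm_per_pixel = 0.11, stop_fraction = 0.5,
                                  delta_theta = 0.5, delta_rho = 1,
                                  max_dtheta_deg = 20) {
  if (n_lines_max < 1L) stop("n_lines_max must be >= 1")
  w <- if (inherits(phase_map, "phase_map")) phase_map$values else as.matrix(phase_map)
  shape <- dim(w)
  theta_range <- band_theta_range + 90
  removal_px <- removal_width_mm / mm_per_pixel
  g <- center_grid(shape)

  lines <- list()
  first_strength <- NA_real_
  for (iter in seq_len(n_lines_max)) {
    acc <- localized_radon(w, roi, theta_range, delta_theta, delta_rho)
    votes <- acc$votes
    unconstrained_max <- max(votes)
    if (length(lines) > 0L) {
      ok <- abs(acc$theta_deg - (lines[[1L]]$theta_deg %% 180)) <= max_dtheta_deg
      votes[!ok, ] <- -Inf
    }
    peak <- which(votes == max(votes), arr.ind = TRUE)[1L, ]
    strength <- votes[peak[1L], peak[2L]]
    if (!is.finite(strength) || strength <= 0) {
      if (length(lines) > 0L && unconstrained_max > 0 &&
          unconstrained_max >= stop_fraction * first_strength) {
        warning("no peak inside the constrained search window; returning ",
                length(lines), " line(s)")
      }
      break
    }
    if (is.na(first_strength)) {
      first_strength <- strength
    } else if (strength < stop_fraction * first_strength) {
      break
    }
    ln <- detected_line(acc$theta_deg[peak[1L]], acc$rho_px[peak[2L]],
                        strength = strength, rank = length(lines) + 1L)
    lines[[length(lines) + 1L]] <- ln
    # revoting: silence all pixels near the accepted line
    th <- ln$theta_deg * pi / 180
    d <- abs(g$x * cos(th) + g$y * sin(th) - ln$rho_px)
    w[d <= removal_px] <- 0
  }
  lines
}

#' Tendinous region mask from detected lines
#'
#' Marks every pixel whose distance to the nearest detected line is at most
#' `t_d_mm` (2.5 mm by default — the reported average diameter of the
#' gastrocnemius tendon and aponeuroses), forming the union of fixed-width
#' bands around the aponeuroses.
#'
#' @param frame_shape integer (rows, cols).
#' @param lines non-empty list of [detected_line()].
#' @param t_d_mm distance threshold in millimetres.
#' @param mm_per_pixel calibration.
#' @return Object of class `region_mask` with kind "tendinous".
#' @export
tendinous_region <- function(frame_shape, lines, t_d_mm = 2.5, mm_per_pixel = 0.11) {
  if (length(lines) < 1L) stop("need at least one detected line")
  g <- center_grid(frame_shape)
  t_px <- t_d_mm / mm_per_pixel
  dmin <- NULL
  for (ln in lines) {
    th <- ln$theta_deg * pi / 180
    d <- abs(g$x * cos(th) + g$y * sin(th) - ln$rho_px)
    dmin <- if (is.null(dmin)) d else pmin(dmin, d)
  }
  structure(list(mask = dmin <= t_px, kind = "tendinous",
                 source_lines = lines, t_d_mm = t_d_mm, t_otsu = NA_real_),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %s, %d x %d px, %d (%.1f%%) pixels set>\n",
              x$kind, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Otsu threshold of a value collection
#'
#' Builds a 256-bin histogram over \[0, 1\] and returns the bin boundary that
#' maximizes the between-class variance, i.e. the classic Otsu criterion.
#'
#' @param values numeric vector with values in \[0, 1\]; at least two
#'   distinct values.
#' @param n_bins number of histogram bins.
#' @return Threshold level in (0, 1); values <= threshold form the low class.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) {
    stop("degenerate input: need at least 2 distinct values for Otsu thresholding")
  }
  values <- pmin(pmax(values, 0), 1)
  idx <- pmin(floor(values * n_bins), n_bins - 1L) + 1L
  h <- tabulate(idx, nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for split after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  w0 <- omega[k]
  num <- (mu_t * w0 - mu[k])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  k_star <- which.max(sigma_b)
  k_star / n_bins
}

#' Effective MTJ region
#'
#' Thresholds the phase map restricted to the tendinous region with the Otsu
#' level and keeps the configured side, yielding the region over which the
#' affine optical flow is fitted. `keep_high` retains the high-symmetry
#' (visible tendinous structure) pixels and is the default; `keep_low` keeps
#' the opposite side.
#'
#' @param phase_map the oriented `phase_map` used for segmentation.
#' @param gamma_t a tendinous [tendinous_region()] mask of matching shape.
#' @param comparison `"keep_high"` or `"keep_low"`.
#' @return A `region_mask` of kind "mtj", guaranteed to be a subset of
#'   `gamma_t`; `t_otsu` records the threshold used.
#' @export
effective_mtj_region <- function(phase_map, gamma_t,
                                 comparison = c("keep_high", "keep_low")) {
  comparison <- match.arg(comparison)
  v <- if (inherits(phase_map, "phase_map")) phase_map$values else as.matrix(phase_map)
  if (!all(dim(v) == dim(gamma_t$mask))) stop("phase map / mask shape mismatch")
  if (!any(gamma_t$mask)) stop("tendinous region is empty")
  t_otsu <- otsu_threshold(v[gamma_t$mask])
  sel <- if (comparison == "keep_high") v > t_otsu else v <= t_otsu
  structure(list(mask = gamma_t$mask & sel, kind = "mtj",
                 source_lines = gamma_t$source_lines,
                 t_d_mm = gamma_t$t_d_mm, t_otsu = t_otsu),
            class = "region_mask")
}
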