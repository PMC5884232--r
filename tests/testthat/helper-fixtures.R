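# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures are stored.

# Seed points on the true band lines of a phantom, for initializing the
# tracker (superficial = band 1, deep = band 2).
init_points_from_truth <- function(truth, xs = c(100, 220)) {
  center <- mtjtrack:::image_center(truth$shape)
  on_line <- function(lrow) {
    th <- lrow[1L] * pi / 180
    x <- xs - center[1L]
    y <- (lrow[2L] - x * cos(th)) / sin(th)
    cbind(xs, y + center[2L])
  }
  tracked_points(on_line(truth$line1[1L, ]), on_line(truth$line2[1L, ]))
}

rms_trajectory_error <- function(traj, truth) {
  n <- nrow(traj)
  d <- cbind(traj$mtj_x_px, traj$mtj_y_px) - truth$mtj_xy_true[seq_len(n), ]
  sqrt(mean(rowSums(d^2)))
}

# Anti-aliased unit-strength line map: tent profile of half-width 1 px
# around the line (theta_normal_deg, rho_px), centre-relative geometry.
line_phase_map <- function(shape, theta_normal_deg, rho_px) {
  g <- mtjtrack:::center_grid(shape)
  th <- theta_normal_deg * pi / 180
  d <- abs(g$x * cos(th) + g$y * sin(th) - rho_px)
  pmax(1 - d, 0)
}

# Smooth random texture with mean ~0.5, used for flow-recovery tests; the
# gradient-based fit is only valid when displacements are small relative to
# the texture correlation length, hence the generous smoothing.
smooth_texture <- function(rows, cols, sigma = 4) {
  tx <- mtjtrack:::gaussian_smooth(matrix(stats::runif(rows * cols), rows), sigma)
  tx <- (tx - mean(tx)) / stats::sd(tx)
  0.5 + 0.15 * tx
}

# Exact subpixel translation via spectral phase shift (periodic).
spectral_shift <- function(img, dx, dy) {
  u <- mtjtrack:::fft_freqs(ncol(img))
  v <- mtjtrack:::fft_freqs(nrow(img))
  ph <- exp(-2i * pi * (outer(rep(1, nrow(img)), u) * dx +
                          outer(v, rep(1, ncol(img))) * dy))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / length(img)
}

# Warp an image by an affine velocity field (inverse mapping, bilinear),
# sampling from a larger source so borders stay valid: out(p) = img(p - V(p))
# to first order is emulated exactly by sampling at the inverse-transformed
# position.
affine_warp <- function(img, flow, center) {
  g <- mtjtrack:::center_grid(dim(img))
  A <- diag(2) + matrix(c(flow$d + flow$s1, flow$s2 + flow$r,
                          flow$s2 - flow$r, flow$d - flow$s1), 2L, 2L)
  inv <- solve(A)
  px <- as.vector(g$x) - flow$vxt
  py <- as.vector(g$y) - flow$vyt
  x0 <- inv[1L, 1L] * px + inv[1L, 2L] * py
  y0 <- inv[2L, 1L] * px + inv[2L, 2L] * py
  matrix(bilinear_sample(img, x0 + center[1L], y0 + center[2L]),
         nrow(img), ncol(img))
}
bilinear_sample <- mtjtrack:::bilinear_sample

# Per-pixel loop evaluation of the phase-symmetry measure from precomputed
# filter responses — the independent oracle for the vectorized path.
phase_symmetry_loop <- function(resp, thresholds, epsilon = 1e-4,
                                cutoff = 0.5, gain = 10) {
  dims <- dim(resp[[1L]][[1L]])
  n_r <- length(resp); n_s <- length(resp[[1L]])
  out <- matrix(0, dims[1L], dims[2L])
  for (i in seq_len(dims[1L])) {
    for (j in seq_len(dims[2L])) {
      num <- 0; den <- 0
      for (r in seq_len(n_r)) {
        energy <- 0; suma <- 0; maxa <- 0
        for (s in seq_len(n_s)) {
          z <- resp[[r]][[s]][i, j]
          energy <- energy + abs(Re(z)) - abs(Im(z))
          a <- Mod(z)
          suma <- suma + a
          if (a > maxa) maxa <- a
        }
        width <- (suma / (maxa + .Machine$double.eps) - 1) / (n_s - 1)
        w <- 1 / (1 + exp(gain * (cutoff - width)))
        num <- num + w * max(energy - thresholds[r], 0)
        den <- den + suma
      }
      out[i, j] <- min(max(num / (den + epsilon), 0), 1)
    }
  }
  out
}

# Exhaustive Otsu oracle: test all candidate split points of the same
# 256-bin histogram, computing class weights and means by explicit sums.
otsu_exhaustive <- function(values, n_bins = 256L) {
  values <- pmin(pmax(values, 0), 1)
  idx <- pmin(floor(values * n_bins), n_bins - 1L) + 1L
  h <- tabulate(idx, nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1L):n_bins] * mids[(k + 1L):n_bins]) / w1
    sb <- (w0 / sum(h)) * (w1 / sum(h)) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  best_k / n_bins
}

# Brute-force localized Radon oracle: explicit loop over pixels and theta
# bins with the same linear rho interpolation rule.
radon_loop <- function(w, roi, thetas, rhos, delta_rho) {
  votes <- matrix(0, length(thetas), length(rhos))
  g <- mtjtrack:::center_grid(dim(w))
  rho0 <- rhos[1L]
  for (row in (roi[3L] + 1L):(roi[4L] + 1L)) {
    for (col in (roi[1L] + 1L):(roi[2L] + 1L)) {
      val <- w[row, col]
      if (val <= 0) next
      x <- g$x[row, col]; y <- g$y[row, col]
      for (it in seq_along(thetas)) {
        th <- thetas[it] * pi / 180
        t <- (x * cos(th) + y * sin(th) - rho0) / delta_rho
        i0 <- floor(t)
        fr <- t - i0
        votes[it, i0 + 1L] <- votes[it, i0 + 1L] + val * (1 - fr)
        votes[it, i0 + 2L] <- votes[it, i0 + 2L] + val * fr
      }
    }
  }
  votes
}
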