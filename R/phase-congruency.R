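# Phase congruency on a log-Gabor quadrature filter bank.
#
# Tendinous tissue (aponeuroses, tendon) appears as ridge-like hyperechoic
# bands, i.e. axes of local intensity symmetry. At a point of symmetry the
# even-symmetric filter response dominates the odd-symmetric one across
# scales, which the phase-symmetry measure rewards; the measure is invariant
# to illumination and contrast, which matters for B-mode gain variation.

# DFT frequencies for n samples, in cycles/pixel, fftshift-free order.
fft_freqs <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Build a log-Gabor quadrature filter bank
#'
#' Constructs one complex-quadrature transfer function per (orientation,
#' scale) pair on the DFT grid of `shape`. The radial profile is log-Gaussian
#' around the centre frequency `1 / (min_wavelength * scale_multiplier^(s-1))`
#' (zero at DC by construction); the angular profile is a Gaussian in angle
#' around each orientation centre, covering a single half-plane so that the
#' inverse transform of `spectrum * filter` yields the even-symmetric response
#' in its real part and the odd-symmetric response in its imaginary part.
#'
#' Orientation centres are uniformly spaced over \[0, 180) degrees and name the
#' RIDGE direction, measured from the image x-axis counter-clockwise; the
#' spectral energy of a ridge lies along its normal, which the constructor
#' accounts for internally.
#'
#' @param shape integer (rows, cols) of the frames the bank will filter;
#'   both must be at least 16.
#' @param n_scales number of wavelet scales (>= 2).
#' @param n_orientations number of orientation centres (>= 3).
#' @param min_wavelength wavelength in pixels of the smallest-scale filter.
#' @param scale_multiplier geometric spacing between successive scales.
#' @param sigma_on_f ratio of the radial Gaussian's sigma to the centre
#'   frequency (log-domain bandwidth; 0.55 is roughly two octaves).
#' @param angular_sigma angular standard deviation in degrees; default
#'   `(180 / n_orientations) / 1.2`, giving even orientation coverage.
#' @return An object of class `loggabor_bank`; `$filters[[r]][[s]]` is the
#'   real transfer function for orientation centre r and scale s.
#' @export
build_loggabor_bank <- function(shape, n_scales = 4L, n_orientations = 6L,
                                min_wavelength = 3, scale_multiplier = 2.1,
                                sigma_on_f = 0.55, angular_sigma = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L)) {
    stop("shape must be (rows, cols) with both dimensions >= 16")
  }
  if (n_scales < 2L) stop("n_scales must be >= 2")
  if (n_orientations < 3L) stop("n_orientations must be >= 3")
  if (min_wavelength <= 0) stop("min_wavelength must be positive (pixels)")
  if (scale_multiplier <= 1) stop("scale_multiplier must exceed 1")
  rows <- shape[1L]; cols <- shape[2L]
  if (is.null(angular_sigma)) angular_sigma <- (180 / n_orientations) / 1.2

  fx <- matrix(rep(fft_freqs(cols), each = rows), rows, cols)
  fy <- matrix(rep(fft_freqs(rows), times = cols), rows, cols)
  radius <- sqrt(fx^2 + fy^2)
  radius[1L, 1L] <- 1  # placeholder; DC forced to zero below
  theta <- atan2(fy, fx)
  sintheta <- sin(theta); costheta <- cos(theta)

  orientation_centers <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  sig_rad <- angular_sigma * pi / 180

  radial <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    wavelength <- min_wavelength * scale_multiplier^(s - 1L)
    f0 <- 1 / wavelength
    g <- exp(-(log(radius / f0))^2 / (2 * log(sigma_on_f)^2))
    g[1L, 1L] <- 0
    radial[[s]] <- g
  }

  filters <- vector("list", n_orientations)
  for (r in seq_len(n_orientations)) {
    # spectral centre is the ridge normal: ridge direction + 90 degrees
    psi <- (orientation_centers[r] + 90) * pi / 180
    ds <- sintheta * cos(psi) - costheta * sin(psi)
    dc <- costheta * cos(psi) + sintheta * sin(psi)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * sig_rad^2))
    filters[[r]] <- lapply(radial, function(g) g * spread)
  }

  structure(
    list(
      shape = shape,
      n_scales = as.integer(n_scales),
      n_orientations = as.integer(n_orientations),
      min_wavelength = min_wavelength,
      scale_multiplier = scale_multiplier,
      sigma_on_f = sigma_on_f,
      orientation_centers = orientation_centers,
      angular_sigma = angular_sigma,
      filters = filters
    ),
    class = "loggabor_bank"
  )
}

#' @export
print.loggabor_bank <- function(x, ...) {
  cat(sprintf(
    "<loggabor_bank %d x %d px, %d scales x %d orientations, min wavelength %g px>\n",
    x$shape[1L], x$shape[2L], x$n_scales, x$n_orientations, x$min_wavelength))
  invisible(x)
}

# Raised-cosine border taper: damps the border towards the image mean so the
# periodic spectral boundary assumption does not create wrap-around ridges.
taper_border <- function(px, width) {
  if (width <= 0) return(px)
  ramp <- function(n) {
    d <- pmin(seq_len(n) - 1L, n - seq_len(n))
    w <- rep(1, n)
    idx <- d < width
    w[idx] <- 0.5 * (1 - cos(pi * d[idx] / width))
    w
  }
  win <- outer(ramp(nrow(px)), ramp(ncol(px)))
  m <- mean(px)
  m + (px - m) * win
}

#' Quadrature filter responses of a frame
#'
#' Filters the frame with every (orientation, scale) pair of the bank in the
#' frequency domain. The real part of each returned array is the
#' even-symmetric (line-like) response and the imaginary part the
#' odd-symmetric (edge-like) response; the modulus is the local amplitude
#' A_rs.
#'
#' @param frame an [image_frame()] or plain matrix whose shape matches the
#'   bank's spectral grid.
#' @param bank a [build_loggabor_bank()] result.
#' @param orientations integer indices of orientation centres to compute
#'   (default all); restricting the set is how the oriented variant avoids
#'   paying for unused orientations.
#' @param taper_px width of the raised-cosine border taper applied before the
#'   transform (0 disables).
#' @return A list over orientations (named by centre angle), each a list over
#'   scales of complex matrices.
#' @export
filter_responses <- function(frame, bank, orientations = NULL, taper_px = 16) {
  px <- frame_pixels(frame)
  if (!all(dim(px) == bank$shape)) {
    stop("frame shape (", nrow(px), " x ", ncol(px),
         ") does not match bank shape (", bank$shape[1L], " x ", bank$shape[2L], ")")
  }
  if (is.null(orientations)) orientations <- seq_len(bank$n_orientations)
  # scale-invariant floating point representation
  mx <- max(px)
  if (mx > 1) px <- px / mx
  px <- taper_border(px, taper_px)
  n <- length(px)
  spectrum <- stats::fft(px)
  out <- lapply(orientations, function(r) {
    lapply(bank$filters[[r]], function(h) stats::fft(spectrum * h, inverse = TRUE) / n)
  })
  names(out) <- sprintf("%g", bank$orientation_centers[orientations])
  out
}

#' Rayleigh noise threshold for one orientation's responses
#'
#' Estimates the expected noise energy in the scale-summed amplitude of one
#' orientation from the median amplitude of the smallest-scale (highest
#' frequency) filter, which is assumed to respond mostly to noise. With
#' Rayleigh-distributed noise amplitude, `median = sigma * sqrt(log 4)`; the
#' per-scale sigma is extrapolated across scales by the geometric series of
#' the bandpass gains and the threshold is `k` times the resulting mean noise
#' energy, so it is exactly linear in `k`.
#'
#' @param responses list of complex response matrices over scales, smallest
#'   scale first (one orientation of [filter_responses()]).
#' @param k noise-threshold multiplier (default 2).
#' @param scale_multiplier geometric scale spacing used to extrapolate the
#'   noise amplitude across scales (must match the bank).
#' @return Non-negative scalar threshold T_r; 0 for all-zero responses.
#' @export
estimate_noise_threshold <- function(responses, k = 2, scale_multiplier = 2.1) {
  if (length(responses) < 2L) stop("need responses for at least 2 scales")
  a1 <- Mod(responses[[1L]])
  tau <- stats::median(a1) / sqrt(log(4))
  m <- 1 / scale_multiplier
  total_tau <- tau * (1 - m^length(responses)) / (1 - m)
  k * total_tau * sqrt(pi / 2)
}

# Shared core of the plain and oriented phase-symmetry measures.
phase_symmetry_core <- function(frame, bank, orientations, epsilon, k_noise,
                                cutoff, gain, noise_thresholds, taper_px,
                                oriented, orientation_range) {
  resp <- filter_responses(frame, bank, orientations, taper_px)
  shape <- bank$shape
  num <- matrix(0, shape[1L], shape[2L])
  den <- matrix(0, shape[1L], shape[2L])
  t_used <- numeric(length(orientations))
  for (i in seq_along(orientations)) {
    rs <- resp[[i]]
    energy <- matrix(0, shape[1L], shape[2L])
    sum_a <- matrix(0, shape[1L], shape[2L])
    max_a <- matrix(0, shape[1L], shape[2L])
    for (s in seq_along(rs)) {
      a <- Mod(rs[[s]])
      energy <- energy + abs(Re(rs[[s]])) - abs(Im(rs[[s]]))
      sum_a <- sum_a + a
      max_a <- pmax(max_a, a)
    }
    t_r <- if (is.null(noise_thresholds)) {
      estimate_noise_threshold(rs, k_noise, bank$scale_multiplier)
    } else {
      noise_thresholds[i]
    }
    t_used[i] <- t_r
    # frequency-spread weighting: penalize narrow-band (single-scale) energy
    width <- (sum_a / (max_a + .Machine$double.eps) - 1) / (length(rs) - 1)
    w <- 1 / (1 + exp(gain * (cutoff - width)))
    num <- num + w * pmax(energy - t_r, 0)
    den <- den + sum_a
  }
  values <- num / (den + epsilon)
  values[values < 0] <- 0
  values[values > 1] <- 1
  structure(
    list(
      values = values,
      oriented = oriented,
      orientation_range = orientation_range,
      orientation_centers = bank$orientation_centers[orientations],
      noise_thresholds = t_used,
      epsilon = epsilon
    ),
    class = "phase_map"
  )
}

#' Phase-symmetry map of a frame
#'
#' Per pixel, sums over all orientations r the weighted, noise-thresholded
#' even-over-odd energy excess `W_r * max(sum_s(|e_rs| - |o_rs|) - T_r, 0)`
#' and normalizes by the total amplitude `sum_rs A_rs + epsilon`, clipping the
#' result to \[0, 1\]. Bright ridges score high; step edges and flat regions
#' score near zero.
#'
#' @inheritParams filter_responses
#' @param epsilon small positive constant guarding the normalization.
#' @param k_noise noise-threshold multiplier passed to
#'   [estimate_noise_threshold()].
#' @param cutoff,gain parameters of the sigmoid frequency-spread weighting
#'   W(x, y) (fractional spread below `cutoff` is suppressed).
#' @param noise_thresholds optional fixed per-orientation thresholds,
#'   overriding the Rayleigh estimate (useful for controlled experiments).
#' @return An object of class `phase_map` with `$values` in \[0, 1\].
#' @export
phase_symmetry <- function(frame, bank, epsilon = 1e-4, k_noise = 2,
                           cutoff = 0.5, gain = 10, noise_thresholds = NULL,
                           taper_px = 16) {
  phase_symmetry_core(frame, bank, seq_len(bank$n_orientations), epsilon,
                      k_noise, cutoff, gain, noise_thresholds, taper_px,
                      oriented = FALSE, orientation_range = c(0, 180))
}

# Map an orientation centre (deg in [0,180)) into the signed band-direction
# convention and test membership of [lo, hi] modulo 180.
orientations_in_range <- function(centers, range) {
  lo <- range[1L]; hi <- range[2L]
  if (hi - lo >= 180) return(seq_along(centers))
  d <- (centers - lo) %% 180
  which(d <= (hi - lo) + 1e-9)
}

#' Orientation-restricted phase-symmetry map
#'
#' Identical to [phase_symmetry()] but sums only over orientation centres
#' whose ridge direction falls inside `orientation_range` (degrees from the
#' image x-axis, counter-clockwise, modulo 180). Aponeuroses in sagittal
#' scans lie within about -10 to 10 degrees of horizontal, so restricting the
#' bank to that band suppresses obliquely oriented fascicle texture.
#'
#' @inheritParams phase_symmetry
#' @param orientation_range numeric \[lo, hi\] in degrees; a width of 180 or
#'   more selects every orientation, reproducing [phase_symmetry()] exactly.
#' @return A `phase_map` with `oriented = TRUE` and the range recorded.
#' @export
oriented_phase_symmetry <- function(frame, bank, orientation_range = c(-10, 10),
                                    epsilon = 1e-4, k_noise = 2, cutoff = 0.5,
                                    gain = 10, noise_thresholds = NULL,
                                    taper_px = 16) {
  sel <- orientations_in_range(bank$orientation_centers, orientation_range)
  if (length(sel) == 0L) {
    stop("no orientation centre falls in [", orientation_range[1L], ", ",
         orientation_range[2L], "] deg; available centres: ",
         paste(bank$orientation_centers, collapse = ", "), " deg")
  }
  phase_symmetry_core(frame, bank, sel, epsilon, k_noise, cutoff, gain,
                      noise_thresholds, taper_px,
                      oriented = TRUE, orientation_range = orientation_range)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map %d x %d px%s, values in [%.3g, %.3g]>\n",
              nrow(x$values), ncol(x$values),
              if (x$oriented) sprintf(", oriented [%g, %g] deg",
                                      x$orientation_range[1L],
                                      x$orientation_range[2L]) else "",
              min(x$values), max(x$values)))
  invisible(x)
}
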