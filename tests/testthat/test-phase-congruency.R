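# Log-Gabor bank construction and the phase-symmetry measure.

test_that("bank has one DC-free quadrature filter per orientation/scale pair", {
  bank <- build_loggabor_bank(c(128, 128), n_scales = 4, n_orientations = 6)
  expect_length(bank$filters, 6L)
  for (r in seq_len(6L)) {
    expect_length(bank$filters[[r]], 4L)
    for (s in seq_len(4L)) {
      expect_identical(bank$filters[[r]][[s]][1L, 1L], 0)
    }
  }
  expect_equal(bank$orientation_centers, c(0, 30, 60, 90, 120, 150))
})

test_that("smallest-scale filter peaks at the design centre frequency", {
  bank <- build_loggabor_bank(c(128, 128), min_wavelength = 3)
  h <- bank$filters[[1L]][[1L]]
  peak <- which(h == max(h), arr.ind = TRUE)[1L, ]
  fx <- mtjtrack:::fft_freqs(128L)[peak[2L]]
  fy <- mtjtrack:::fft_freqs(128L)[peak[1L]]
  expect_lt(abs(sqrt(fx^2 + fy^2) - 1 / 3), 1.5 / 128)
})

test_that("bank constructor rejects degenerate requests", {
  expect_error(build_loggabor_bank(c(8, 128)), "16")
  expect_error(build_loggabor_bank(c(64, 64), min_wavelength = -1), "positive")
  expect_error(build_loggabor_bank(c(64, 64), n_scales = 1), "n_scales")
})

test_that("filter responses vanish on constant frames and match a spatial oracle", {
  bank <- build_loggabor_bank(c(64, 64))
  const <- image_frame(matrix(0.7, 64, 64))
  resp <- filter_responses(const, bank, taper_px = 0)
  expect_lt(max(vapply(resp, function(rr) max(vapply(rr, function(z) max(Mod(z)),
                                                     numeric(1L))), numeric(1L))),
            1e-10)

  # spatial-domain circular convolution oracle at a handful of pixels
  set.seed(42)
  img <- matrix(runif(64 * 64), 64, 64)
  resp <- filter_responses(img, bank, taper_px = 0)
  kern <- stats::fft(bank$filters[[2L]][[2L]], inverse = TRUE) / (64 * 64)
  got <- resp[[2L]][[2L]]
  set.seed(7)
  pts <- cbind(sample(64, 12L), sample(64, 12L))
  for (p in seq_len(nrow(pts))) {
    i <- pts[p, 1L]; j <- pts[p, 2L]
    acc <- 0 + 0i
    for (qi in 1:64) {
      di <- (i - qi) %% 64 + 1L
      dj <- ((j - (1:64)) %% 64) + 1L
      acc <- acc + sum(img[qi, ] * kern[di, dj])
    }
    expect_lt(Mod(acc - got[i, j]) / max(Mod(got[i, j]), 1e-12), 1e-6)
  }
})

test_that("a matched cosine grating yields uniform amplitude and even-dominant response", {
  bank <- build_loggabor_bank(c(64, 64), min_wavelength = 4, scale_multiplier = 2)
  wavelength <- 8  # centre wavelength of scale 2
  y <- matrix(rep(0:63, times = 64), 64, 64)
  img <- 0.5 + 0.4 * cos(2 * pi * y / wavelength)
  resp <- filter_responses(image_frame(img), bank, taper_px = 0)
  # ridge direction 0 deg (horizontal bands) is the first orientation
  z <- resp[[1L]][[2L]]
  a <- Mod(z)[17:48, 17:48]
  expect_lt(stats::sd(a) / mean(a), 0.02)
  maxima_rows <- which(abs(cos(2 * pi * (0:63) / wavelength) - 1) < 1e-9)
  odd_at_max <- abs(Im(z[maxima_rows, 32]))
  even_at_max <- abs(Re(z[maxima_rows, 32]))
  expect_true(all(odd_at_max < 0.05 * even_at_max))
})

test_that("noise threshold is zero for silence, linear in k, and matches its formula", {
  zero <- lapply(1:4, function(s) matrix(0 + 0i, 8, 8))
  expect_identical(estimate_noise_threshold(zero), 0)

  set.seed(3)
  bank <- build_loggabor_bank(c(64, 64))
  resp <- filter_responses(matrix(runif(64 * 64), 64, 64), bank, taper_px = 0)
  t2 <- estimate_noise_threshold(resp[[1L]], k = 2, scale_multiplier = 2.1)
  t4 <- estimate_noise_threshold(resp[[1L]], k = 4, scale_multiplier = 2.1)
  expect_equal(t4, 2 * t2, tolerance = 1e-12)

  # independent reconstruction from the Rayleigh-median definition
  tau <- stats::median(Mod(resp[[1L]][[1L]])) / sqrt(log(4))
  m <- 1 / 2.1
  expected <- 2 * tau * (1 - m^4) / (1 - m) * sqrt(pi / 2)
  expect_equal(t2, expected, tolerance = 1e-12)
})

test_that("phase symmetry is zero on constant frames and peaks on ridges, not edges", {
  bank <- build_loggabor_bank(c(64, 64))
  expect_true(all(phase_symmetry(image_frame(matrix(0.4, 64, 64)), bank)$values == 0))

  ridge <- matrix(0, 64, 64); ridge[32, ] <- 1
  ps_ridge <- phase_symmetry(image_frame(ridge), bank)$values
  for (col in 20:45) {
    expect_equal(which.max(ps_ridge[, col]), 32L)
  }
  step <- matrix(0, 64, 64); step[32:64, ] <- 1
  ps_step <- phase_symmetry(image_frame(step), bank)$values
  expect_gt(ps_ridge[32, 32], ps_step[32, 32])
})

test_that("phase maps stay in [0, 1] on random noise frames", {
  bank <- build_loggabor_bank(c(64, 64))
  set.seed(10)
  for (i in 1:5) {
    pm <- phase_symmetry(image_frame(matrix(runif(64 * 64), 64, 64)), bank)
    expect_true(all(pm$values >= 0 & pm$values <= 1))
  }
})

test_that("the measure is invariant to global intensity scaling", {
  set.seed(12)
  bank <- build_loggabor_bank(c(64, 64))
  img <- matrix(runif(64 * 64, 0.2, 1), 64, 64)
  img[30:34, ] <- img[30:34, ] + 0.8  # add a band so the map is non-trivial
  img <- img / max(img)
  resp <- filter_responses(img, bank, taper_px = 16)
  thr <- vapply(resp, estimate_noise_threshold, numeric(1L))
  ps1 <- phase_symmetry(image_frame(img), bank, noise_thresholds = thr)
  c_scale <- 0.5
  ps2 <- phase_symmetry(image_frame(img * c_scale), bank,
                        noise_thresholds = thr * c_scale)
  expect_lt(max(abs(ps1$values - ps2$values)), 1e-3)
})

test_that("oriented map selects ridges by direction and degenerates to the full measure", {
  bank <- build_loggabor_bank(c(64, 64))
  img <- matrix(0, 64, 64)
  img[32, ] <- 1   # horizontal ridge
  img[, 20] <- 1   # vertical ridge
  pm <- oriented_phase_symmetry(image_frame(img), bank, c(-10, 10))
  horiz <- pm$values[32, setdiff(25:55, 20)]
  vert <- pm$values[setdiff(5:25, 32), 20]
  expect_gt(mean(horiz), 5 * mean(vert))

  # full angular range reproduces the unrestricted measure exactly
  set.seed(4)
  noise <- matrix(runif(64 * 64), 64, 64)
  expect_identical(oriented_phase_symmetry(image_frame(noise), bank, c(0, 180))$values,
                   phase_symmetry(image_frame(noise), bank)$values)

  expect_true(all(oriented_phase_symmetry(image_frame(matrix(0.3, 64, 64)),
                                          bank)$values == 0))
  expect_error(oriented_phase_symmetry(image_frame(noise), bank, c(41, 44)),
               "available centres")
})

test_that("an oblique ridge dominates in its own orientation band at every ridge pixel", {
  bank <- build_loggabor_bank(c(64, 64))
  g <- mtjtrack:::center_grid(c(64, 64))
  phi <- 30 * pi / 180  # ridge direction; normal at 120 deg
  d <- abs(g$x * cos(phi + pi / 2) + g$y * sin(phi + pi / 2))
  img <- exp(-d^2 / (2 * 1.5^2))
  on_band <- oriented_phase_symmetry(image_frame(img), bank, c(20, 40))$values
  off_band <- oriented_phase_symmetry(image_frame(img), bank, c(110, 130))$values
  ridge_px <- which(d < 1 & abs(g$x) < 20 & abs(g$y) < 20)
  expect_true(all(on_band[ridge_px] > off_band[ridge_px]))
})

test_that("vectorized measure equals the per-pixel loop oracle", {
  set.seed(20)
  bank <- build_loggabor_bank(c(32, 32))
  img <- matrix(runif(32 * 32), 32, 32)
  resp <- filter_responses(img, bank, taper_px = 16)
  thr <- vapply(resp, estimate_noise_threshold,
                numeric(1L), scale_multiplier = bank$scale_multiplier)
  got <- phase_symmetry(image_frame(img), bank, noise_thresholds = thr)$values
  want <- phase_symmetry_loop(resp, thr)
  expect_lt(max(abs(got - want)), 1e-9)
})
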