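# Localized Radon transform, revoting line detection, region masks, Otsu.

test_that("accumulator matches brute-force voting and is linear", {
  set.seed(31)
  w <- matrix(0, 32, 32)
  w[sample(length(w), 40L)] <- runif(40L)
  roi <- c(0, 31, 0, 31)
  acc <- localized_radon(w, roi, theta_range = c(80, 100),
                         delta_theta = 2, delta_rho = 2)
  want <- radon_loop(w, roi, acc$theta_deg, acc$rho_px, 2)
  expect_lt(max(abs(acc$votes - want)), 1e-9)

  w2 <- matrix(0, 32, 32)
  w2[sample(length(w2), 40L)] <- runif(40L)
  sum_votes <- localized_radon(w + w2, roi, c(80, 100), 2, 2)$votes
  expect_lt(max(abs(sum_votes -
                      (acc$votes + localized_radon(w2, roi, c(80, 100), 2, 2)$votes))),
            1e-9)
})

test_that("a single centred row votes to (theta = 90, rho = 0)", {
  w <- matrix(0, 65, 65)
  w[33, ] <- 1  # the centre row: y_c = 0
  acc <- localized_radon(w, theta_range = c(80, 100))
  peak <- which(acc$votes == max(acc$votes), arr.ind = TRUE)[1L, ]
  expect_equal(acc$theta_deg[peak[1L]], 90)
  expect_equal(acc$rho_px[peak[2L]], 0)
})

test_that("two parallel rows 10 px apart give two peaks 10 rho-bins apart", {
  w <- matrix(0, 65, 65)
  w[23, ] <- 1
  w[33, ] <- 1
  acc <- localized_radon(w, theta_range = c(80, 100), delta_rho = 1)
  i90 <- which(acc$theta_deg == 90)
  prof <- acc$votes[i90, ]
  top2 <- order(prof, decreasing = TRUE)[1:2]
  expect_setequal(acc$rho_px[top2], c(-10, 0))

  expect_true(all(localized_radon(matrix(0, 65, 65), theta_range = c(80, 100))$votes == 0))
  expect_error(localized_radon(w, roi = c(0, 100, 0, 31)), "roi")
  expect_error(localized_radon(w, theta_range = c(100, 80)), "min < max")
})

test_that("revoting recovers two crossing bands and stops on a single band", {
  shape <- c(400L, 400L)
  # crossing thin ridges at band directions +5 / -5 deg through (300, 200)
  center <- mtjtrack:::image_center(shape)
  mtj_rel <- c(300, 200) - center
  mk_line <- function(band_deg) {
    th <- (band_deg + 90) * pi / 180
    detected_line(band_deg + 90, cos(th) * mtj_rel[1L] + sin(th) * mtj_rel[2L])
  }
  la <- mk_line(5); lb <- mk_line(-5)
  w <- pmax(line_phase_map(shape, la$theta_deg, la$rho_px),
            line_phase_map(shape, lb$theta_deg, lb$rho_px))
  # removal around line 1 also erases line 2's crossing segment, so the
  # second peak keeps ~48% of the first's votes; the stop rule is exercised
  # separately below, here we test geometry recovery
  lines <- detect_lines_revoting(w, mm_per_pixel = 0.11, stop_fraction = 0.4)
  expect_length(lines, 2L)
  got <- lapply(lines, function(l) c(l$theta_deg, l$rho_px))
  want <- lapply(list(la, lb), function(l) c(l$theta_deg, l$rho_px))
  # match each detected line to its nearest truth
  for (g in got) {
    errs <- vapply(want, function(t) {
      c(abs(((g[1L] - t[1L]) + 90) %% 180 - 90), abs(g[2L] - t[2L]))
    }, numeric(2L))
    best <- which.min(colSums(errs))
    expect_lte(errs[1L, best], 0.5)
    expect_lte(errs[2L, best], 1)
  }

  single <- line_phase_map(shape, la$theta_deg, la$rho_px)
  expect_length(detect_lines_revoting(single, mm_per_pixel = 0.11,
                                      stop_fraction = 0.5), 1L)
  expect_length(detect_lines_revoting(matrix(0, 50, 50), mm_per_pixel = 0.11), 0L)
})

test_that("revoting removal silences pixels near the accepted line", {
  shape <- c(120L, 120L)
  w <- pmax(line_phase_map(shape, 90, 0), 0.8 * line_phase_map(shape, 90, -40))
  first <- detect_lines_revoting(w, mm_per_pixel = 0.11, n_lines_max = 1L)[[1L]]
  # manual second iteration: zero the removal band, then vote again
  g <- mtjtrack:::center_grid(shape)
  th <- first$theta_deg * pi / 180
  d <- abs(g$x * cos(th) + g$y * sin(th) - first$rho_px)
  w2 <- w; w2[d <= 2 / 0.11] <- 0
  acc2 <- localized_radon(w2, theta_range = c(80, 100))
  manual_peak <- which(acc2$votes == max(acc2$votes), arr.ind = TRUE)[1L, ]
  both <- detect_lines_revoting(w, mm_per_pixel = 0.11, n_lines_max = 2L,
                                stop_fraction = 0.1)
  expect_length(both, 2L)
  expect_equal(both[[2L]]$theta_deg %% 180, acc2$theta_deg[manual_peak[1L]] %% 180)
  expect_equal(abs(both[[2L]]$rho_px), abs(acc2$rho_px[manual_peak[2L]]))
})

test_that("Radon peak localization succeeds on random single-line maps", {
  set.seed(77)
  hits <- 0L
  for (i in 1:12) {
    band <- runif(1, -10, 10)
    rho <- runif(1, -40, 40)
    w <- line_phase_map(c(128L, 128L), band + 90, rho)
    acc <- localized_radon(w, theta_range = c(80, 100))
    peak <- which(acc$votes == max(acc$votes), arr.ind = TRUE)[1L, ]
    if (abs(acc$theta_deg[peak[1L]] - (band + 90)) <= 0.5 &&
        abs(acc$rho_px[peak[2L]] - rho) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})

test_that("point-line distance matches the two-point cross-product oracle", {
  expect_equal(line_point_distance(detected_line(0, 0), c(0, 0)), 0)
  expect_equal(line_point_distance(detected_line(0, 0), c(7, 0)), 7)
  set.seed(8)
  for (i in 1:20) {
    ln <- detected_line(runif(1, -90, 90), runif(1, -30, 30))
    pt <- runif(2, -50, 50)
    th <- ln$theta_deg * pi / 180
    p0 <- ln$rho_px * c(cos(th), sin(th))
    p1 <- p0 + c(-sin(th), cos(th))
    v <- p1 - p0
    want <- abs(v[1L] * (pt[2L] - p0[2L]) - v[2L] * (pt[1L] - p0[1L])) / sqrt(sum(v^2))
    expect_equal(line_point_distance(ln, pt), want, tolerance = 1e-9)
  }
})

test_that("tendinous region is the union of distance bands around the lines", {
  shape <- c(200L, 200L)
  ln <- detected_line(90, 0)
  gt <- tendinous_region(shape, list(ln), t_d_mm = 2.5, mm_per_pixel = 0.11)
  # brute-force oracle
  g <- mtjtrack:::center_grid(shape)
  want <- abs(g$y) <= 2.5 / 0.11
  expect_identical(gt$mask, want)
  per_col <- colSums(gt$mask)
  expect_true(all(per_col == per_col[1L]))
  expect_lt(abs(per_col[1L] - 2 * 2.5 / 0.11), 2)

  ln2 <- detected_line(90, -60)
  both <- tendinous_region(shape, list(ln, ln2), 2.5, 0.11)
  single2 <- tendinous_region(shape, list(ln2), 2.5, 0.11)
  expect_identical(both$mask, gt$mask | single2$mask)

  # t_d = 0 keeps only exact-distance-zero pixels (odd-sized frame)
  z <- tendinous_region(c(33L, 33L), list(detected_line(0, 0)), 0, 1)
  expect_identical(which(z$mask, arr.ind = TRUE)[, "col"],
                   rep(17L, 33L), ignore_attr = TRUE)
  expect_error(tendinous_region(shape, list()), "at least one")
})

test_that("Otsu threshold equals the exhaustive between-class maximizer", {
  v <- c(rep(0, 50), rep(1, 50))
  t0 <- otsu_threshold(v)
  expect_gt(t0, 0); expect_lt(t0, 1)
  expect_equal(sum(v <= t0), 50L)

  v2 <- c(0, 0, 0, 0.9, 0.9, 0.9)
  t2 <- otsu_threshold(v2)
  expect_true(all(v2[v2 <= t2] == 0) && all(v2[v2 > t2] == 0.9))
  expect_equal(t2, otsu_exhaustive(v2))

  set.seed(55)
  for (i in 1:30) {
    vals <- switch(i %% 3 + 1L,
                   runif(200),
                   c(rnorm(80, 0.25, 0.05), rnorm(120, 0.7, 0.1)),
                   rbeta(150, 2, 5))
    expect_identical(otsu_threshold(vals), otsu_exhaustive(vals))
  }
  expect_error(otsu_threshold(rep(0.5, 10)), "degenerate")
})

test_that("effective MTJ region is the Otsu-selected subset of the tendinous band", {
  shape <- c(100L, 100L)
  ln <- detected_line(90, 0)
  gt <- tendinous_region(shape, list(ln), 2.5, 0.11)
  set.seed(9)
  pm <- matrix(runif(100 * 100, 0, 0.2), 100, 100)
  pm[48:52, ] <- runif(5 * 100, 0.6, 0.9)  # bright band inside Gamma_T
  mtj <- effective_mtj_region(pm, gt, "keep_high")
  expect_true(all(gt$mask[mtj$mask]))
  want_t <- otsu_exhaustive(pm[gt$mask])
  expect_equal(mtj$t_otsu, want_t)
  expect_identical(mtj$mask, gt$mask & pm > want_t)

  low <- effective_mtj_region(pm, gt, "keep_low")
  expect_identical(low$mask, gt$mask & pm <= want_t)
  expect_true(all(gt$mask[low$mask]))

  flat <- matrix(0.5, 100, 100)
  expect_error(effective_mtj_region(flat, gt), "degenerate")
})

test_that("line intersection solves both equations and rejects parallels", {
  expect_equal(intersect_lines(detected_line(0, 0), detected_line(90, 5)),
               c(0, 5))
  expect_equal(intersect_lines(detected_line(45, 0), detected_line(-45, 0)),
               c(0, 0), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    a <- detected_line(runif(1, -90, 90), runif(1, -40, 40))
    b <- detected_line(a$theta_deg + runif(1, 5, 90), runif(1, -40, 40))
    xy <- intersect_lines(a, b)
    for (ln in list(a, b)) {
      th <- ln$theta_deg * pi / 180
      expect_lt(abs(xy[1L] * cos(th) + xy[2L] * sin(th) - ln$rho_px), 1e-9)
    }
  }
  expect_error(intersect_lines(detected_line(10, 0), detected_line(10.2, 5)),
               "parallel")
})
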