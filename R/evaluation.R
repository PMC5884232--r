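# Waveform agreement statistics for comparing displacement trajectories:
# coefficient of multiple correlation (CMC), intraclass correlation (ICC),
# Bland-Altman limits of agreement and polynomial angle-displacement
# regression.

#' Coefficient of multiple correlation between waveforms
#'
#' Within-day (Kadaba-type) CMC: with M waveforms of F frames each,
#' \deqn{CMC = \sqrt{1 - \frac{\sum_f \sum_m (Y_{mf} - \bar Y_f)^2 / (F(M-1))}
#'                        {\sum_f \sum_m (Y_{mf} - \bar Y)^2 / (MF-1)}}}
#' where \eqn{\bar Y_f} is the across-waveform mean at frame f and
#' \eqn{\bar Y} the grand mean. Identical waveforms give 1; unrelated
#' waveforms give values near 0. The measure is invariant to adding a common
#' constant to all waveforms but not to rescaling a single one. A negative
#' radicand (within-frame scatter exceeding overall variance) is clamped to
#' 0, recorded in the `"clamped"` attribute.
#'
#' @param waveforms F x M numeric matrix, one waveform per column (F >= 2
#'   frames, M >= 2 waveforms), all values finite.
#' @return CMC in \[0, 1\].
#' @export
cmc <- function(waveforms) {
  y <- as.matrix(waveforms)
  f <- nrow(y); m <- ncol(y)
  if (m < 2L || f < 2L) stop("need at least 2 waveforms of at least 2 frames")
  if (!all(is.finite(y))) stop("waveforms must be finite")
  frame_means <- rowMeans(y)
  grand_mean <- mean(y)
  within <- sum((y - frame_means)^2) / (f * (m - 1))
  total <- sum((y - grand_mean)^2) / (m * f - 1)
  if (total <= 0) stop("zero total variance: CMC undefined for constant waveforms")
  radicand <- 1 - within / total
  clamped <- radicand < 0
  out <- sqrt(max(radicand, 0))
  attr(out, "clamped") <- clamped
  out
}

#' Intraclass correlation coefficient
#'
#' Two-way mixed-effects, consistency, single-measure ICC (ICC(3,1)) from
#' the mean squares of the two-way subject x rater decomposition:
#' `ICC = (MS_subject - MS_error) / (MS_subject + (k - 1) MS_error)`. Used
#' for intra-observer repeatability of repeated manual measurements, where
#' the raters (repetitions) are fixed. The one-way model ICC(1,1),
#' `((MS_subject - MS_within) / (MS_subject + (k - 1) MS_within))` with the
#' rater effect pooled into the error, is available via `model`.
#'
#' @param measurements n_subjects x k_raters numeric matrix, no missing
#'   cells, n >= 2 and k >= 2.
#' @param model `"ICC3_1"` (default, consistency) or `"ICC1_1"`.
#' @return ICC value (at most 1; can be negative for discordant tables).
#' @export
icc <- function(measurements, model = c("ICC3_1", "ICC1_1")) {
  model <- match.arg(model)
  y <- as.matrix(measurements)
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (!all(is.finite(y))) stop("missing or non-finite cells are not supported")
  grand <- mean(y)
  ss_subject <- k * sum((rowMeans(y) - grand)^2)
  ss_rater <- n * sum((colMeans(y) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ms_subject <- ss_subject / (n - 1)
  if (model == "ICC3_1") {
    ss_error <- ss_total - ss_subject - ss_rater
    ms_error <- ss_error / ((n - 1) * (k - 1))
  } else {
    ss_error <- ss_total - ss_subject
    ms_error <- ss_error / (n * (k - 1))
  }
  if (ms_subject <= 0 && ms_error <= 0) {
    stop("degenerate table: no between-subject or residual variance")
  }
  (ms_subject - ms_error) / (ms_subject + (k - 1) * ms_error)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`; limits of agreement are
#' `mean(d) +- 1.96 * sd(d)` with the n-1 standard deviation.
#'
#' @param a,b numeric series of equal length >= 2.
#' @return Object of class `agreement_stats` with `mean_difference`,
#'   `sd_difference`, `limits_of_agreement` (lower, upper) and `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 2L) stop("need at least 2 paired values")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_difference = m, sd_difference = s,
         limits_of_agreement = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
         n = length(d)),
    class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement: mean diff %.4g, limits [%.4g, %.4g], n = %d>\n",
              x$mean_difference, x$limits_of_agreement[1L],
              x$limits_of_agreement[2L], x$n))
  invisible(x)
}

#' Polynomial regression of displacement on joint angle
#'
#' Least-squares polynomial fit of MTJ displacement on ankle angle plus the
#' Pearson correlation between fitted and observed displacement.
#'
#' @param angle numeric series, degrees.
#' @param displacement numeric series, millimetres; same length as `angle`,
#'   longer than `degree + 1`.
#' @param degree polynomial degree.
#' @return List with `coefficients` (ascending powers, intercept first),
#'   `pearson_r`, and the `lm` `fit`.
#' @export
angle_displacement_regression <- function(angle, displacement, degree = 2L) {
  if (length(angle) != length(displacement)) stop("series lengths differ")
  if (length(angle) <= degree + 1L) {
    stop("need more than degree + 1 points for a degree-", degree, " fit")
  }
  fit <- stats::lm(displacement ~ stats::poly(angle, degree, raw = TRUE))
  if (anyNA(stats::coef(fit))) stop("rank-deficient polynomial design")
  fitted <- stats::fitted(fit)
  r <- if (stats::sd(fitted) == 0 || stats::sd(displacement) == 0) {
    NA_real_
  } else {
    stats::cor(fitted, displacement)
  }
  co <- unname(stats::coef(fit))
  list(coefficients = co, pearson_r = r, fit = fit)
}
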