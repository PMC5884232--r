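# Shared numerical helpers.

# Bilinear interpolation of a matrix at fractional 0-based (x, y) positions
# (x = column, y = row). Coordinates are clamped to the matrix extent, i.e.
# edge values replicate outward.
bilinear_sample <- function(mat, x, y) {
  rows <- nrow(mat); cols <- ncol(mat)
  x <- pmin(pmax(x, 0), cols - 1)
  y <- pmin(pmax(y, 0), rows - 1)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- pmin(x0 + 1L, cols - 1L)
  y1 <- pmin(y0 + 1L, rows - 1L)
  i00 <- y0 + 1L + rows * x0
  i10 <- y1 + 1L + rows * x0
  i01 <- y0 + 1L + rows * x1
  i11 <- y1 + 1L + rows * x1
  (mat[i00] * (1 - fy) + mat[i10] * fy) * (1 - fx) +
    (mat[i01] * (1 - fy) + mat[i11] * fy) * fx
}

# Evaluate a computation under a fixed RNG seed, restoring the caller's
# random state afterwards so generator determinism never leaks.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Smooth 0..1 ramp: 0 below lo, 1 above hi, cosine-smooth between.
smoothstep <- function(x, lo, hi) {
  t <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  t * t * (3 - 2 * t)
}
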