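# Speckle phantom generator: synthetic B-mode-like sequences with two
# hyperechoic bands meeting at a known MTJ, fascicle-like distractors with
# independent motion, and multiplicative Rayleigh speckle attached to the
# moving tissue. Every frame comes with exact ground-truth geometry, so each
# pipeline stage can be validated without real recordings.

#' Constant-velocity translation schedule
#'
#' @param n_frames number of frames in the sequence.
#' @param velocity_px_per_frame numeric (vx, vy) in px/frame.
#' @return n_frames x 6 matrix of per-frame affine rates (columns vxt, vyt,
#'   d, r, s1, s2); row f holds the transform from frame f-1 to f, so row 1
#'   is all zero.
#' @export
schedule_translation <- function(n_frames, velocity_px_per_frame = c(0, 0)) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  m <- matrix(0, n_frames, 6L,
              dimnames = list(NULL, c("vxt", "vyt", "d", "r", "s1", "s2")))
  if (n_frames > 1L) {
    m[2:n_frames, 1L] <- velocity_px_per_frame[1L]
    m[2:n_frames, 2L] <- velocity_px_per_frame[2L]
  }
  m
}

#' Sinusoidal back-and-forth translation schedule
#'
#' Emulates the cyclic MTJ excursion driven by constant-velocity passive
#' ankle rotation between plantar flexion and dorsiflexion: position follows
#' `amplitude * sin(2 pi f / period)` along the given axis.
#'
#' @inheritParams schedule_translation
#' @param amplitude_px peak displacement (ax, ay) in pixels.
#' @param period_frames frames per full back-and-forth cycle.
#' @return Per-frame affine rate matrix as in [schedule_translation()].
#' @export
schedule_sinusoid <- function(n_frames, amplitude_px = c(55, 0),
                              period_frames = 480) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  f <- 0:(n_frames - 1L)
  pos <- sin(2 * pi * f / period_frames)
  m <- matrix(0, n_frames, 6L,
              dimnames = list(NULL, c("vxt", "vyt", "d", "r", "s1", "s2")))
  if (n_frames > 1L) {
    dp <- diff(pos)
    m[2:n_frames, 1L] <- dp * amplitude_px[1L]
    m[2:n_frames, 2L] <- dp * amplitude_px[2L]
  }
  m
}

#' Phantom specification
#'
#' Defaults mirror the acquisition the package targets: a ~400 x 400 px
#' region at 0.11 mm/pixel sampled at 40 frames/s, two hyperechoic bands of
#' 2.5 mm diameter within +-10 degrees of horizontal meeting at the MTJ, and
#' a sinusoidal tendinous excursion emulating passive ankle rotation at
#' 5 deg/s over a 30-degree range (one full cycle every 12 s, i.e. 480
#' frames; peak amplitude about 6 mm).
#'
#' @param shape (rows, cols) in pixels.
#' @param mm_per_pixel physical calibration.
#' @param fps frame rate.
#' @param n_frames sequence length.
#' @param band_width_mm full width at half maximum of the bands' Gaussian
#'   cross-section.
#' @param band_angles_deg band directions of the two aponeuroses, degrees
#'   from horizontal; must differ by at least 1 degree.
#' @param mtj_start_xy initial MTJ position, 0-based (x, y) pixels.
#' @param band_continues_distal logical per band: TRUE renders the band
#'   across the whole frame (an aponeurosis continuing into the free tendon,
#'   like the deep GM aponeurosis into the Achilles tendon), FALSE ends it
#'   blendwise at the MTJ (the superficial aponeurosis bounding the muscle
#'   wedge).
#' @param tendinous_motion per-frame affine rate matrix for the tendinous
#'   compartment (default: sinusoidal excursion).
#' @param distractor_motion per-frame affine rate matrix for the muscular
#'   (distractor) compartment (default: static).
#' @param speckle_scale Rayleigh scale of the multiplicative speckle factors
#'   (default `sqrt(2/pi)`, giving mean factor 1); 0 disables speckle.
#' @param speckle_coherence_px Gaussian coherence of the speckle cells as
#'   (lateral x, axial y) sigmas in pixels, emulating the point-spread
#'   function of the scanner (lateral resolution is coarser than axial);
#'   c(0, 0) gives uncorrelated per-pixel speckle.
#' @param temporal_reseed if TRUE, speckle is re-drawn independently every
#'   frame in image coordinates (pure temporal noise) instead of moving with
#'   the tissue.
#' @param contrast band peak intensity as a multiple of the mean background
#'   echo level.
#' @param n_fascicles number of fascicle-like streaks in the distractor
#'   compartment.
#' @param seed integer RNG seed; same spec and seed give bit-identical
#'   output.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(400L, 400L), mm_per_pixel = 0.11, fps = 40,
                         n_frames = 40L, band_width_mm = 2.5,
                         band_angles_deg = c(5, -5),
                         mtj_start_xy = c(300, 200),
                         band_continues_distal = c(TRUE, FALSE),
                         tendinous_motion = NULL, distractor_motion = NULL,
                         speckle_scale = sqrt(2 / pi), temporal_reseed = FALSE,
                         speckle_coherence_px = c(2, 1),
                         contrast = 3, n_fascicles = 30L, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (abs(band_angles_deg[1L] - band_angles_deg[2L]) < 1) {
    stop("band angles must differ by at least 1 degree")
  }
  if (is.null(tendinous_motion)) {
    tendinous_motion <- schedule_sinusoid(n_frames)
  }
  if (is.null(distractor_motion)) {
    distractor_motion <- schedule_translation(n_frames, c(0, 0))
  }
  if (nrow(tendinous_motion) != n_frames || nrow(distractor_motion) != n_frames) {
    stop("motion schedules must have one row per frame")
  }
  structure(
    list(shape = as.integer(shape), mm_per_pixel = mm_per_pixel, fps = fps,
         n_frames = as.integer(n_frames), band_width_mm = band_width_mm,
         band_angles_deg = band_angles_deg, mtj_start_xy = mtj_start_xy,
         band_continues_distal = band_continues_distal,
         tendinous_motion = tendinous_motion,
         distractor_motion = distractor_motion,
         speckle_scale = speckle_scale, temporal_reseed = temporal_reseed,
         speckle_coherence_px = speckle_coherence_px,
         contrast = contrast, n_fascicles = as.integer(n_fascicles),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Compose per-frame affine rates into cumulative transforms mapping
# centre-relative material (frame 0) coordinates to frame-f coordinates:
# p_f = L %*% p_0 + t.
cumulative_transforms <- function(schedule) {
  n <- nrow(schedule)
  out <- vector("list", n)
  L <- diag(2); tr <- c(0, 0)
  out[[1L]] <- list(L = L, t = tr)
  for (f in seq_len(n)[-1L]) {
    p <- schedule[f, ]
    Mf <- diag(2) + matrix(c(p["d"] + p["s1"], p["s2"] + p["r"],
                             p["s2"] - p["r"], p["d"] - p["s1"]), 2L, 2L)
    L <- Mf %*% L
    tr <- Mf %*% tr + c(p["vxt"], p["vyt"])
    out[[f]] <- list(L = L, t = as.vector(tr))
  }
  out
}

# Map a line (normal form, centre-relative) through an affine transform by
# transforming a point on the line and its direction.
transform_line <- function(line, L, tr) {
  th <- line$theta_deg * pi / 180
  nrm <- c(cos(th), sin(th))
  p0 <- line$rho_px * nrm
  u <- c(-nrm[2L], nrm[1L])
  p1 <- as.vector(L %*% p0 + tr)
  v <- as.vector(L %*% u)
  n2 <- c(-v[2L], v[1L])
  n2 <- n2 / sqrt(sum(n2^2))
  detected_line(atan2(n2[2L], n2[1L]) * 180 / pi, sum(n2 * p1))
}

rayleigh_field <- function(rows, cols, scale) {
  if (scale <= 0) return(matrix(1, rows, cols))
  matrix(scale * sqrt(-2 * log(stats::runif(rows * cols))), rows, cols)
}

# Speckle factor field: per-pixel Rayleigh draws given a PSF-like coherence
# length by anisotropic Gaussian smoothing (y/axial, x/lateral).
speckle_field <- function(rows, cols, scale, coherence_px = c(2, 1)) {
  f <- rayleigh_field(rows, cols, scale)
  if (scale <= 0 || all(coherence_px <= 0)) return(f)
  gaussian_smooth(f, c(coherence_px[2L], coherence_px[1L]))
}

# Low-pass tissue echo texture with mean `level`.
tissue_texture <- function(rows, cols, level = 0.22, sd = 0.06, sigma = 1.5) {
  tx <- gaussian_smooth(matrix(stats::runif(rows * cols), rows, cols), sigma)
  tx <- (tx - mean(tx)) / stats::sd(tx)
  pmax(level + sd * tx, 0.02)
}

#' Generate a phantom ultrasound sequence with ground truth
#'
#' Renders the two bands with a Gaussian cross-section into a static material
#' texture (terminating smoothly at the MTJ so the wedge between the
#' aponeuroses looks like the real junction), adds fascicle-like oblique
#' streaks to the surrounding muscular compartment, and produces each frame
#' by warping the two compartments through their own cumulative affine
#' transforms with a 3-px alpha blend at the seam. Speckle is multiplicative
#' Rayleigh noise attached to the moving tissue (or re-drawn per frame when
#' `temporal_reseed` is set).
#'
#' @param spec a [phantom_spec()].
#' @return List with `frames` (list of [image_frame()]) and `truth`, a
#'   `phantom_truth` object holding per-frame true MTJ positions, true band
#'   lines, true affine schedules and a [compartment_mask()] accessor.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    rows <- spec$shape[1L]; cols <- spec$shape[2L]
    center <- image_center(spec$shape)
    ten_tf <- cumulative_transforms(spec$tendinous_motion)
    dis_tf <- cumulative_transforms(spec$distractor_motion)

    # margin: how far outside the frame material can be sampled from
    corners <- rbind(c(0, 0), c(cols - 1, 0), c(0, rows - 1),
                     c(cols - 1, rows - 1))
    corners <- sweep(corners, 2L, center)
    reach <- 0
    for (tf in c(ten_tf, dis_tf)) {
      inv <- solve(tf$L)
      back <- t(inv %*% (t(corners) - tf$t))
      reach <- max(reach, abs(back - corners))
    }
    mar <- ceiling(reach) + 8L
    mrows <- rows + 2L * mar; mcols <- cols + 2L * mar

    # --- material textures (frame-0 coordinates, with margin) ---
    fwhm_px <- spec$band_width_mm / spec$mm_per_pixel
    sigma_b <- fwhm_px / (2 * sqrt(2 * log(2)))
    base_level <- 0.22
    band_peak <- min(spec$contrast * base_level, 0.9)

    # centre-relative coordinate grids of the material plane
    gx <- matrix(rep((0:(mcols - 1L)) - mar - center[1L], each = mrows), mrows, mcols)
    gy <- matrix(rep((0:(mrows - 1L)) - mar - center[2L], times = mcols), mrows, mcols)

    mtj_rel <- spec$mtj_start_xy - center
    band_lines <- lapply(spec$band_angles_deg, function(a) {
      th <- (a + 90) * pi / 180  # normal = band direction + 90 deg
      nrm <- c(cos(th), sin(th))
      detected_line(a + 90, sum(nrm * mtj_rel))
    })

    band_field <- matrix(0, mrows, mcols)
    wedge_d <- NULL
    for (i in seq_along(band_lines)) {
      ln <- band_lines[[i]]
      th <- ln$theta_deg * pi / 180
      d <- abs(gx * cos(th) + gy * sin(th) - ln$rho_px)
      if (isTRUE(spec$band_continues_distal[i])) {
        along <- 1  # aponeurosis continues into the free tendon
      } else {
        u <- c(sin(th), -cos(th))         # along-band direction
        if (u[1L] < 0) u <- -u            # oriented distally (+x)
        s <- (gx - mtj_rel[1L]) * u[1L] + (gy - mtj_rel[2L]) * u[2L]
        along <- 1 / (1 + exp(s / 3))     # band ends blendwise at the MTJ
      }
      band_field <- pmax(band_field, exp(-d^2 / (2 * sigma_b^2)) * along)
      deff <- d + (1 - along) * 1e6       # distance counts only where band exists
      wedge_d <- if (is.null(wedge_d)) deff else pmin(wedge_d, deff)
    }

    ten_mat <- tissue_texture(mrows, mcols)
    ten_mat <- pmax(ten_mat, band_peak * band_field)

    dis_mat <- tissue_texture(mrows, mcols)
    if (spec$n_fascicles > 0L) {
      # fascicles: thin, short, oblique, and noticeably less echogenic than
      # the aponeuroses (pennation angles roughly 15-35 deg)
      for (i in seq_len(spec$n_fascicles)) {
        ang <- (stats::runif(1, 15, 35)) * sample(c(-1, 1), 1) * pi / 180
        cx <- stats::runif(1, min(gx), max(gx))
        cy <- stats::runif(1, min(gy), max(gy))
        len <- stats::runif(1, 25, 60)
        amp <- stats::runif(1, 0.12, 0.28)
        ux <- cos(ang); uy <- sin(ang)
        s <- (gx - cx) * ux + (gy - cy) * uy
        d <- abs(-(gx - cx) * uy + (gy - cy) * ux)
        streak <- amp * exp(-d^2 / (2 * 1^2)) * (abs(s) < len / 2)
        dis_mat <- pmax(dis_mat, streak)
      }
    }

    # tendinous compartment: within one band width of a band, 3-px seam blend
    alpha_mat <- 1 - smoothstep(wedge_d, fwhm_px, fwhm_px + 3)

    if (!spec$temporal_reseed && spec$speckle_scale > 0) {
      ten_mat <- ten_mat * speckle_field(mrows, mcols, spec$speckle_scale,
                                         spec$speckle_coherence_px)
      dis_mat <- dis_mat * speckle_field(mrows, mcols, spec$speckle_scale,
                                         spec$speckle_coherence_px)
    }

    # --- per-frame rendering ---
    fx <- matrix(rep((0:(cols - 1L)) - center[1L], each = rows), rows, cols)
    fy <- matrix(rep((0:(rows - 1L)) - center[2L], times = cols), rows, cols)
    fxv <- as.vector(fx); fyv <- as.vector(fy)

    sample_material <- function(mat, tf) {
      inv <- solve(tf$L)
      px0 <- inv[1L, 1L] * (fxv - tf$t[1L]) + inv[1L, 2L] * (fyv - tf$t[2L])
      py0 <- inv[2L, 1L] * (fxv - tf$t[1L]) + inv[2L, 2L] * (fyv - tf$t[2L])
      matrix(bilinear_sample(mat, px0 + center[1L] + mar, py0 + center[2L] + mar),
             rows, cols)
    }

    frames <- vector("list", spec$n_frames)
    mtj_true <- matrix(NA_real_, spec$n_frames, 2L)
    l1 <- matrix(NA_real_, spec$n_frames, 2L)
    l2 <- matrix(NA_real_, spec$n_frames, 2L)
    for (f in seq_len(spec$n_frames)) {
      ten_f <- sample_material(ten_mat, ten_tf[[f]])
      dis_f <- sample_material(dis_mat, dis_tf[[f]])
      alpha_f <- sample_material(alpha_mat, ten_tf[[f]])
      img <- alpha_f * ten_f + (1 - alpha_f) * dis_f
      if (spec$temporal_reseed && spec$speckle_scale > 0) {
        img <- img * speckle_field(rows, cols, spec$speckle_scale,
                                   spec$speckle_coherence_px)
      }
      img <- pmin(pmax(img, 0), 1)
      frames[[f]] <- image_frame(img, spec$mm_per_pixel, f - 1L, spec$fps)

      tl1 <- transform_line(band_lines[[1L]], ten_tf[[f]]$L, ten_tf[[f]]$t)
      tl2 <- transform_line(band_lines[[2L]], ten_tf[[f]]$L, ten_tf[[f]]$t)
      l1[f, ] <- c(tl1$theta_deg, tl1$rho_px)
      l2[f, ] <- c(tl2$theta_deg, tl2$rho_px)
      mtj_true[f, ] <- intersect_lines(tl1, tl2, center)
    }

    truth <- structure(
      list(mtj_xy_true = mtj_true, line1 = l1, line2 = l2,
           tendinous_motion = spec$tendinous_motion,
           distractor_motion = spec$distractor_motion,
           tendinous_transforms = ten_tf,
           alpha_material = alpha_mat, margin = mar, shape = spec$shape,
           mm_per_pixel = spec$mm_per_pixel),
      class = "phantom_truth")
    list(frames = frames, truth = truth)
  })
}

#' Ground-truth compartment mask at a frame
#'
#' @param truth the `phantom_truth` of a [generate_phantom()] result.
#' @param frame 0-based frame index.
#' @return Logical matrix, TRUE where the pixel belongs to the tendinous
#'   compartment at that frame.
#' @export
compartment_mask <- function(truth, frame = 0L) {
  tf <- truth$tendinous_transforms[[frame + 1L]]
  rows <- truth$shape[1L]; cols <- truth$shape[2L]
  center <- image_center(truth$shape)
  fx <- rep((0:(cols - 1L)) - center[1L], each = rows)
  fy <- rep((0:(rows - 1L)) - center[2L], times = cols)
  inv <- solve(tf$L)
  px0 <- inv[1L, 1L] * (fx - tf$t[1L]) + inv[1L, 2L] * (fy - tf$t[2L])
  py0 <- inv[2L, 1L] * (fx - tf$t[1L]) + inv[2L, 2L] * (fy - tf$t[2L])
  a <- bilinear_sample(truth$alpha_material,
                       px0 + center[1L] + truth$margin,
                       py0 + center[2L] + truth$margin)
  matrix(a >= 0.5, rows, cols)
}

#' True displacement series of a phantom
#'
#' Convenience wrapper projecting the true MTJ path the same way
#' [displacement_series()] projects the tracked one.
#'
#' @inheritParams displacement_series
#' @param truth a `phantom_truth`.
#' @export
true_displacement <- function(truth, reference_frame = 0L, distal_axis = c(1, 0)) {
  displacement_series(truth$mtj_xy_true, reference_frame,
                      truth$mm_per_pixel, distal_axis)
}
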