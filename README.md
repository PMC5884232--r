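# mtjtrack

Automatic tracking of the myotendinous junction (MTJ) in B-mode
musculoskeletal ultrasound sequences.

## Who this is for

Researchers in muscle-tendon mechanics who record sagittal ultrasound of the
gastrocnemius medialis (or a similar pennate muscle) during motion and need
the frame-by-frame displacement of the MTJ — the point where the superficial
and deep aponeuroses converge into the free tendon — without measuring it
manually in every frame. The MTJ displacement separates tendon length change
from fascicle length change within the muscle-tendon unit.

## The method

The difficulty is that tissues around the junction (muscle bellies, fascicles,
subcutaneous layers) move differently from the tendinous tissue, so a motion
model fitted over a whole region of interest is contaminated, and speckle
noise corrupts intensity-based similarity measures. `mtjtrack` therefore
segments the tendinous tissue first and fits the motion model only there:

1. **Oriented phase congruency** — a contrast/illumination-invariant ridge
   measure from a log-Gabor quadrature filter bank, restricted to
   orientations within ±10° of horizontal:
   `PS(x,y) = Σ_r W_r ⌊Σ_s (|e_rs| − |o_rs|) − T_r⌋ / (Σ_rs A_rs + ε)`,
   with even/odd responses `e, o`, amplitudes `A`, a Rayleigh-statistics
   noise threshold `T_r` and a frequency-spread weighting `W`.
2. **Localized Radon transform with revoting** — line-integral voting of the
   phase map over (θ, ρ) within the tendinous angular range; peaks are
   extracted one by one, removing the 2 mm neighbourhood of each accepted
   line before re-voting, yielding the two aponeurosis lines.
3. **Effective MTJ region Γ_MTJ** — pixels within T_d = 2.5 mm of a detected
   line (the tendinous band Γ_T), thresholded by Otsu's method on the phase
   values inside Γ_T.
4. **Masked affine Lucas-Kanade flow** — the six-parameter global affine
   velocity field `Vx = x(d+s1) + y(s2−r) + vxt`,
   `Vy = x(s2+r) + y(d−s1) + vyt` fitted by least squares from the
   spatiotemporal gradients over Γ_MTJ only, advecting manually seeded points
   on each aponeurosis.
5. **MTJ = intersection of the two refitted aponeurosis lines**, linearly
   extrapolated when the junction leaves the field of view; displacement is
   the projection onto the distal axis in millimetres.

The package also ships a **speckle phantom generator** (known band geometry,
independent compartment motion, Rayleigh speckle attached to the moving
tissue) and the **agreement statistics** used to evaluate trackers: the
coefficient of multiple correlation (CMC), ICC(3,1), Bland-Altman limits of
agreement, and polynomial angle-displacement regression.

## Worked example

Track a phantom whose tendinous compartment translates distally at
0.5 px/frame (0.11 mm/px, 40 frames/s):

```r
library(mtjtrack)

spec <- phantom_spec(n_frames = 40,
                     tendinous_motion = schedule_translation(40, c(0.5, 0)),
                     seed = 42)
ph <- generate_phantom(spec)

# seed points on each aponeurosis in frame 0 (normally read from a CSV of
# manually picked points via read_init_points())
init <- tracked_points(
  superficial = rbind(c(100, 182.5), c(220, 193.0)),
  deep        = rbind(c(100, 217.5), c(220, 207.0)))

traj <- track_sequence(ph$frames, init)
traj[c(1, 2, 20, 40), c("frame", "time_s", "mtj_x_px", "mtj_y_px",
                        "in_roi", "displacement_mm")]
#> <mtj_trajectory: 4 frames, displacement 0.00 .. 2.13 mm>
#>    frame time_s mtj_x_px mtj_y_px in_roi displacement_mm
#> 1      0  0.000 300.0000 200.0000   TRUE      0.00000000
#> 2      1  0.025 300.4973 200.0025   TRUE      0.05470192
#> 20    19  0.475 309.4475 200.0295   TRUE      1.03922738
#> 40    39  0.975 319.3960 200.0649   TRUE      2.13355801
```

The MTJ starts at its true position (300, 200) and advances ~0.5 px/frame
distally; `displacement_mm` is the signed distal excursion relative to frame
0 (19.4 px × 0.11 mm/px ≈ 2.13 mm by frame 39). Comparing against the
phantom's ground truth:

```r
dtrue <- true_displacement(ph$truth)
as.numeric(cmc(cbind(traj$displacement_mm, dtrue)))
#> 1                                  # identical waveforms give CMC = 1
bland_altman(traj$displacement_mm, dtrue)$mean_difference
#> -0.0056                            # mm
err <- sqrt(rowSums((cbind(traj$mtj_x_px, traj$mtj_y_px) - ph$truth$mtj_xy_true)^2))
sqrt(mean(err^2))
#> 0.0696                             # px RMS position error
```

Running the same sequence with `track_sequence(..., unmasked = TRUE)` fits
the flow over the whole frame (the traditional Lucas-Kanade baseline); on
phantoms whose muscular compartment moves independently this degrades sharply
while the masked tracker is unaffected — the ordering the method exists to
demonstrate.

## Command line

A thin launcher over the same functions is installed at
`inst/cli/mtjtrack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mtjtrack.R", package="mtjtrack"))')" \
  track --input seq.tif --init init.csv --out traj.csv [--config cfg.yaml] [--unmasked]
# other subcommands: segment, simulate, evaluate
```

Input sequences are multi-page TIFF stacks or directories of PNG/TIFF frames
(8/16-bit grayscale; RGB is reduced by luma conversion). Trajectories are CSV
with columns `frame, time_s, mtj_x_px, mtj_y_px, theta1_deg, rho1_px,
theta2_deg, rho2_px, in_roi, displacement_mm`.

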