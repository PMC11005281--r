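# limbalign

Automatic measurement of lower-limb alignment from standing anteroposterior
long-leg radiographs, for knee osteoarthritis assessment and arthroplasty
planning.

Surgeons quantify limb alignment by marking ten anatomical landmarks per
limb (femoral head centre, femoral diaphysis centre, condylar margins, knee
joint centres, tibial plateau margins, tibial diaphysis centre, ankle
centre) and measuring five angles between the lines that connect them:

* **HKA** — hip-knee-ankle angle, between the femoral mechanical axis
  (femoral head centre to knee centre, `v1 -> v4`) and the tibial
  mechanical axis (`v7 -> v10`); 0° for a straight limb, negative for
  varus, positive for valgus.
* **JCLA** — joint line convergence angle, between the femoral condylar
  line (`v3 -> v5`) and the tibial plateau line (`v6 -> v8`); positive
  when the joint lines converge medially.
* **AMA** — anatomical-mechanical angle of the femur (`v2 -> v4` vs
  `v1 -> v4`).
* **mLDFA** — mechanical lateral distal femoral angle (femoral mechanical
  axis vs femoral joint line, lateral side).
* **mMPTA** — mechanical medial proximal tibial angle (tibial mechanical
  axis vs tibial joint line, medial side).

Limbs are classified varus (HKA ≤ −2°), neutral, or valgus (HKA ≥ +2°).

`limbalign` implements the full measurement chain:

* **Detector** — a compact two-branch network (Gaussian-heatmap regression
  head plus an edge-vector constraint head) over a three-stream
  multi-resolution backbone, implemented directly on BLAS matrix products
  so a desk-scale variant trains on one CPU in minutes.
* **Heatmap codec** — peak-1 Gaussian encoding (σ = 2 heatmap pixels) and
  argmax decoding with quarter-pixel refinement.
* **Geometry** — landmark-to-angle conversion with documented sign
  conventions and loud failure on side/coordinate inconsistencies.
* **Phantom generator** — synthetic AP long-leg radiographs with exactly
  known landmarks and angles (knee-osteoarthritis cohort mixture: 54.5%
  varus / 30.7% neutral / 14.8% valgus, optional knee prosthesis,
  portable-capture degradation), so the pipeline trains and validates with
  no clinical data.
* **Evaluation statistics** — mean radial error (MRE), mean absolute
  difference (MAD), angle-deviation rates (AD < 1°, < 2°), Bland-Altman
  95% limits of agreement, and Pearson chi-square subgroup tests.

See `vignettes/limbalign-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a phantom cohort, measure the ground-truth landmarks, and check
the agreement machinery against a jittered copy of the measurements:

```r
library(limbalign)

dir <- tempfile()
cmd_simulate(6, dir, phantom_cohort(image_height = 160, image_width = 80),
             seed = 7)
angles <- cmd_measure(file.path(dir, "landmarks.csv"),
                      file.path(dir, "angles_auto.csv"))
angles[, c("image_id", "side", "hka", "mldfa", "mmpta", "alignment")]
#> # A tibble: 6 x 6
#>   image_id     side     hka mldfa mmpta alignment
#>   <chr>        <chr>  <dbl> <dbl> <dbl> <fct>
#> 1 phantom_0001 left    5.40  88.4  88.9 valgus
#> 2 phantom_0002 left   -2.28  89.1  87.2 varus
#> 3 phantom_0003 left  -10.3   93.5  84.2 varus
#> 4 phantom_0004 left   -7.41  91.1  85.1 varus
#> 5 phantom_0005 left  -10.3   90.7  84.7 varus
#> 6 phantom_0006 left   -1.07  88.1  85.2 neutral

set.seed(1)
noisy <- dplyr::mutate(angles, hka = hka + rnorm(6, 0, 0.5))
rep <- agreement(angles$hka, noisy$hka)
rep
#> <agreement_report> n = 6
#>   MAD 0.366 +/- 0.249 deg
#>   AD < 1 deg: 100.00%
#>   AD < 2 deg: 100.00%
#>   Bland-Altman bias -0.015, 95% LoA [-0.939, 0.910]
autoplot(rep)   # Bland-Altman plot
```

The HKA values land in the varus/neutral/valgus bands of the configured
cohort mixture, and the agreement report shows the jitter's own scale:
MAD near `0.5 * sqrt(2/pi) ≈ 0.4`, limits of agreement near `±1.96 * 0.5`.

Train the desk-scale detector end to end on phantoms:

```r
cohort <- phantom_cohort(image_height = 128, image_width = 64,
                         spacing_mm = 2.75)
specs <- sample_phantom_specs(220, cohort, seed = 101)
samples <- lapply(seq_len(220), function(i) render_phantom(specs[i, ]))
cfg <- detector_config(input_height = 128L, input_width = 64L,
                       backbone_width = 8L, epochs = 30L, batch_size = 4L,
                       lr_initial = 3e-3, lr_steps = c(20L, 27L),
                       heatmap_peak_weight = 30,
                       augment = c(flip = TRUE, rotate = FALSE,
                                   intensity = TRUE, noise = TRUE),
                       seed = 5L)
fit <- train_detector(samples[1:180], cfg)    # ~6 min on one CPU core
pred <- predict_landmarks(samples[[200]]$image, fit, spacing_mm = 2.75)
measure_limb(prediction_to_limb(pred, samples[[200]]$landmarks$side))
```

On 40 held-out phantoms this configuration detects every joint and
recovers landmarks with a mean radial error of about 0.6 px — roughly 85
times better than the 51.5 px expected of a uniform-random predictor
(`uniform_mre_baseline(64, 128)`) — giving HKA agreement well under 1°
MAD.

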