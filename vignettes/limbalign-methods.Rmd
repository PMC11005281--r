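---
title: "Automated lower-limb alignment measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lower-limb alignment measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbalign)
```

## The measurement problem

Planning and follow-up of knee osteoarthritis therapy — in particular total
knee arthroplasty — rely on the alignment of the lower limb as read from a
standing anteroposterior long-leg radiograph (LLR). Surgeons measure
alignment by marking anatomical landmarks and measuring angles between the
lines connecting them. Done by hand this is slow and poorly reproducible.
`limbalign` codifies the whole measurement chain: a two-branch neural
detector finds ten landmarks per limb, a geometry engine converts them to
the five standard alignment angles, and an evaluation layer quantifies
agreement against reference readings. A parametric phantom generator
provides radiograph-like images with exactly known ground truth, so the
pipeline is trained and validated end to end without clinical data.

## Landmarks and angle constructions

The ten landmarks are: v1 centre of the femoral head, v2 centre of the
femoral diaphysis, v3/v5 lowest points of the lateral/medial femoral
condyle (or prosthesis), v4 centre of the knee joint on the femoral side,
v6/v8 lowest points of the lateral/medial tibial plateau, v7 centre of the
knee joint on the tibial side, v9 centre of the tibial diaphysis, v10
centre of the ankle joint.

The landmark schema admits exactly one two-point construction for each
axis, which is how the package defines them:

* femoral mechanical axis `v1 -> v4`; tibial mechanical axis `v7 -> v10`;
* femoral anatomical axis `v2 -> v4`;
* femoral joint line `v3 -> v5`; tibial joint line `v6 -> v8`.

From these, in the image frame (x right, y down, angles in degrees):

* **HKA** — signed angle between the mechanical axes; 0 for a straight
  limb, *negative for varus* (knee apex lateral: the tibial axis deviates
  medially relative to the femoral axis), positive for valgus.
* **JCLA** — signed angle between the two joint lines, positive when they
  converge medially (open laterally). Only magnitudes are typically
  reported clinically; the sign convention is documented because the
  package keeps signed differences for agreement statistics (an absolute
  convention is available via `jcla_signed = FALSE`).
* **AMA** — unsigned angle between the femoral anatomical and mechanical
  axes (normative centre about 6).
* **mLDFA** — lateral angle between the femoral mechanical axis and the
  femoral joint line; 90 for the symmetric neutral limb, above 90 in varus
  femoral alignment.
* **mMPTA** — medial angle between the tibial mechanical axis and the
  tibial joint line; below 90 in varus tibial alignment.

The medial direction is resolved from the *side label*, never from the
x-ordering of landmarks: a landmark table whose lateral/medial ordering
contradicts its side label raises an error rather than silently flipping
mLDFA/mMPTA and the HKA sign. Limb classification uses the boundary-
inclusive bands varus (HKA less than or equal to -2), neutral, valgus
(greater than or equal to +2).

v9 participates in detection and in radial-error evaluation but in none of
the five angles, mirroring its role in the landmark schema.

### The joint-line closure identity

In any planar limb model whose joint lines are rigid segments, the five
angles are over-determined. With the conventions above,

\[
\mathrm{JCLA} \;=\; \mathrm{mMPTA} - \mathrm{mLDFA} - \mathrm{HKA} .
\]

This follows directly from adding up the directed angles between the four
lines (two mechanical axes, two joint lines). The phantom generator
therefore samples HKA, AMA, mLDFA and mMPTA and *derives* JCLA from the
identity; sampling all five independently would make exact ground truth
impossible. Real measurements violate the identity only through landmark
noise, because each clinical angle is measured from separate landmark
pairs.

## The phantom generator

`sample_phantom_specs()` draws study conditions emulating a surgical knee
osteoarthritis cohort:

* alignment class mixture 54.5% varus / 30.7% neutral / 14.8% valgus,
  with HKA uniform in the class band (varus -12..-2, neutral -2..2, valgus
  2..12);
* AMA normal around 6 (sd 1);
* mLDFA and mMPTA normal (sd 1) around centres that shift with HKA with a
  *bone share* of 0.35 per bone (varus -8 gives mLDFA about 90.8 and mMPTA
  about 84.2). Without this covariation the closure identity would push
  the entire deformity into the joint line and produce JCLA values far
  outside the physiologic range; with it, the derived JCLA stays within a
  few degrees, rising with varus severity as intra-articular wear does;
* side left/right with probability one half; an optional knee prosthesis
  (probability 0.25 by default).

`render_phantom()` builds the landmark geometry analytically (so the
ground-truth angles are exact by construction, verified to below 0.01
degrees by `measure_limb`) and draws a stylised limb: soft-tissue
silhouette, femoral and tibial shafts, a femoral-head disc whose centre is
v1, condylar discs whose lowest points are exactly v3/v5, a plateau
capsule whose upper edge passes through v6/v8, and an ankle blob at v10.
Prosthesis mode replaces the condylar margins and plateau by
high-intensity implant silhouettes with a short tibial stem. Additive
Gaussian intensity noise (sd 0.03 of the unit intensity range) emulates
detector noise.

Portable-capture mode (`capture_degradation = "photo"`) emulates
photographing a film with a hand-held device: a small similarity jitter
(rotation up to 2 degrees, scale 0.97-1.03, shift up to 1% of the frame),
vignetting and extra sensor noise. The jitter is a similarity transform
*by design*: it is reapplied exactly to the ground-truth landmarks, and
because similarities preserve angles, the ground-truth angles are
identical with degradation on or off. A projective warp would break that
exactness; emulating strong perspective is deliberately out of scope (the
capture protocol it stands for is a tripod-mounted, centred camera, which
motivates small distortion).

What the phantoms do *not* emulate: osteophytes and joint-surface wear,
soft-tissue texture, scatter, bilateral full-pelvis scenes, or genuinely
unknown pixel spacing. Passing tests on phantoms therefore demonstrate
that the pipeline machinery is correct and trainable, not that the
shipped desk-scale weights transfer to clinical radiographs.

## Heatmap codec

Landmarks are encoded for training as 2D Gaussian heatmaps with sigma = 2
heatmap pixels, truncated at 3 sigma and rescaled so every in-frame
channel peaks at exactly 1 (the peak-1 reading of "normalised to [0,1]";
unit-mass normalisation would make peak values resolution-dependent).
Landmarks outside the frame yield an all-zero channel with a visibility
flag, never an error.

Decoding takes the channel argmax — first in row-major scan order on ties
— refined by a quarter-pixel shift toward the larger neighbour per axis.
For a truncated Gaussian the argmax is the nearest grid point, so the
refined estimate errs by at most 0.25 px per axis, 0.354 px radially,
inside the frame; the documented bound of 0.5 px holds over the whole
sub-pixel offset cell and is verified exhaustively in the tests. The bare
argmax (error up to 0.707 px radially) is available with
`refine = FALSE`.

Edges between landmarks are encoded as unit direction vectors
`(p_b - p_a)/||p_b - p_a||`; degenerate edges give the zero vector with a
flag. The supervised edge set (configurable) chains
v1-v2-v4, v4-v3, v4-v5, v7-v6, v7-v8, v7-v9-v10 and bridges the joint
with v4-v7, so every angle-defining segment appears.

## Detector

The detector is a compact two-stream backbone in the high-resolution-
network style: a stride-2 stem, a high-resolution stream (stride 2) and a
low-resolution stream (stride 4, double width) run in parallel through
two fusion exchanges (1x1-conv + nearest upsampling low-to-high; stride-2
conv high-to-low), ending in two heads: a 10-channel heatmap head on the
high-resolution stream (output stride 2) and an edge-vector head (global
average pooling + linear) on the low-resolution stream. `backbone_width`
scales all channel counts, so a width-8 variant (about 15k parameters)
trains on one CPU. Forward and backward passes are implemented directly
on BLAS matrix products (one product per kernel offset), with exactness
of the gradients verified against central finite differences in the test
suite.

The input has three channels: the standardised image plus two normalised
coordinate encodings. Convolutions are translation-equivariant, and at
desk-scale depth the receptive field cannot reach the frame borders, so
absolute position along a homogeneous diaphysis (needed for the
shaft-centre landmarks v2 and v9, which have no local appearance cue) is
otherwise unrecoverable. The coordinate channels supply it explicitly and
are appended after augmentation, in the model frame.

Preprocessing resamples each image bilinearly to the configured isotropic
spacing (0.79 mm/pixel by default), preserves aspect ratio, centres with
padding in the input frame and standardises intensities per image; the
affine between original and model coordinates is returned and exactly
invertible. Images with unknown spacing (portable-photo mode) are scaled
to fill the frame; angles remain valid because they are scale-invariant,
and radial errors are then reported in model pixels.

Training minimises

\[
L = \overline{(1 + c\,T)\,(P - T)^2} + w_e\,\mathrm{MSE}(\text{edge vectors}),
\qquad w_e = 0.1,
\]

where \(P\) and \(T\) are the predicted and target heatmaps and
\(c\) (`heatmap_peak_weight`, default 20; 0 recovers the plain
mean-squared error) emphasises the foreground. The emphasis term exists
because the target blobs cover well under 2% of the heatmap area: under a
plain mean square their gradient is diluted by the background, and on
short schedules the channels of landmarks with weak appearance cues never
form. Optimisation is Adam under a stepped learning-rate schedule
(defaults: 1e-3 stepped tenfold down at epochs 120 and 170 of 200, batch
32 — the full-scale protocol; desk-scale runs use a smaller frame and
schedule, see below). The edge head is a training-time consistency
constraint only and is not used at inference. Augmentations —
horizontal flip (which turns a right limb into a left limb; lateral
structures remain lateral, so landmark identities are preserved and only
coordinates mirror), rotation within 5 degrees, intensity scaling within
10%, mild Gaussian noise — are individually toggleable. All randomness is seeded:
identical configs reproduce identical loss curves bitwise.

Detection failure is defined per joint: if any landmark's peak confidence
falls below `detection_threshold` (default 0.3) the joint is reported
not detected; low confidence is a value, never an exception. Each limb is
processed as its own crop (`frame_mode = "per_side"`); a shared full-frame
20-channel mode was considered and not implemented, as the per-side
contract is what the phantom module produces.

## Desk-scale study conditions

The self-contained validation study that the acceptance script and test
suite run uses: 220 phantoms at 128 x 64 pixels (180 train / 40 held
out), backbone width 8, heatmap output stride 2, 30 epochs, batch 4,
learning rate 3e-3 dropped tenfold at epochs 20 and 27, foreground
emphasis 30, edge weight 0.1, flip/intensity/noise augmentation (rotation
off for this short schedule). These sizes keep a full run in the minutes
range on a single CPU core; the full-scale protocol (640 x 320, 200
epochs) is expressed by the defaults of `detector_config()` but is not
exercised by the shipped tests.

The reference comparison point for landmark error is the analytic
mean radial error of a uniform-random predictor,
`uniform_mre_baseline(width, height)` — the closed-form expected distance
between two uniform points in the frame rectangle (about 52 px for a
128 x 64 frame). The trained desk-scale model beats it by well over an
order of magnitude (held-out mean radial error around 0.6 px).

### The joint-line precision floor at desk scale

Angle precision is bounded by landmark precision divided by the length of
the line the angle is measured over. The mechanical axes span about 55 px
at desk scale, so sub-pixel landmark errors leave HKA and AMA mean
absolute differences well under 2 degrees. The joint lines, however, are
anatomically short — condyle width is about 10% of limb length, roughly
13 px here — and the quarter-pixel decode quantises each endpoint
coordinate to a 0.5-px input grid at output stride 2. The decode
quantisation alone therefore contributes a mean absolute difference floor
of roughly `atan(1/3 / 13.3)` (about 1.4 degrees) to mLDFA and mMPTA and
nearly 2 degrees to JCLA (two quantised lines), before any model error.
Measured desk-scale MADs land at roughly 0.6 (HKA), 1.2 (AMA) and 2.3-2.8
degrees (joint-line angles), i.e. the joint-line angles sit essentially on
this floor plus a small model term. Stride-1 heads, which halve the
floor, did not converge within the 30-epoch desk schedule in any tested
configuration (the option is retained in `detector_config()` for longer
schedules), and distribution-aware sub-pixel decoding is deliberately out
of the codec's scope. At clinical resolution the joint line is about 95
px and the same landmark errors put all five angles comfortably below the
floor; the desk-scale joint-line MADs are a resolution artefact, not a
pipeline defect.

## Evaluation statistics

* **MRE** — arithmetic mean of Euclidean radial errors between predicted
  and reference landmarks; the unit (pixels or millimetres via the pixel
  spacing) is preserved and tagged by the caller.
* **MAD** — mean of absolute angle differences, reported with the sample
  standard deviation of the absolute differences.
* **AD rates** — fraction of limbs with absolute deviation *strictly*
  below 1 and 2 degrees (the thresholds carry a strict "<"; a deviation of
  exactly 1 degree does not count as "below 1").
* **Bland-Altman** — bias (mean of prediction minus reference) and 95%
  limits of agreement, bias +/- 1.96 times the sample standard deviation
  (n - 1 denominator) of the differences.
* **Chi-square** — Pearson statistic without continuity correction
  (`stats::chisq.test(correct = FALSE)` behind the package interface),
  df = (r-1)(c-1), upper-tail p, no multiplicity adjustment; used to
  compare accuracy (AD below 1 degree) across patient subgroups. An
  independent brute-force `sum((O-E)^2/E)` oracle cross-checks it in the
  tests.

Differences are signed (prediction minus reference) throughout, including
for JCLA; MAD takes magnitudes afterwards.

## Numerical choices and degenerate inputs

* Angle kernel: `atan2(cross, dot)`, magnitude equal to the arccosine of
  the normalised dot product; vectors shorter than 1e-12 raise an
  invalid-geometry error naming the degenerate axis.
* Decoding ties break to the first maximum in row-major scan order;
  boundary pixels skip the refinement shift on the missing side.
* The bilinear warp used for preprocessing and capture jitter places
  pixel centres at 1-based integer coordinates in both frames; its affine
  metadata is what makes the original-to-model coordinate round trip
  exact to 1e-9 px.
* Constant or empty images raise a preprocessing error; all-zero heatmap
  channels decode to "not detected" with confidence 0.
* Phantom geometry that would leave the frame raises a frame-fit error
  suggesting a larger image rather than rendering clipped bones.

## Known limitations

* The phantom is stylised, not anatomical; transfer of trained weights to
  clinical radiographs is out of scope, and the desk-scale accuracy
  figures describe phantom recovery, not clinical agreement.
* The closure identity makes the five phantom ground-truth angles exactly
  consistent; clinical measurements are not, so agreement statistics on
  phantoms are slightly optimistic for JCLA.
* Only per-side crops are supported; bilateral full-frame detection would
  require a 20-channel head and a bilateral phantom scene.
* The edge branch is a regulariser; no structural inference (e.g.
  skeleton-constrained decoding) is performed at prediction time.
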