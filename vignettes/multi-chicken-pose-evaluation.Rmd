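---
title: "Evaluating multi-chicken pose estimation with CKS, mAP and PCK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-chicken pose estimation with CKS, mAP and PCK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpose)
```

## The problem

Automated behaviour analysis of poultry starts from posture: where each
bird's body, legs and head landmarks are in every camera frame. Modern
systems solve this *top-down*: an object detector first puts a bounding
box around each chicken, each box is cropped and resized to a fixed
input, and a pose network regresses per-keypoint heatmaps inside the
crop, whose peaks are mapped back to image coordinates. `mcpose`
implements everything around the neural networks — the data model, the
evaluation mathematics, the two-stage orchestration, and a synthetic
scene generator — so that the full pipeline and all metrics are testable
on a desk, without datasets or trained weights. Real detectors and pose
networks plug in through two closure contracts.

The animal is described by a 10-keypoint schema: `body_center`,
`body_tail`, left/right knee and heel, left/right eye, `comb` and
`beak`.

## Chicken keypoint similarity

The central quantity is the chicken keypoint similarity (CKS), an
adaptation of COCO's object keypoint similarity (OKS) to this schema.
For a ground-truth pose $B^T$ and a predicted pose $B^P$:

$$
\mathrm{CKS}(B^T, B^P) =
\frac{\sum_{i=1}^{N} \exp\!\left(-\dfrac{\lVert B_i^T - B_i^P\rVert^2}
  {2\,\alpha\,\beta_i^2}\right) v_i}{\sum_{i=1}^{N} v_i},
$$

with $N = 10$ keypoints, $v_i \in \{0, 1\}$ the ground-truth visibility,
$\alpha$ the object scale (bounding-box area in px²) and $\beta_i$ a
per-keypoint normalisation constant: $\beta = 0.107$ for `body_center`
and $0.025$ for all other keypoints. The body centre is hard to annotate
consistently, so its kernel is over four times wider (in standard
deviations, $\sqrt{\alpha}\,\beta$) than the well-localised head and leg
points. CKS is 1 exactly when all visible keypoints coincide and decays
smoothly with displacement.

Two conventions are deliberate and worth stating:

* **$\alpha$ is the ground-truth box area.** This keeps the similarity
  independent of how loose the detector's boxes are, matching OKS
  practice.
* **Only ground-truth visibility gates a keypoint.** The kernel has a
  single $v_i$; a predicted visibility flag of 0 does not remove a
  keypoint from CKS (it does remove it from keypoint-level error
  metrics, where there is no predicted coordinate worth measuring).

A ground-truth instance with *no* visible keypoint has undefined CKS; it
is excluded from matching and counted in the report diagnostics rather
than silently treated as zero.

```{r cks-example}
sch <- default_chicken_schema()
xy <- cbind(x = seq(40, 400, 40), y = seq(40, 400, 40), v = 1)
gt <- pose_instance(bounding_box(0, 0, 450, 450), xy, schema = sch)
cks(gt, gt, schema = sch)           # identical poses: exactly 1
```

## Instance matching and mAP / mAR

Detections are matched to ground truth greedily, per image, at each CKS
threshold in $\{0.50, 0.55, \ldots, 0.95\}$: predictions are processed
in descending score order; each takes the still-unmatched ground truth
with the highest CKS and is a true positive iff that CKS reaches the
threshold, otherwise a false positive that consumes no ground truth.
Ties in score are broken by input order and ties in CKS by ground-truth
input order, so matching is deterministic. This greedy rule is the COCO
convention; it is a convention choice of this package, stated
prominently because other matchers (e.g. Hungarian assignment) give
slightly different TP sets on crowded scenes.

From the pooled, score-ranked predictions the cumulative precision
$P = TP/(TP+FP)$ and recall $R = TP/(TP+FN)$ define the 101-point
interpolated average precision

$$
AP = \frac{1}{101} \sum_{\tilde r \in \{0, 0.01, \ldots, 1\}}
\max\{P \;\text{at ranks with}\; R \ge \tilde r\},
$$

with the maximum over an empty set taken as 0 and no further smoothing.
The average recall at a threshold is the maximum attainable recall with
every prediction admitted (no detection cap). mAP and mAR are unweighted
means over the ten thresholds. The recall grid is generated as
`(0:100)/100` rather than `seq(0, 1, 0.01)` so grid values such as 0.5
are exact binary fractions and comparisons like $R \ge \tilde r$ do not
wobble in the last bit.

## Keypoint-level metrics

Pixel error (PE) is the Euclidean distance between a matched
ground-truth/predicted keypoint pair; per-keypoint RMSE is the root mean
of squared PE. Pairs are formed by the same greedy assignment run
*without* a similarity threshold, so localisation error is measured for
every assigned detection, not only those above a cut — otherwise the
error table would be censored exactly where the model is worst.

Per-keypoint tables need an "average" row, and two inequivalent
aggregations are in circulation: the arithmetic mean of the per-keypoint
RMSEs and the pooled RMSE (root of the mean of all squared errors,
equivalent to weighting keypoints by their pair counts). Published
tables do not always say which rule they used, and the two differ
whenever errors are heterogeneous, so `rmse_per_keypoint()` reports
both and claims neither as canonical.

PCK (percentage of correct keypoints) counts a pair correct when its PE
is strictly below $\tau$ times a per-instance reference length. Human
pose uses the head segment (PCKh); chickens have no such convention, so
the reference is configurable with the ground-truth box diagonal and
$\tau = 0.05$ as defaults — a declared package convention, not a
community standard. The strict inequality means a distance exactly at
the threshold does not count.

## The top-down pipeline scaffold

`run_pipeline()` wires the stages together for one image: detector
closure → per-detection crop (`crop_and_resize()`, direct non-uniform
resize of the box to 512×512, the most literal "crop and adjust to the
same size"; an aspect-preserving mode is not the default) → pose
closure returning a heatmap stack → `decode_heatmaps()` →
back-projection through the inverse crop transform. The instance score
is the detection score; the systems this scaffold emulates define no
keypoint-score fusion, so none is invented. A failure in one backend
call skips that instance with a warning and the pipeline continues.

Heatmap decoding is argmax plus an optional quarter-stride shift toward
the larger axial neighbour — the standard simple-baselines refinement.
Ties in the argmax go to the lowest (row, col) in row-major order; a
flat map warns and decodes to the first cell; a peak below `vis_floor`
(default 0.05) yields visibility 0. The heatmap stride is a parameter
(default 4 crop px per cell): the resolution after a real network's
deconvolution stages varies by architecture, so it is not hard-coded.
With stride $s$ the decoding quantisation is at most $s/2$ per axis in
crop coordinates (at most $s/4$ with refinement and a symmetric peak),
which shrinks by the crop scale factor $W_{\text{crop}}/w_{\text{box}}$
when mapped back to image coordinates.

The bundled reference backends are *oracles built from ground truth*:
the detector returns the ground-truth boxes with a fixed score, and the
pose backend projects ground-truth keypoints into the crop and renders
Gaussian peaks (optionally jittered). They make the pipeline's geometry
testable end-to-end: with noise off, the round trip must reproduce
ground truth to within decoding quantisation and evaluate to mAP 1.

`compound_scaling()` is a small self-contained utility for the compound
model-scaling rule (depth $\alpha^\phi$, width $\beta^\phi$, resolution
$\gamma^\phi$ under $\alpha\beta^2\gamma^2 \approx 2$); network training
itself is out of scope.

## The synthetic scene generator

`generate_dataset()` places birds by scaling (60–120 px), rotating
(full circle) and translating a canonical 10-point body template inside
a 640 × 640 image (the working resolution of the emulated system), one
to six birds per image; the ground-truth box is the tight keypoint box
inflated by 10 % per side so degenerate poses still have positive area.
Predictions derive from ground truth through a noise model that mirrors
the failure modes reported for real top-down chicken systems: Gaussian
keypoint jitter (default σ = 2 px), keypoints dropped near recognition
limits (`p_miss_keypoint = 0.05`), left/right foot confusion
(`p_swap_lr = 0.03`, applied before jitter — the network confuses the
sides, then localises the wrong side with the usual noise), missed
detections (0.05), spurious detections (0.05 per true bird, scored from
a lower-mean distribution so ranking stays informative), box
perturbation (±2 px) and a Gaussian score model (true 0.85 ± 0.05,
spurious 0.4 ± 0.1, clipped to [0.05, 1]). The magnitudes are package
choices made once for test coverage: no published quantitative noise
rates exist for broiler keypoints, and nothing here is tuned to any
reported benchmark number.

All randomness flows from one seed through a single stream consumed in
a fixed order (images → birds within an image → prediction noise), so
datasets are reproducible to the serialized byte.

The generator supports an analytic cross-check: under jitter-only noise
the squared keypoint displacement is $\sigma^2 \chi^2_2$, so each CKS
term has expectation $v^*_i/(v^*_i + \sigma^2)$ with
$v^*_i = \alpha \beta_i^2$, and `expected_mean_cks()` returns the mean
over visible keypoints. Likewise $E[PE^2] = 2\sigma^2$, so per-keypoint
RMSE must recover $\sigma\sqrt 2$. The test suite holds the Monte-Carlo
estimates to these closed forms (3 standard errors for the CKS mean at
10⁴ draws; 5 % for RMSE at 2000 pairs per keypoint).

What the generator does **not** emulate: photorealistic appearance,
geometry-derived occlusion (visibility is sampled, not computed from
overlap), perspective foreshortening, and video correlation between
frames. Passing tests therefore certify the *evaluation mathematics and
plumbing*, not the accuracy of any real detector on real barns.

## Numerical and degenerate-input conventions

* Coordinates are continuous, 0-based, origin top-left, y downward;
  boxes are half-open `[x, x+w) × [y, y+h)` (the COCO convention the
  JSON dialect borrows).
* COCO visibility 2 ("visible") and 1 ("occluded but labeled") both map
  to 1; the mapping is idempotent.
* The CKS histogram's bins are left-closed right-open except the last,
  which is closed so a similarity of exactly 1.0 is counted.
* JSON serialisation uses a stable key order and full float precision,
  so write→read is structurally the identity and fixed inputs are
  byte-stable.
* Errors are classed conditions (`mcp_validation_error`,
  `mcp_io_error`, `mcp_undefined_metric_error`); undefined metrics
  (CKS with no visible keypoint, PCK on an empty pair set, PR with zero
  ground truth) raise rather than return a silent 0.

## Problem sizes in the test suite

The suite exercises: 1000 random instances against a brute-force CKS
oracle (tolerance 10⁻¹²), 200 random small scenes (≤ 3 ground truth,
≤ 4 predictions) against an independently coded greedy matcher and
grid-max AP oracle, 10⁴ Monte-Carlo draws for the closed-form CKS
expectation, 2000 pairs per keypoint for RMSE recovery, 50 datasets for
threshold monotonicity, 100 seeds for the counting identities, and a
10-image oracle pipeline round trip. These sizes keep the whole suite
around half a minute on one core while leaving Monte-Carlo tolerances
honest (3 standard errors, or 5 % where stated).

## Known limitations

* The greedy matcher and the PCK normalisation are declared
  conventions; numbers produced under different conventions (Hungarian
  matching, PCKh-style segments) are not directly comparable.
* Per-keypoint RMSE is conditioned on assignment: with extreme noise,
  wrong assignments leak large errors into the table — by design, since
  censoring them would flatter the model.
* The oracle backends validate geometry and plumbing only; they say
  nothing about real network accuracy.
* Bottom-up (keypoints-first) estimation and cross-frame identity
  tracking are out of scope.
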