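---
title: "Quantifying tumor microvasculature morphometry: models and methods"
author: "microvasq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor microvasculature morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvasq)
```

## The problem

Contrast-free high-definition microvasculature imaging (HDMI) visualizes
sub-millimeter vessels — down to roughly 300 µm — from high-frame-rate
ultrasound by separating slowly varying tissue "clutter" from decorrelating
blood signal, and then quantifies the *shape* of the recovered vascular
network. Malignant lesions, driven by angiogenesis, tend to grow vascular
beds that are denser, more branched, and more tortuous than those of benign
lesions, so morphometric biomarkers of the vessel skeleton carry diagnostic
information even without contrast agents.

`microvasq` implements the full analysis chain as testable components:

1. **Image formation** — SVD clutter filtering of the slow-time IQ ensemble
   on its Casorati matrix, power-Doppler integration, optional top-hat
   background equalization and multiscale Hessian (Frangi-type) vessel
   enhancement.
2. **ROI handling** — lesion masks with a 10 mm perilesional dilation
   (disk structuring element, clipped at image borders).
3. **Segmentation** — thresholding (fixed fraction or Otsu), removal of
   small objects, filling of small holes, topology-preserving thinning,
   and construction of a segment/branch-point graph with per-pixel radius
   estimates from the Euclidean distance transform.
4. **Morphometry** — the nine biomarkers: vessel density (VD), number of
   vessel segments (NV), number of branch points (NB), mean and maximum
   distance-metric tortuosity ($\tau_{mean}$, $\tau_{max}$), mean diameter
   ($D_{mean}$), box-counting fractal dimension (FD), mean Murray's-law
   deviation ($MD_{mean}$), and mean bifurcation angle ($BA_{mean}$).
5. **Group statistics** — per-group mean ± SD summaries and two-sided
   Wilcoxon rank-sum screening at $\alpha = 0.05$ (strict inequality, no
   multiplicity adjustment driving the flag; a Holm-adjusted column is
   reported alongside).

Every stage is exercised against ground truth from a synthetic
vascular-tree generator, so the package needs no external data.

## Coordinate and unit conventions

Images are matrices indexed `[row, col]` with row = axial/depth and
col = lateral. Pixel centers sit on the integer grid; physical position in
mm is `(index - 1) * pixel_size_mm`. All lengths are in mm, areas in mm²,
angles in degrees.

## The synthetic vascular tree generator

`generate_vessel_tree()` grows a strictly binary tree: each segment is a
straight chord plus a windowed sinusoidal transverse perturbation
$a\,\sin(2\pi c t)\,\sin^2(\pi t)$, whose value *and slope* vanish at both
segment ends. That windowing is deliberate: it makes the true tangent at a
bifurcation equal to the chord direction, so the generator's recorded
opening angle is exactly the geometric quantity the angle estimator is
asked to recover. Daughter diameters obey the generalized Murray relation
$d_p^k = d_1^k + d_2^k$ exactly before optional multiplicative noise.

A two-dimensional random binary tree self-intersects with high
probability, which would make rasterized topology differ from generated
topology through no fault of the skeleton stage. The generator therefore
rejection-samples each daughter pair (up to 40 attempts) against an
obstacle cloud of previously laid segments, requiring a wall-to-wall
clearance of 4.5 px; the field-of-view border is treated as an obstacle so
geometry is never clipped. When no clear geometry exists, a daughter is
truncated just before its first collision (minimum 1.5 mm, the shortest
segment that still thins to a recoverable spur); if even that is
impossible the bifurcation is abandoned and the parent terminates. A
daughter shorter than 1.8 mm does not branch further, because a junction
within ~one vessel diameter of another merges into a single branch-pixel
cluster after thinning. Ground truth always records the topology and
chords actually generated, so `NV = 2 NB + 1` holds for every single-root
tree.

Default geometry (root diameter 1.2 mm, segment length 4 ± 0.6 mm,
opening angle 70 ± 8°, tortuosity amplitude 0.3 mm, 0.1 mm pixels on a
19.2 mm field of view) keeps every vessel at or above 6 px diameter — the
regime in which counts are recovered exactly.

The slow-time simulator (`simulate_iq_ensemble()`) composes (i) tissue
clutter as a rank-limited sum of smooth spatial fields times slowly
drifting unit-modulus temporal envelopes, (ii) blood as a per-pixel
complex AR(1) process (coefficient 0.3, short coherence) confined to the
vessel mask, and (iii) white complex noise, with analytically set power
ratios. The clutter's Casorati matrix is exactly rank `clutter_rank`,
which is what makes the SVD filter's behavior provable: the residual
clutter after removing the leading singular component scales like
$1/n_{frames}$ (subspace-estimation error from the blood+noise
interference), reaching about −23 dB for a 40 dB rank-1 clutter at 400
frames. Short ensembles of a few dozen frames cannot reach −20 dB no
matter the filter; the package's efficacy checks therefore use a few
hundred frames, well within a multi-second acquisition at ultrafast frame
rates.

Cohort emulation (`generate_cohort()`) has two modes. Image-level mode
draws per-lesion trees whose parameters differ by group — malignant-like
lesions get two roots, depth-3 branching, larger tortuosity amplitude and
a wider, larger opening-angle distribution — so NV, NB, tortuosity, FD and
BA are stochastically larger in the malignant group, mirroring the
reported effect directions. Metric-level mode draws each biomarker from a
log-normal matched to published group means/SDs for benign (n = 10) and
malignant (n = 19) hepatic lesions (`reference_group_moments()`);
biomarkers with a hard floor of 1 (tortuosity, FD) are drawn as
1 + log-normal on the excess so records never violate their invariants.

## Numerical choices in segmentation and morphometry

**Thinning.** Zhang–Suen parallel thinning is followed by a sequential
pass deleting 8-simple points (Yokoi connectivity number = 1, endpoints
kept). The parallel algorithm alone leaves two-pixel diagonal staircases;
those chain into spurious wide "branch clusters" when skeleton pixels are
classified by neighbor count. The sequential pass reduces them to minimal
one-pixel chains without changing topology.

**Graph construction.** Skeleton pixels with one 8-neighbor are endpoints
and those with three or more are branch candidates; adjacent candidates
merge into a single node at their centroid (thinning produces branch-pixel
clusters that would otherwise inflate NB). Spur edges shorter than
`min_segment_mm` (default 0.3 mm, the resolution floor of the method) are
pruned; junction-scale self-loops (shorter than $\pi \times$ the local
diameter) are removed as thinning artifacts; nodes left with degree 2 are
dissolved and their edges merged. Segment length and chord are measured on
a lightly smoothed path (5-px moving average, ends fixed) running from
node centroid to node centroid, which removes most of the staircase bias
of 8-connected chain lengths; total skeleton length then tracks
ground-truth centerline length within 5%.

**Diameters.** Per-segment diameter is the junction-trimmed mean of twice
the distance-transform radius along the segment (pixels inside the
junction ball at either end are excluded), minus 0.1 px — the empirically
measured mean overshoot of the grid distance transform at a rasterized
boundary. Rasterization quantizes each tube's width to roughly ±0.5 px,
which puts a floor on diameter accuracy: Murray's deviation, a cube-law
quantity, inherits three times the relative error. $MD_{mean} < 0.05$ on
Murray-compliant trees is therefore a *well-resolved-vessel* property
(daughters ≥ ~15 px); the package's checks run that case at 0.05 mm
pixels and report the seed-averaged value.

**Bifurcation angles.** The default convention is the whole-segment
direction: the principal axis of the daughter's skeleton path beyond the
junction ball. Two alternatives were evaluated and rejected as defaults.
A straight-line fit over the first 1 mm of the path is biased 10–30°
upward, because the skeleton inside the junction blob (radius ≈ parent
radius, extending $r/\sin(\theta/2)$ along each daughter) traces thinning
geometry rather than the vessel, and because tortuous daughters curve
within the window. A quadratic-in-arc-length fit starting beyond the
junction ball (available by setting a finite `tangent_window_mm`) removes
the junction bias but keeps ±5–10° noise per bifurcation on tortuous
vessels. The whole-segment convention recovers a clean symmetric Y to
within ~1° and matches the ground-truth mean angle of tortuous trees to
within ~1–2° across seeds.

**Fractal dimension.** Box counting over dyadic sizes anchored at the
foreground bounding box; FD is minus the least-squares slope of
log N(s) versus log s, excluding the single-pixel and whole-image sizes,
which are dominated by pixelation and saturation respectively. A straight
line, a filled square and an order-7 Sierpinski triangle land on 1, 2 and
log 3 / log 2 to within the stated tolerances.

**Otsu thresholding.** The between-class-variance criterion is flat
across an empty gap between modes, so any threshold in the gap is a valid
maximizer; comparisons against an exhaustive search are made on the
achieved criterion value, not the arg max.

## Statistics

`wilcoxon_rank_sum()` enumerates all $\binom{m+n}{m}$ assignments of the
pooled midranks when $m + n \le 20$ (two-sided p = twice the smaller tail,
capped at 1). The approximate mode is a normal approximation with
continuity correction *plus an Edgeworth kurtosis term*: because the rank
sum is the total of an m-subset drawn without replacement from the
midrank population, its exact variance and fourth central moment follow
from finite-population sampling formulas (valid under ties). The plain
continuity-corrected normal — what most software uses — deviates from the
exact test by up to 0.0375 at $m, n \le 7$; the Edgeworth correction
brings that below 0.02. Under null cohorts at the 10 vs 19 study size the
per-metric flag rate at $\alpha = 0.05$ stays inside the exact binomial
99% interval.

The SVD "filter twice equals filter once" intuition deserves a caveat:
re-estimating the subspace on already-filtered data removes the *next*
singular components, so the literal function composition is not
idempotent. What holds — and what the tests assert — is the projection
property: the filtered ensemble has zero energy in the removed subspace
of the input's SVD.

## What the simulations do and do not establish

The generator produces piecewise-smooth planar trees with constant
per-segment diameter, stationary background noise, and (in the ensemble
simulator) exactly rank-limited clutter. Real liver HDMI data adds
depth-dependent attenuation, speckle, respiratory and cardiac motion,
out-of-plane vessels, and clutter of ambiguous rank. Passing tests
therefore certify the *measurement chain* — that the estimators recover
known geometry and that the statistics are calibrated — not clinical
performance. The published patient-level group separations cannot be
reproduced from first principles without the raw ultrasound data, which
is not publicly deposited; the cohort generator instead emulates the
reported effect directions and group moments so that the screening
machinery can be exercised at the real study size (10 benign vs 19
malignant). With the default image-level cohort parameters the group
separation is stronger than in the patient data (NV, NB and
$\tau_{max}$ are flagged in essentially every replicate); this is a
property of the chosen simulation parameters, not a claim about clinical
effect sizes.

Problem sizes used by the packaged checks: 192² px images at 0.1 mm
(cohorts), 96² px ensembles of 400 frames (clutter filtering), 50 cohort
replicates for the power study, 1000 replicates for null calibration.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(seed = 42))
res <- run_pipeline(co, pipeline_config(dilation_mm = 0))
res$stats[, c("metric", "mean_a", "mean_b", "p", "significant")]
```

The `stats` table has one row per biomarker with benign and malignant
mean ± SD, the two-sided rank-sum p-value, and the significance flag.
A full-FOV mask is used for simulated lesions (the entire image is the
analysis region), so `dilation_mm = 0`; for real masks the default 10 mm
perilesional dilation applies.

## Known limitations

- Strictly 2-D; no out-of-plane geometry, no 3-D skeletonization.
- Diameter accuracy is floor-limited by rasterization (±0.5 px per
  segment); cube-law quantities amplify this threefold.
- Per-bifurcation angle estimates on tortuous vessels carry ±5–10° noise;
  only the lesion-level mean is a stable biomarker.
- The clutter and blood signal models are deliberately simple stand-ins
  chosen for provability, not acoustic realism.
- Exact rank-sum enumeration is limited to $m + n \le 20$; beyond that the
  Edgeworth-corrected approximation is used.
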