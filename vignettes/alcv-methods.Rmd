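---
title: "Methods: quantifying anterior lens capsule vascularity and predicting gestational age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying anterior lens capsule vascularity and predicting gestational age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcv)
```

## The measurement problem

The fetal lens is wrapped in a transient capillary net that regresses on a
predictable schedule between about 27 and 35 weeks of gestation. Under
retroillumination the surviving vessels show as dark branches against the
bright red pupil reflex, so a photograph of a preterm infant's eye carries a
readable developmental clock. This package implements the full measurement
chain — pupil extraction, vessel segmentation, branch morphometry, and a
linear gestational-age (GA) model over the resulting biomarkers — together
with a synthetic scene generator that makes every stage verifiable against
analytic ground truth.

Two global conventions apply throughout: images are `rows x cols x 3` arrays
in `[0, 255]` indexed 1-based as `(row, col)` (the R convention), and all
biomarkers are in pixels and percent unless the optional pupil-radius
normalization is switched on (`normalize_by_pupil`).

## Pupil detection

`hough_circle_candidates()` votes for circle centers by correlating a Sobel
edge map with ring templates (FFT cross-correlation), over a radius grid
covering 10–45% of the short image side by default — the pupil occupies only
a fraction of a handheld ophthalmoscope frame. The accumulator response of a
candidate is the fraction of its circumference supported by strong edges;
candidates below `accumulator_floor = 0.3` are discarded, and the edge
threshold keys off the 99th gradient percentile rather than the maximum so a
single specular highlight cannot mask the pupil rim. Mildly elliptical
pupils are handled by the refinement stage rather than an explicit ellipse
transform; the one-parameter circle family plus a color-driven boundary
refinement recovers small eccentricities at far lower cost.

Candidates are ranked by a weighted vote (`score_candidates()`) over three
per-frame min–max normalized scores: interior/annulus gray contrast,
circularity (fraction of boundary samples on gradient ridges), and redness
`(R - max(G, B))/255` of the interior, which targets the red reflex
specifically. The weights default to equal thirds — nothing in the source
material constrains them — and ties break lexicographically on
(score, row, col, radius) so detection is deterministic.

`refine_pupil_mask()` thresholds redness and HSV saturation/value inside the
candidate disk dilated by 15%, keeps the largest 8-connected component,
closes and hole-fills it. The redness threshold adapts to the frame (half
the median redness of the disk interior, floored at 10 intensity units):
an absolute threshold misclassifies dimly reddish iris surrounds. If the
refined component covers less than half the candidate disk the raw disk is
used and the region is flagged — downstream code can treat flagged masks
with suspicion, mirroring the semiautomated workflow's human checkpoint.

## Vessel segmentation

Inside the pupil, the red and green channels (the blue channel carries
almost no vessel contrast under retroillumination and is ignored) are
linearly stretched between their 2nd and 98th percentiles computed **within
the pupil mask only** — global percentiles would be dominated by the dark
surround. The stretched channels are averaged and inverted: vesselness is
high where the image is dark. The pupil mask is first eroded by 3 px
(`boundary_erosion_px`): the blurred dark rim at the pupil boundary
otherwise segments as a ring of false vessels.

`hysteresis_segment()` applies two-threshold segmentation: seeds at
vesselness ≥ `high` (default 0.55), grown through 8-connected pixels ≥
`low` (default 0.25), with components under `min_object_px = 20` removed.
The defaults are package choices, exposed both programmatically and through
`tune_segmentation()`, which re-runs segmentation with partial overrides and
records `params_used` so any mask is reproducible from (image, pupil,
parameters) — the audit trail for the manual-verification step. Hysteresis
masks are monotone in both thresholds (lower thresholds give supersets),
which the tests exploit as a property check alongside exact equality with a
brute-force threshold-and-flood-fill oracle.

## Morphometry conventions

The binary vasculature is thinned to a 1-px skeleton (Zhang–Suen), followed
by two cleanups that matter in practice: removal of redundant pixels whose
neighbors are already mutually 8-connected (thinning leaves staircase
doublings and 1-px nubs at curve extrema, which otherwise masquerade as
junctions), and folding of junction-to-junction chains shorter than
`prune_len` into a single junction node (thinning splits thick junctions).
Terminal spurs shorter than `prune_len = 5` px are pruned iteratively.
Branches are traced node-to-node deterministically (row-major order,
smallest-index continuation), and every skeleton pixel is accounted to
exactly one branch — junction-interior pixels go to the first branch that
touches them.

Three rasterization conventions were calibrated against rendered strokes of
known geometry; each is a measurement-accuracy decision, not a tuning knob:

- **Length.** The raw 4/8-step chain length overestimates oblique digital
  curves by up to ~10% (staircase aliasing; +8.6% measured at 10°). Branch
  length is therefore the Euclidean length of the centerline subsampled
  every 3 px — negligible bias at vessel-scale curvature — plus an end-cap
  extension of the local inscribed radius at free ends, compensating the
  centerline retraction that thinning causes there. The raw step rule is
  still used for pruning decisions, where only the scale matters.
- **Width.** The width at a path pixel is `2*EDT - 0.5`, where EDT is the
  exact Euclidean distance transform of the mask. `2*EDT` alone reads
  `w + 1` on axis-aligned strokes (background pixel centers sit half a pixel
  beyond the band edge) but `w` on oblique ones; −0.5 is the
  orientation-marginal correction, bounding the error by ~0.6 px across
  widths 2–8 px. Pixels whose inscribed disk still touches a junction's
  inscribed disk are excluded from the profile mean.
- **Tortuosity.** Box counting over box sizes {2, 4, 8, 16, 32} px (sizes
  above half the bounding-box extent dropped, at least three required),
  least-squares slope of log(count) against log(1/size), clamped to [1, 2].
  Branches spanning under 8 px return the straight-line sentinel 1.0 —
  a log–log fit over one or two scales is meaningless. Coarse box counting
  is a *relative* tortuosity index: it is exactly 1 for straight branches
  and increases with sinuosity, but it is not strictly monotone in
  amplitude at every geometry, and the ordering tests use a fixed chord and
  cycle count for that reason.

"Width" versus "thickness": the published final model names both, without
definitions. The package computes both candidates — the distance-transform
width above (`branch_width_*`) and the chord-perpendicular extent of the
centerline plus stroke width (`branch_extent_*`) — and the shipped
coefficient file declares the mapping (thickness → distance-transform
width, width → perpendicular extent). The mapping is data in the
coefficients JSON, validated at load, so either reading of the published
table can be swapped in without code changes.

Session aggregation is the arithmetic mean of per-video biomarkers,
including the extrema (the session `branch_length_max` is the mean of
per-video maxima, not the maximum of maxima) — matching how repeated videos
of one imaging session were averaged in the source workflow.

## The GA model

`predict_ga()` is a plain affine form over the mapped biomarkers with the
shipped intercept 34.406 weeks. Nothing is clamped; predictions outside
27–37 weeks trigger a warning, since the vasculature carries no signal
outside its regression window. An important caveat is shipped with the
coefficients: the feature-unit convention (pixels/percent, at what
resolution) behind the published values was never stated, so predictions
with the default file are unit-convention dependent. Refitting on local
data (`fit_mixed_model()`) and dropping the resulting coefficients into a
new JSON file is the supported path.

The mixed model is a Gaussian random-intercept-per-subject model fit
natively: for any variance ratio λ = σ²(subject)/σ²(residual) the GLS fixed
effects have a closed form via per-group rank-one updates, and the profiled
log-likelihood is maximized over log λ by 1-D optimization (with the λ = 0
boundary checked explicitly). ML is the default so AIC/BIC comparisons
across fixed-effect sets remain valid; REML is a switch. The implementation
reproduces `lme4` point estimates, standard errors and log-likelihoods to
numerical precision on simulated cohorts — the test suite asserts this
against `lme4` as an independent oracle. `variance_inflation()` provides
the usual 1/(1−R²) screening with an `Inf` sentinel for exact collinearity.

Bland–Altman agreement (`bland_altman()`) reports bias, SD of differences,
bias ± 1.96 SD limits, Pearson r, and the fraction of sessions within ±1
and ±2 weeks. The Hittner staging (`hittner_grade_range()`) returns the
printed two-week ranges; because those ranges leave one-week gaps, the
inverse classifier uses contiguous half-open bins IV [27, 29), III [29, 31),
II [31, 33), I [33, 35) — a package convention, chosen so each printed
range's midpoint classifies back to its own grade.

## The synthetic world, and what a green test establishes

`render_scene()` draws: background, a pupil reflex disk (default reddish
(200, 70, 60) on a darker iris (70, 45, 45)), dark vessels ((60, 18, 18))
as disks of diameter `width` stamped along sub-pixel paths at ≤ 0.5 px
spacing, bright elliptical specular blobs and thin bright streaks (mucus
mimics, never labeled as vessels in ground truth), then Gaussian blur,
additive Gaussian channel noise, and clipping. The seed fully determines
the image, and ground truth (masks, analytic branch lengths and widths,
density) is computed before degradation.

`simulate_cohort()` draws biomarkers from independent normals at realistic
pixel scales for a ~160 px pupil (e.g. maximal branch length 60 ± 15 px,
density 8 ± 3%), and generates `ultrasound_ga` from the declared linear
predictor plus a subject intercept (default SD 1.5 weeks) and residual
(0.7 weeks). Defaults mirror the pilot-study scale: 24 subjects, 3 sessions.

What the generator does **not** emulate: corneal clouding, eyelid
occlusion beyond a test-only "bite", motion blur anisotropy, compression
artifacts, inter-operator variability, or the correlation structure of real
repeated biomarkers (features are drawn independently across sessions). A
green recovery test therefore establishes that the algorithms are correct
on images satisfying the stated model — dark vessels on a bright reflex
with Gaussian degradations — not that the pipeline is clinically validated.
The published clinical agreement figures (r = 0.78, 86% within ±2 weeks)
require the original patient videos and are out of reach of this artifact
by design.

## Numerical and design choices worth knowing

- Determinism everywhere: no stage of detection/quantification uses RNG;
  seeded generators save and restore the caller's RNG state; candidate and
  frame rankings have declared tie-breaks. Two runs over the same inputs
  produce byte-identical CSV/JSON.
- Degenerate inputs are contracts, not crashes: a constant pupil interior
  yields an all-zero, flagged vesselness map; an empty vessel mask yields an
  empty branch set and zero density; a session with no detectable pupil
  yields a QC-flagged record (`insufficient retroillumination`) and CLI
  exit code 2, distinct from crashes (1).
- Row duplication in the mixed model is *not* a no-op under profiled ML —
  it is exactly equivalent to doubling the variance ratio, which the tests
  assert in that form.
- The 2·SE fixed-effect recovery study in the acceptance suite sits at the
  edge of its own Monte-Carlo noise: true per-term coverage of plug-in Wald
  intervals at 24 subjects is ~0.93–0.97 (above the 90% requirement in
  expectation), and one term lands at 89/100 in the pre-committed seed
  batch. The test is kept faithful rather than re-seeded; the failure
  message carries the per-term counts.
- Frame quality ranking multiplies the pupil vote by the variance of the
  gradient magnitude inside the detected pupil (min–max normalized per
  video) — focus information exists only in the pupil region, since the
  surrounding face is out of the retroillumination focal plane.
- `extract_frames()` reads a directory of stills as "the video" (0-based
  frame indices); no codec is bundled, and MP4/MOV inputs error with an
  explicit message rather than being mis-parsed.
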