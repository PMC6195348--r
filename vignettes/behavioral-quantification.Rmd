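---
title: "Quantifying behavioral endophenotypes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral endophenotypes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpheno)
```

`cbpheno` implements the quantitative machinery of a mouse behavioral-
phenotyping study built around regional cerebellar chemogenetics: raw-signal
processing (arena video tracking, eyelid traces, paw placements, spike
trains), a fixed panel of behavioral metrics across four assays, a
control-space PCA ("eigenbehavior") analysis, permutation-based correlation
networks, and linear models relating per-lobule reporter-expression dosage
to behavior. Because this class of experiment rarely ships raw data, the
package includes a first-class synthetic-data module that generates every
input with planted ground truth; all claims the test suite makes are claims
about recovery of that ground truth.

## Video tracking

The tracker follows the classic background-subtraction recipe. A background
image is the Gaussian-filtered pixel-wise mean of a mouse-free segment
recorded before the animal is inserted (a 5 s segment at 50 frames/s is the
convention the generator reproduces: 185 frames). For each frame the
absolute difference between the Gaussian-filtered frame and the background
is thresholded at a user-chosen value; connected regions of the binary
image are extracted and the largest-area surviving region's centroid is the
animal position. Region extraction uses connected-component labelling
(`EBImage::bwlabel`): the largest connected region of the thresholded
difference image has the same outline a contour-following edge detector
would trace around it, and its centroid is the natural reading of a
contour's "center" (bounding-box centers behave badly for elongated
animals).

Three exclusion rules run *before* largest-area selection: a candidate is
discarded if its center is more than `jump_limit` (default 100 px) from the
previous position, if it lies outside the arena bounds, or if it falls
inside a user-declared exclusion area. Filtering before selection is what
lets the jump rule protect the track when a reflection or a second bright
object is momentarily the largest blob. When no candidate survives, the
animal is inferred to be at its most recent detected location and the frame
is flagged `inferred`; before the first detection the jump rule is
suspended (there is no previous position) and positions are `undefined`.
Ties between equal-area candidates go to the one nearest the previous
position. Defaults the protocol leaves open: Gaussian sigma 2 px; a
minimum-area floor of 5 px to suppress single-pixel noise.

Zone analytics are frame counting: time in a zone is occupancy frames over
frame rate, an entrance is a transition of the zone label into the zone,
distance is the sum of consecutive-position Euclidean steps over the pixel
scale. Elevated plus-maze entries are split into *full* and *jittery* by a
penetration-depth criterion: a centroid tracker cannot see torso
stretching, so an arm visit that never reaches `full_depth_cm` (default
4 cm) into the arm counts as jittery. Near-cup interaction in the
three-chamber task is scored inside an annulus of the cup radius plus a
2 cm margin; the boundary is not quantified by the protocol, so both are
configurable.

## Behavioral metrics

The 19-metric panel is implemented exactly as printed: ratios
(open-arm preference, commitment, social preference), normalized
differences (novelty-seeking, grooming ratio), session means and endpoints,
and least-squares slopes over the first three sessions of an acquisition or
reversal day. Two points deserve note. Novelty-seeking is implemented with
the printed sign — baseline minus test over baseline — although that makes
*larger* values mean *less* test-phase activity; a `negate_novelty` flag is
provided for the intuitive orientation. Grooming events shorter than one
second are excluded *strictly* (an exactly 1.0 s bout survives), and the
grooming ratio is undefined (missing) when the saline-condition mean bout
is zero. Missing metric values propagate as `NA`; the correlation network
uses pairwise-complete observations, while each task's PCA drops mice
missing any metric of that task's subset (a PCA basis cannot be fitted
around holes without imputation, which we deliberately avoid).

## Eyeblink scoring

Traces are normalized per session: full eye closure is the mean
peak-above-baseline of the US-only trials (the mean, not the max, so one
large reflex does not set the scale), and each trial's baseline is the mean
of the 200 ms before CS onset (first 200 ms of the trial for US-only
trials; the protocol does not state the window). A conditioned response is
a normalized deflection exceeding 0.15 of full closure anywhere in the
window 100-280 ms after CS onset; the window is treated half-open,
`(CS+100, CS+280]`, an arbitrary but fixed boundary convention. Response
probability is CRs over counted (paired + CS-only) trials. Spike-train
summaries are firing frequency `(N-1)/(t_N - t_1)` and the standard local
CV2, `mean(2|ISI[i+1]-ISI[i]| / (ISI[i+1]+ISI[i]))`, which is 0 for regular
firing, near 1 for Poisson firing, and below 2 always.

## Gait

Stride is the mean distance between successive placements of the same paw.
Stance is the mean left-right separation of a girdle's step-paired
placements projected perpendicular to the travel direction (the principal
axis of all placements). The source protocol is internally inconsistent
here — its figure legend says stance was measured *along* the direction of
locomotion while its methods define it as the left-right paw distance — and
we adopt the conventional stance *width* (perpendicular projection), which
matches the left-right definition. Because the gait cycle staggers left and
right placements along the travel axis, the principal axis tilts slightly
toward the stagger; at realistic stride/stance ratios this biases stance by
about 1%, which the tests absorb in their tolerances. Left/right pairing is
by step index after trimming to the common length, flagged when trimming
occurred.

## Eigenbehaviors

Each task's metrics are z-scored to the *control* group's mean and SD, and
PCA (SVD of the centered, z-scored control matrix) is fitted on controls
only. The resulting components — "eigenbehaviors", linear combinations of
behavioral metrics — form the basis onto which every group, control or
perturbed, is projected after the same control-referenced normalization.
Loadings are sign-fixed (largest-magnitude loading positive) for
reproducible reporting; all downstream selection criteria use absolute mean
differences, so the convention is immaterial. A component is
*high-contribution* for a group when all three criteria hold: absolute mean
score difference from controls at least 0.01 (in component-score units, the
units of the control-normalized data — the protocol does not state units,
and score units are the only scale on which the companion 10%-variance
criterion also lives), group variance fraction on that component at least
10%, and a two-sample two-tailed t-test (Welch) below 0.05.

Group comparisons further include the two-sample Kolmogorov-Smirnov test
(`stats::ks.test`, exact where feasible), a variance-ratio F test with a
two-sided p from the F distribution, and Cohen's d with the pooled SD at
`n_A + n_B - 2` degrees of freedom.

The correlation network computes Spearman's rho for every metric pair on
pairwise-complete observations. P-values come from the permutation
distribution: exhaustive enumeration of all `n!` rank orders up to `n = 9`,
Monte-Carlo with at least `1e5` seeded draws beyond that (with the
`(1+k)/(1+B)` estimator). Because rank marginals are fixed under
permutation, the null statistic reduces to rank cross-products, making
exhaustive enumeration cheap. A t-approximation variant is provided
(`spearman_ttest`) since both appear in practice; permutation is the
default. Pairs with fewer than four complete observations or a constant
metric are skipped and reported, not silently dropped.

## Expression dosage

Expression volumes are binary labeled-voxel arrays over four disjoint
lobule masks (lobule VI, lobule VII, crus I, crus II) on a common isotropic
grid — registration is out of scope, inputs arrive registered; the
conventional reference grid is 25 um isotropic. Per-lobule dosage is the
fraction of the lobule's voxels carrying label; mice are classified by the
majority lobule (ties broken by fixed lobule order and flagged). The
mediolateral profile reduction is max-projection along the
anterior-posterior axis followed by the dorsoventral mean at each
mediolateral coordinate, with optional ROI masking first.

Dosage models are one OLS fit per behavioral metric: metric value against
the four lobule fractions plus intercept, injected mice only (controls have
no expression and are excluded by construction), fitted separately per
cohort (juvenile-perturbed and adult-perturbed; pooling across cohorts is
deliberately not done since the two perturbation regimes differ in kind).
The three discrete Y-maze metrics (final learning, initial reversal 2,
final reversal 2) are excluded by default as non-continuous. The reported
quantity per lobule is the normalized weight, coefficient over its standard
error, from the standard OLS covariance estimator with `n - 5` residual
degrees of freedom. Rank-deficient designs fail loudly, naming the
collinear lobule columns. Relative neocortical tracing expression divides
each region's GFP-positive section count by the motor-cortex count, so the
reference region is identically 1.

## The synthetic-data module

The generators define the study conditions under which everything is
tested:

* **Video**: 50 frames/s; frames rendered at 120 x 160 px (a quarter-scale
  scene that keeps full test-suite tracking runs fast while leaving blob
  geometry, noise and the 100 px jump limit meaningful); a dark background
  at level 0.08 with additive Gaussian pixel noise (SD 0.02) and an
  anisotropic Gaussian animal blob (sigma 5 x 3.5 px, amplitude 0.8),
  quantized to 8 bits so PNG round trips are lossless. Distractor blobs and
  dropout frames default to rate 0. The trajectory model is a reflected
  autoregressive velocity process.
* **Eyeblink**: exactly 200 paired, 20 CS-only and 10 US-only trials per
  session in randomized order; 500 ms CS, 30 ms US co-terminating with the
  CS; alpha-function CR and UR transients; amplitudes expressed in
  fraction-of-full-UR units so the 0.15 criterion is directly exercisable;
  trace noise SD 0.02 in those units.
* **Metric tables**: multivariate normal with per-metric means and SDs on
  realistic scales and a block correlation structure whose dominant block
  ties the distance/movement metrics together (correlation 0.8) — this is
  what makes the fitted control PC1 a "distance" component, matching the
  qualitative structure the eigenbehavior analysis assumes. A smaller
  learning block at 0.5 links the reversal-learning slopes. Mean shifts,
  raw-unit shifts and variance inflation can be planted per group.
* **Expression cohorts**: targeted-lobule fraction from a truncated normal
  with mean 0.21, SD 0.12, spillover into one neighbor at mean 0.11,
  SD 0.11 (the reported injection-fill statistics), traces near zero
  elsewhere; metric values from the planted linear forward model plus
  Gaussian noise.
* **Walker, grooming, spikes**: stride/stance walker with placement jitter;
  sequential non-overlapping grooming bouts with a configurable sub-second
  fraction; Poisson, regular or gamma-renewal spike trains.

Every generator is bit-reproducible under its seed and restores the
caller's RNG state. What the generators do *not* emulate: photorealistic
appearance, multi-animal scenes, camera distortion, movement artifacts in
eyelid traces, non-Gaussian metric distributions, or spatially structured
injection shapes. Passing tests therefore demonstrate that the algorithms
are correct inverse maps for their idealized forward models — not that the
tracker would survive arbitrary real-world video.

## Numerical and calibration choices

* Sizes used by the self-calibration tests are chosen for statistical
  validity at desk scale: the component-selection power check runs 200
  seeds at 12 mice per group with 10 metrics; planted shifts are expressed
  in component-score SD units (3 SDs), the scale on which t-test power is
  well defined. Null false-selection rates are checked per component with
  an exact binomial test against the nominal 5% t-test size, rather than a
  hard threshold on the Monte-Carlo estimate, which would reject a
  correctly calibrated procedure half the time.
* The KS p-value uniformity check uses group sizes 37 and 41: the
  two-sample D statistic is lattice-valued and equal group sizes make the
  p-value distribution visibly discrete; coprime sizes refine the lattice
  enough for a KS-against-uniform check at 1000 replicates.
* The dosage-noise level used in calibration (metric noise SD 0.45 with the
  default planted weights) puts model fit near R^2 = 0.5 at 20 mice. Note
  that with 20 mice and 5 parameters a planted-zero lobule's normalized
  weight is exactly t-distributed with 15 df, so |coef/SE| stays below 2 in
  93.6% of fits — not 95%; a Gaussian intuition overstates the rate. The
  package reports the honest t behavior.
* Degenerate inputs fail loudly and by name: zero-variance metrics in the
  control PCA, empty lobule masks, rank-deficient dosage designs, missing
  US-only calibration trials, zero reference counts.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)

## track a synthetic session and compute zone metrics
traj <- synth_trajectory(cfg, n_frames = 500)
vid <- synth_arena_video(cfg, traj)
tracked <- track_video(vid, params = tracker_params(threshold = 0.25))
occ <- occupancy_and_entrances(tracked, vid$arena)

## score an eyeblink session
sb <- synth_eyeblink_session(cfg)
response_probability(sb$session)

## eigenbehavior analysis of a perturbed cohort
m <- synth_metric_groups(cfg, groups = list(
  lobule_vi = list(n = 10, shift = c("YM_Multisession Reversal 1" = -1.5))))
space <- fit_control_space(m[m$group == "control", ])
proj <- project_group(m[m$group == "lobule_vi", ], space)
high_contribution_pcs(proj,
                      project_group(m[m$group == "control", ], space)$scores)

## dosage models on an expression cohort
cohort <- synth_expression_cohort(cfg, n_mice = 20, noise_sd = 0.45)
fit_dosage_models(cohort$metrics, cohort$fractions, exclude = character(0))
```

## Known limitations

* The tracker maintains a single identity; multi-animal scenes and pose
  estimation are out of scope.
* Y-maze first-choice scoring from trajectories is a convenience reading of
  the zone sequence; the primary input is scored per-session percent
  correct.
* Exhaustive permutation enumeration is limited to n = 9 (362,880 orders);
  beyond that the Monte-Carlo p has sampling error of order
  `sqrt(p(1-p)/1e5)`.
* The dosage models are linear by design; conflicting or nonlinear
  lobule effects fold into the residual.
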