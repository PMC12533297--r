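---
title: "Methods: lymph-node morphology, topology and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lymph-node morphology, topology and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmts)
```

## The model

The lymph-node system draining a rectal tumor carries prognostic
information in two aggregate quantities that `lnmts` extracts from an
instance-labeled 3D MRI segmentation mask (background 0, tumor 1, each
node its own label ≥ 2):

**Total node volume (tLNV, mm³).** Each node's volume is approximated
from its pixel count, $V \approx N \times p$, where $p$ is the
in-plane pixel area (row spacing × column spacing, mm²), and the
patient total is $V_\mathrm{total} = \sum_i V_i$ over the $N_V$ nodes.

**Total drainage distance (tLND, mm).** Each node's distance to the
tumor is the Euclidean distance between the two structure centroids,
$D = \sqrt{(x_2-x_1)^2 + (y_2-y_1)^2 + z^2_\Delta}$, where the
in-plane terms are centroid differences in mm and the through-plane
term accounts for the acquisition geometry of a stack of slices with
thickness $T$ and inter-slice gap $G$: for a separation of
$\Delta S$ slices,
$z_\Delta = \Delta S \cdot G + (\Delta S - 1)\cdot T$.
The patient total is $D_\mathrm{total} = \sum_i D_i$.

Dichotomizing both totals at survival-optimal cutoffs yields the
three-tier risk model: large volume (L-tLNV) with distant drainage
(D-tLND) is low risk (LRS), small volume with near drainage is high
risk (HRS), and the two mixed combinations are moderate risk (MRS).
The biological reading is that a voluminous, widely distributed nodal
system reflects an active regional immune response.

## Feature-extraction choices

Several aspects of the quantities above are underdetermined and had to
be fixed once; each is surfaced in the package output so numbers stay
interpretable.

* **Pixel-counting mode.** The verbal definition of $N$ admits two
  readings: the count in the node's maximal cross-section, or the
  count accumulated over all slices. The default is **accumulated**
  (`mode = "accumulated"`), because the operational description is an
  accumulation over labeled areas; `"max_cross_section"` is kept as an
  explicit alternative, and `"voxel_volume"` ($N \times p \times
  (T+G)$) gives a dimensionally true volume. Note that $N \times p$
  has units mm² even though the quantity is conventionally labeled
  mm³; the mode used is recorded in every output row.
* **Same-slice pairs.** Read literally, the through-plane expression
  gives $(-T)^2 = T^2$ for $\Delta S = 0$, i.e. a nonzero
  through-plane distance for structures on the *same* slice, which
  contradicts the 3D-coordinate definition it specializes
  ($z_2 = z_1 \Rightarrow 0$). The package therefore sets the
  through-plane term to 0 when $\Delta S = 0$ and applies the printed
  rule only for $\Delta S \ge 1$. This is the one deviation by
  necessity, and every pipeline run logs it.
* **The printed rule is not "corrected".** The conventional
  center-to-center distance of $\Delta S$ slices would be
  $\Delta S (T+G)$; the implemented $z_\Delta$ differs from it by
  $T$. The package implements the rule as stated and tests it against
  its own hand evaluation ($\Delta S = 2$, $G = 1$, $T = 4$, in-plane
  (3,4) mm ⇒ $D = \sqrt{61}$).
* **$\Delta S$** is the absolute difference of the two centroid slice
  indices, each rounded to the nearest integer (half away from zero),
  making it integral as a count of sections.
* **Tumor reference point** is the 3D centroid of the whole tumor
  mask; "tumor center" admits no finer definition from the available
  description.
* **Gap semantics.** $G$ is taken as edge-to-edge spacing, so the
  center-to-center slice pitch is $T + G$; whether the source meant
  edge-to-edge or pitch-minus-thickness is not decidable from the
  printed formula, and this reading is the one that makes
  $T + G$ the natural voxel height.
* **Node size classes.** Individual nodes are annotated L-LN vs S-LN
  at a 5 mm (0.5 cm) equivalent diameter — the diameter of the circle
  with the node's maximal cross-section area — because a radiologic
  short-axis measurement is not recoverable from pixel counts; and
  D-LN vs N-LN at 50 mm drainage distance. Both thresholds are
  inclusive on the large/distant side and configurable.
* **Axes and origins.** Array axis 1 is the slice axis; voxel physical
  position is the 0-based index times the spacing at the voxel center.
  Origin offsets cancel in all differences, so the origin is fixed at
  zero.

## Cutoff learning

The published model reports a single threshold per feature, learned on
a training cohort by survival analysis, without naming the procedure.
The standard operationalization of that artifact shape is **maximally
selected log-rank**: evaluate the two-group log-rank statistic at
every distinct observed feature value whose split keeps at least 10%
of patients on each side (guard configurable), and keep the maximizing
value, breaking ties toward the smaller cutoff. The default endpoint
is overall survival. The full candidate grid is returned for audit.

Because the maximum over many candidate splits is optimistically
biased, the naive $\chi^2_1$ p-value at the selected cutoff is
reported as `p_naive` only; `permutation_pvalue()` permutes features
against (time, event) pairs and recomputes the maximal statistic,
giving an honest selection-adjusted p with add-one correction, bounded
in $[1/(B+1), 1]$.

The published cutoff pair (71.5 mm³, 140.5 mm) ships via
`published_cutoffs()` for apply-only use and is labeled as
transferred, not re-derived: it was learned on cohorts that are not
distributed, and there is no guarantee it transfers to other scanners
or populations.

Patients exactly at a cutoff are classified on the favorable side
(L-tLNV, D-tLND); the source does not state the tie side, so the
package fixes inclusive-favorable once and prints the rule in every
report header.

## Survival machinery

The Kaplan–Meier estimator, the $k$-group log-rank test and Cox
proportional-hazards regression are implemented in the package itself
(the `survival` package is used in the test suite as an independent
cross-check, to 10⁻⁶ on fixtures with tied event times). Numerical
choices:

* subjects censored at an event time remain in the risk set at that
  time;
* log-rank uses the hypergeometric variance with the covariance matrix
  over the first $k-1$ groups ($\mathrm{df} = k - 1$); risk sets of
  size 1 contribute no variance; a rank-deficient covariance falls
  back to a pseudo-inverse;
* Cox ties default to **Breslow** with **Efron** as an option (the
  reference reporting style does not state its ties method); fitting
  is Newton–Raphson with step-halving on overshoot, convergence at
  relative partial-log-likelihood change < 10⁻⁹ or 100 iterations;
  confidence intervals are Wald, $\exp(\hat\beta \pm 1.96\,SE)$,
  matching the HR [95% CI] reporting convention;
* a diverging coefficient path (|coef| > 15; monotone likelihood /
  separation) sets a `monotone_likelihood` flag with a warning; a
  singular information matrix is an error. Non-convergence is never
  silent.
* five-year rates are the KM estimate at 1826 days; when a group's
  follow-up ends earlier the rate is reported as *not reached*, never
  extrapolated.

Proportional-hazards diagnostics, time-varying covariates, competing
risks and frailty terms are out of scope; the Cox model is used as a
reporting device for subtype contrasts, optionally adjusted for
user-supplied covariates, and covariate *selection* is left to the
analyst.

## The synthetic generators and what they do (not) show

**Phantoms.** `make_phantom()` rasterizes one tumor and $k$
ellipsoidal nodes onto an anisotropic slice grid by voxel-center
membership — a voxel belongs to a shape iff its center lies inside the
ellipsoid — with no partial volumes, which makes the per-node voxel
count, centroid and distance exactly computable by an independent
brute-force routine (`make_phantom()$truth` shares no geometry code
with the feature extractors). Random phantoms draw in-plane spacing
0.4–1 mm, $T$ 3–5 mm, $G$ 0–1.5 mm, snapping shape centers to voxel
centers so every shape contains at least one voxel. Phantoms establish
that the geometry code computes the stated formulas exactly; they do
not establish robustness to irregular node shapes, partial-volume
segmentation boundaries, or inter-observer delineation variability in
real masks.

**Cohorts.** `simulate_cohort()` draws event times from a
proportional-hazards model: exponential baseline with a five-year
median by default (Weibull optional), hazard multiplied by the planted
subtype ratio (defaults MRS 2, HRS 4 vs LRS). Censoring is independent
exponential dropout with rate $\mu = \lambda_\mathrm{ref}\,q/(1-q)$ —
chosen so the censored fraction is exactly $q$ for the exponential
baseline at HR 1 before horizon truncation — plus administrative
censoring at a 10-year horizon; $q = 1$ censors everyone at time zero.
Disease-free survival adds an independent recurrence process with a
1.2× hazard, so DFS events lead OS events as they do clinically.
`simulate_feature_cohort()` plants the two-feature structure directly:
uniform tLNV/tLND draws, subtype from the planted cutpoints (defaults
at the published 71.5/140.5 with hazard ratios near the reported
training-cohort estimates 2.45/4.63), survival as above. These cohorts
validate *recovery*: that the cutoff search finds a planted cutpoint
and that stratification reproduces a planted hazard ordering. They do
not reproduce the published cohorts' absolute survival rates, case
mix, or feature distributions, and uniform feature draws are a
deliberate simplification.

All generators take an explicit `seed` and restore the caller's RNG
state; the same seed gives bit-identical output.

## Problem sizes and test design

The validation suite runs at sizes chosen to make its statistical
bands tight while staying desk-sized: 50 random phantoms (geometry
equivalence, exact for volumes, 10⁻⁹ mm for distances); 1000
null replicates of $n = 100$ for the log-rank type-I error (accepted
band 0.036–0.064, ±2 binomial SD around 0.05); $n = 1000$ for Cox
recovery of HR 2 within ±0.1 on the log scale; 20 seeds of $n = 600$
for recovery of a planted cutpoint 100 (HR 0.3) within [90, 110] in at
least 90% of runs; and 300 patients per subtype for the end-to-end
ordering check. The demo pipeline (`demo_config()`) uses 4 phantoms
and a 300-patient simulated cohort and is byte-stable across reruns
with the same seed.

## Known limitations

* $N \times p$ volumes are area-scaled (mm²) unless
  `mode = "voxel_volume"` is chosen; comparisons across acquisitions
  with different slice pitch should prefer the voxel-volume mode.
* The through-plane distance rule is implemented as printed; users who
  want conventional center-to-center distances can approximate them
  with small $G$ and thick $T$ only qualitatively — no "corrected"
  mode is offered.
* Single-label node masks are split by 26-connectivity, which merges
  truly abutting nodes and cannot recover instance identity that the
  segmentation itself lost.
* Learned cutoffs are maximally selected and therefore optimistic;
  always report the permutation p-value alongside them.
* The simulators plant proportional hazards; none of the validation
  exercises non-proportional alternatives.
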