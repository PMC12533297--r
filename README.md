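# lnmts

Prognostic stratification of rectal-cancer patients from the
morphology and topology of their lymph-node (LN) system, quantified on
instance-labeled 3D MRI segmentation masks.

Radiology usually reduces the nodal system to counts and single-node
diameters. `lnmts` instead treats it as a system and summarizes it per
patient with two numbers:

* **tLNV** — total LN volume (mm³). Each node's volume is
  approximated from its pixel count, `V ≈ N × p` with `p` the in-plane
  pixel area, and summed: `V_total = Σ V_i`. Pixel counting is
  configurable (`accumulated` over all slices, the default;
  `max_cross_section`; or `voxel_volume`, which scales by the slice
  pitch `T + G`).
* **tLND** — total LN drainage distance (mm). Each node's Euclidean
  distance from the tumor centroid, with the through-plane separation
  of ΔS slices entering as `[ΔS·G + (ΔS−1)·T]²` for slice thickness
  `T` and inter-slice gap `G` (0 when ΔS = 0), summed:
  `D_total = Σ D_i`.

Dichotomizing both features at survival-optimal cutoffs (learned by
maximally selected log-rank search, or the published pair
71.5 mm³ / 140.5 mm via `published_cutoffs()`) gives the three-tier
risk model:

| tLNV | tLND | subtype |
|------|------|---------|
| L-tLNV (≥ cutoff) | D-tLND (≥ cutoff) | **LRS** (low risk) |
| L-tLNV | N-tLND | **MRS** (moderate) |
| S-tLNV | D-tLND | **MRS** (moderate) |
| S-tLNV | N-tLND | **HRS** (high risk) |

Validation uses self-contained Kaplan–Meier / log-rank / Cox
machinery (`km_estimate()`, `logrank_test()`, `cox_fit()`), and a
synthetic generator supplies exact geometric phantoms and survival
cohorts with planted effects so the whole pipeline runs without
patient data. See the methods vignette
(`vignettes/lnmts-methods.Rmd`) for every modeling choice and its
rationale.

## Worked example

```r
library(lnmts)

## a synthetic phantom with exactly known geometry
ph <- make_phantom(random_phantom_spec(42))
pf <- patient_features(ph$volume)
pf$nodes[, c("node_label", "pixel_count", "volume", "delta_s",
             "distance", "size_class", "distance_class")]
#>   node_label pixel_count volume delta_s distance size_class distance_class
#> 1          2          53  48.39       1    21.69       L-LN           N-LN
#> 2          3          59  53.87       5    29.54       L-LN           N-LN

## a 300-patient simulated cohort with the cutpoint planted at 71.5 mm^3
coh <- simulate_feature_cohort(300, seed = 7)
find_optimal_cutoff(coh$tLNV, coh$os_time, coh$os_event,
                    feature_name = "tLNV")
#> Optimal tLNV cutoff (os endpoint): 71.6697
#>   log-rank chi-square = 28.15 (naive p = 1.12e-07, biased by selection)
#>   241 candidates searched over n = 300 patients (guard 10%)
permutation_pvalue(coh$tLNV, coh$os_time, coh$os_event,
                   n_perm = 200, seed = 8)
#> [1] 0.004975124

## classify and report
cls <- classify_risk(coh$tLNV, coh$tLND)   # published cutoffs by default
stratified_report(cbind(coh, subtype = cls$subtype), endpoints = "os")
#> LNs-MTS stratified prognostic report
#>   favorable side inclusive: L-tLNV iff tLNV >= cutoff, D-tLND iff tLND >= cutoff
#>
#> == OS ==
#>   1826-day survival: LRS 54.0%, MRS 16.6%, HRS 2.6%
#>   global log-rank: chi-square = 70.52, df = 2, p = 4.86e-16
#>   Cox HR vs LRS:
#>     MRS_vs_LRS: HR = 2.825 (95% CI 2.080-3.837)
#>     HRS_vs_LRS: HR = 4.915 (95% CI 3.222-7.498)
```

The learned cutoff (71.67) sits next to the planted 71.5; the
five-year (1826-day) rates and hazard ratios reproduce the planted
LRS < MRS < HRS hazard ordering. On real data you would start from
NIfTI masks plus a geometry sidecar (`read_annotated_volume()`) and a
clinical CSV (`read_cohort_table()`); `run_pipeline()` orchestrates
the full simulate → features → cutoffs → classify → report flow from
one YAML config, and a thin CLI wrapper ships in `inst/cli/lnmts.R`.

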