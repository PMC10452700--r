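# pethet — proliferative heterogeneity analysis for FLT-PET tumor imaging

Aggressive tumor models — patient-derived xenografts in particular — often
carry large necrotic cores (30–60% of tumor volume). In such tumors,
whole-tumor summary statistics of [18F]FLT uptake (mean or max SUV) are
diluted by the non-proliferative core and miss early treatment response.
`pethet` implements the analysis chain that recovers the signal, for
preclinical imaging scientists analyzing longitudinal PET studies of
treated tumor cohorts:

- **Muscle-referenced proliferative classification.** Each scan's reference
  muscle ROI defines a per-scan threshold
  `T = SUV_mean(muscle) + 2·SD(muscle)`; a tumor voxel is *proliferative*
  iff `SUV ≥ T` (boundary inclusive), otherwise necrotic. Summary SUV
  statistics are then computed over the proliferative compartment only.
- **Fractional-frequency histograms.** The voxel-SUV distribution of each
  tumor, normalized by total tumor voxel count
  (`f_b = n_b / N` per bin `b`), so tumors of different volumes are
  directly comparable.
- **Kolmogorov–Smirnov distribution comparison.** Distribution shifts
  between timepoints or cohorts are quantified by the two-sample KS distance
  `D = sup_x |F̂₁(x) − F̂₂(x)|` on the raw voxel samples, pooled across the
  animals of a cohort, with exact p-values at small sample sizes and the
  asymptotic Kolmogorov distribution otherwise.
- **Growth-curve analysis.** Caliper volumes
  `V = (4π/3)(L₁/2)(L₂/2)((L₁+L₂)/4)`, per-subject percent change from
  baseline, vehicle normalization, two-tailed Mann–Whitney cohort
  comparisons, and single-pass Grubbs (extreme studentized deviate) outlier
  screening.
- **In-vitro quantification.** Percent survival and assay percent changes
  relative to control wells, dose–response tables, and OLS regression of a
  48 h biomarker (EdU proliferation, 2DG glucose uptake) against endpoint
  viability with `R²` and slope p-value.
- **A seeded synthetic study generator** (phantoms with ellipsoidal tumors,
  concentric necrotic cores at SUV ≈ 0.4, a muscle reference region;
  four-arm growth cohorts; assay plates), so the full pipeline runs and is
  tested without any scanner data.

## Worked example

Generate a phantom with a 45% necrotic core (necrotic SUV 0.4 ± 0.05,
viable rim 1.2 ± 0.2, muscle 0.5 ± 0.05) and quantify it:

```r
library(pethet)
ph <- generate_phantom(phantom_spec(seed = 3))
quantify_study(ph$study)
#> <study_quantification> phantom day 0
#>   tumor  mean 0.841 (sd 0.428, max 2.08, n 51440)
#>   muscle mean 0.4995 (sd 0.0502, n 512)
#>   threshold 0.5999 SUV -> proliferative fraction 0.549
#>   proliferative mean SUV 1.203
```

The whole-tumor mean (0.84) sits between the necrotic and viable levels and
says little; the muscle-referenced threshold (0.5 + 2×0.05 ≈ 0.60) isolates
the viable rim, whose recovered fraction (0.549) matches the closed-form
normal-tail expectation `0.55·Φ((1.2−0.6)/0.2) + 0.45·Φ((0.4−0.6)/0.05)
≈ 0.549`, and whose mean SUV (1.20) recovers the simulated rim level.

A treatment that suppresses viable uptake shifts the voxel distribution long
before the mean moves; the KS distance picks it up:

```r
base <- generate_phantom(phantom_spec(seed = 4))$study
trt  <- generate_phantom(phantom_spec(seed = 5, suppression = 0.8))$study
ks_two_sample(base$suv[base$tumor_mask], trt$suv[trt$tumor_mask])
#> <ks_result> D = 0.2535, p = 0 (asymptotic; n1 = 51440, n2 = 51440)
```

The full pipeline — a four-arm simulated imaging study plus growth and
in-vitro stages, all artifacts and a provenance manifest written to disk —
is one call (or `Rscript inst/cli/pethet.R run-all --seed 11 --out out/`):

```r
res <- run_pipeline(run_config(seed = 11, out_dir = "out"))
res$ks[1:4, 1:3]
#>                  comparison           D   p_value
#> 1     vehicle_day0_vs_day10 0.003335804 0.7227271
#> 2 trastuzumab_day0_vs_day10 0.249803095 0.0000000
#> 3   niraparib_day0_vs_day10 0.189341642 0.0000000
#> 4 combination_day0_vs_day10 0.348927446 0.0000000
```

The vehicle cohort's baseline/day-10 distributions are indistinguishable
(D ≈ 0.003, p = 0.72), while each treated cohort shows a clear shift whose
magnitude tracks the simulated suppression.

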