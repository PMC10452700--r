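---
title: "Quantifying proliferative heterogeneity in FLT-PET tumor imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proliferative heterogeneity in FLT-PET tumor imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pethet)
```

## The problem

[18F]FLT is retained by proliferating cells through thymidine kinase-1, so
FLT-PET images cellular proliferation. In heterogeneous tumor models —
patient-derived xenografts above all — a large fraction of the tumor volume
(commonly 30–60%) is necrotic, takes up little tracer (SUV around 0.4), and
contributes nothing to response. Averaging SUV over the whole tumor mixes
these compartments: a treatment that halves uptake in the viable rim can
leave the whole-tumor mean nearly unchanged, because the necrotic floor
dominates and is treatment-invariant. `pethet` implements a quantification
chain built around that observation: classify voxels first, compare
distributions rather than means, and only then summarize.

## The model and its assumptions

**Proliferative threshold.** For each scan, reference skeletal muscle
supplies a subject- and day-specific background level. The threshold is

\[ T = \bar{S}_{muscle} + k\,\sigma_{muscle}, \qquad k = 2 \text{ by default}, \]

and a tumor voxel is *proliferative* iff \(S \ge T\). Conventions we fix
where the procedure is underdetermined:

- The boundary is inclusive — a voxel exactly at \(T\) is proliferative.
- \(\sigma\) is the sample SD (\(n-1\)); the conservative choice for small
  ROIs. A threshold from a single-voxel muscle ROI is refused outright,
  while single-voxel *summaries* report sd = 0 with a warning.
- Muscle statistics are per-scan, never pooled across animals or days:
  each scan carries its own injection, physiology, and scanner calibration.
- SUV is the body-weight convention, tissue density 1 g/mL, decay
  correction assumed applied upstream. Volumes already in SUV bypass the
  conversion.
- Masks are strictly binary (any nonzero value is membership); volumes and
  masks must share shape and affine to 1e-4 — resampling is out of scope
  and a mismatch is a hard error, not a warning.

**Fractional frequency.** Histograms of tumor voxel SUV are normalized by
the total tumor voxel count, \(f_b = n_b / N\), so distributions from
tumors of different volumes are comparable. Default bins are 0.1 SUV wide
from 0 to the 99.9th percentile of the pooled sample; a single overflow bin
extends to the maximum so every voxel is counted and the frequencies sum to
exactly 1 (values outside the edges are otherwise an error by design —
silently dropping them would corrupt the normalization). Bins are
left-closed/right-open, the last bin closed.

**Distribution comparison.** The two-sample Kolmogorov–Smirnov distance
\(D = \sup_x |\hat F_1(x) - \hat F_2(x)|\) is computed on the *raw* voxel
samples, not on the binned frequencies: binning is for reporting, the raw
ECDF is lossless. Voxels are pooled across the animals of a cohort before
comparison, giving one \(D\) per cohort pair (a per-animal mode exists,
`pool = FALSE`). Whether all tumor voxels or only proliferative ones enter
is a flag (`voxels = "all"` by default, since the histogram analysis
describes whole-tumor intensity distributions). P-values use the exact
conditional distribution (`stats::psmirnov`, tie-aware) when
\(n_1 n_2 \le 10^4\), and the asymptotic Kolmogorov series with effective
size \(n_1 n_2/(n_1+n_2)\) above that; the method is recorded in every
result.

**Growth curves.** Caliper volume is
\(V = \frac{4\pi}{3}\frac{L_1}{2}\frac{L_2}{2}\frac{L_1+L_2}{4}\);
percent change is per subject from its own day-0 baseline (subjects missing
a baseline are excluded with a warning); treated arms can be normalized to
the vehicle-arm mean. Cohort comparisons use the two-tailed Mann–Whitney
test: exact when the smaller group has ≤ 8 observations and no ties, else
the normal approximation with midranks, tie-corrected variance, and
continuity correction — ties never enter the exact branch. Outlier
screening is the single-pass two-sided Grubbs test at α = 0.05 per
group-day (not iterated; iterative ESD removal on n = 5 groups would be
aggressive), off by default in `growth_report()`. No multiple-testing
correction is applied by default, matching how such studies report raw
p-values day by day; `p_adjust = "holm"` is available.

**In-vitro quantification.** Percent survival is the treated replicate
mean over the control mean × 100, with the treated replicate SD propagated
on the same scale; assay percent change is the same quantity minus 100, so
the two are consistent by construction. The biomarker–viability relation is
ordinary least squares with \(R^2 = 1 - SS_{res}/SS_{tot}\) and a
two-tailed slope t-test on \(n-2\) df; a constant response returns
\(R^2 = 0\) with a warning rather than NaN, and a constant biomarker is an
error. No automatic well exclusion is applied — Grubbs screening is
reserved for the in-vivo cohorts.

## What the synthetic generator emulates

The generator exists so every stage is testable end to end with no scanner
or animal data. Its defaults encode the study conditions the analysis is
designed for:

- **Phantoms** (`phantom_spec()`): a 64³ grid of 0.5 mm voxels holding an
  ellipsoidal tumor of ~51,000 voxels; a concentric ellipsoidal necrotic
  core containing 45% of tumor voxels (mid-range of the 30–60% seen in
  necrotic PDX models) at SUV 0.4 ± 0.05; a viable rim at 1.2 ± 0.2; and a
  distant muscle cuboid at 0.5 ± 0.05. The rim and muscle levels are
  modeling assumptions — measured viable-rim SUV is not something the
  emulated study reports — chosen so the rim sits well above the muscle
  threshold at baseline (3σ above, classification probability Φ(3) ≈ 0.999)
  while moderate suppression drags part of it below. Treatment acts as a
  multiplicative factor in (0, 1] on the viable mean only; necrotic tissue
  is non-proliferative and treatment-invariant. Voxels are independent
  Gaussians clipped at 0; spatial autocorrelation and PET physics
  (partial volume, reconstruction texture) are deliberately not modeled and
  are the first extension point.
- **Longitudinal series** share geometry across timepoints (a 10-day
  interval at these sizes changes uptake far more than anatomy) and derive
  per-timepoint noise seeds deterministically from the master seed. The
  pipeline's default day-10 suppression factors (vehicle 1.0, trastuzumab
  0.8, niraparib 0.85, combination 0.7) are assumptions that produce cohort
  KS distances in the 0.2–0.35 range reported for treated arms of such
  studies; they are inputs to the simulation, not estimates.
- **Growth cohorts**: four arms (vehicle / trastuzumab / niraparib /
  combination), five animals per arm, enrollment volumes uniform in the
  125–300 mm³ window, six assessments 3 days apart. Per-assessment
  multiplicative growth rates (+13.8, +6.1, +3.3, −6.3% with sds
  11.5–16%) were derived once so that six assessments compound to endpoint
  percent changes near +117, +43, +22 and −32% with cohort-scale spread.
- **Plates**: five replicate wells per condition. Viability fractions
  0.60 / 0.85 / 0.42 of control for trastuzumab / niraparib / combination
  (the niraparib-alone level at 1 µM is an assumption; single-agent PARP
  inhibition at that dose is modest). EdU fractions 0.325 / 0.771 / 0.203
  with tight replicate sds; 2DG fractions 0.542 / 0.767 / 0.385 with
  deliberately large well-to-well spread (0.22–0.28 of control), because
  glucose-uptake shifts of this size were not statistically resolvable at
  five replicates — the generator reproduces that distinguishing feature,
  and consequently the 2DG–viability \(R^2\) lands below the EdU–viability
  one.

Passing tests on these phantoms show that the *computational chain* is
correct and well calibrated — classification matches brute-force voxel
loops, KS matches its \(O(n^2)\) oracle and holds its null level, the
recovered proliferative fraction matches the closed-form normal tail. They
do not show that real FLT-PET data meet the generator's assumptions
(Gaussian regions, no spatial correlation, clean masks, a stable muscle
reference); on real data those are empirical questions.

## Numerical choices and degenerate inputs

- Necrotic cores are carved by ranking tumor voxels on ellipsoidal radius
  and taking the innermost `round(f·N)`, so the realized fraction is exact
  to one voxel (well within the ±2% tolerance asserted for tumors ≥ 10⁴
  voxels) and the core is contiguous and concentric by construction.
- `necrotic_fraction = 0` degenerates cleanly: the viable mask equals the
  tumor mask.
- Classification with a threshold above the tumor maximum returns an
  explicit empty flag and no fabricated summary; the proliferative fraction
  is 0.
- KS p-values from the asymptotic series are clamped to [0, 1]; the series
  is truncated at 101 terms (double-precision exhaustion happens far
  earlier).
- Growth trajectories floor each per-assessment factor at 0.01 so a large
  negative noise draw cannot produce a non-positive volume (with the
  default sds this binds with probability < 10⁻³ per step).
- Vehicle normalization refuses a vehicle mean of exactly 0 rather than
  returning infinities.
- All generators take one explicit seed, restore the caller's RNG state,
  and derive any sub-seeds deterministically, so identical configuration
  gives byte-identical output — including the NIfTI/CSV/JSON artifacts and
  the manifest checksums written by `run_pipeline()`.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
default 64³ phantoms (~51,000 tumor voxels) where parameter recovery is the
point, 16³–21³ phantoms (hundreds to a few thousand tumor voxels) for the
brute-force-oracle and replication studies (500 null replicates at 500
voxels a side; 50 seeds per suppression gap), and a 4-arm × 4-animal ×
2-timepoint imaging study for the end-to-end run. These sizes give the
Monte-Carlo checks comfortable margins (e.g. the ±0.03 tolerance on a
recovered fraction whose sampling error is ~0.005) while keeping the whole
suite in the tens of seconds.

## Known limitations

- The intensity model is two-component Gaussian; real FLT uptake is
  spatially correlated, has partial-volume blur at the rim–core boundary,
  and a heavier right tail. KS distances on real data will be smaller for
  the same biological effect than on phantoms.
- Masks are taken as given; ROI annotation error, registration error, and
  resampling are all out of scope (mismatches are hard errors).
- The muscle reference assumes muscle uptake is treatment-invariant; a
  therapy with systemic proliferative effects would move the threshold
  itself.
- The exact KS branch conditions on ties via the permutation distribution;
  with heavily discretized data and large samples the asymptotic branch is
  used and is only approximate under ties.
- `generate_growth_cohort()` models arm-level growth as i.i.d. per-step
  multiplicative noise; real cohorts show per-animal growth-rate
  heterogeneity (random slopes), which inflates endpoint variance relative
  to this generator at equal per-step sd.
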