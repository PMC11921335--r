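# ivoc — indoor VOC exposure analysis from time-integrated home sampling

`ivoc` is an R package for analysing indoor volatile organic compound
(VOC) exposure in residential cohorts sampled with multi-day
time-integrated whole-air canisters. It is aimed at indoor-air and
exposure-science researchers who have, per home, a single set of
indoor/outdoor VOC concentrations plus basic building and occupancy
metadata, and who want to move from raw concentrations to ventilation-
and volume-normalised emission rates, health-risk benchmarks, and robust
group comparisons.

## What it computes

**Air change rate (ACR)** from a steady-state occupancy CO₂ mass
balance. With *n*<sub>A</sub> adults and *n*<sub>C</sub> children
generating CO₂ at rates *G*<sub>p,A</sub> = 0.312 and
*G*<sub>p,C</sub> = 0.174 L min⁻¹, an occupancy fraction
*f*<sub>occ</sub>, a furnishing-adjusted room volume
*V*<sub>adj</sub> = 0.93 *V*, and indoor/outdoor CO₂ mixing ratios
*C*<sub>in</sub>, *C*<sub>ex</sub> (ppm, *C*<sub>ex</sub> = 450 assumed):

    ACR = (n_A·G_pA + n_C·G_pC) · f_occ · 0.06
          ─────────────────────────────────────   [h⁻¹]
          V_adj · (C_in − C_ex) · 10⁻⁶

**Episodic outlier treatment** per VOC with log-scale modified Z-scores:
`mz_i = 0.6745 · (log x_i − median(log x)) / MAD(log x)`, removing
values with `mz > 3.5` (one-sided high by default — painting-style
aromatic bursts are high outliers), then back-transforming exactly.

**Time-averaged emission rates** under the same steady-state,
ventilation-only removal model:
`q = ACR · V_adj · (C_in − C_out)` (µg h⁻¹), with TVOC sums, per-class
totals (BTEX, trimethylbenzenes, monoterpenes) and min–max normalisation
`X̂ = (X − X_min)/(X_max − X_min)` so dominant emitters (ethanol,
propane, butane) cannot swamp summed comparisons.

**Risk benchmarks**: exposure concentration
`EC = C · (ET/24)(EF/365)(ED/AT)`, lifetime cancer risk `LCR = IUR · EC`
against the 1 × 10⁻⁶ threshold and hazard quotient `HQ = EC/RfC` against
1, with a bundled, overridable IRIS-sourced unit-risk table.

**Nonparametric statistics** as used in indoor-air studies:
Brunner–Munzel generalized Wilcoxon test (with exact permutation
option), Kruskal–Wallis with Dunn post hoc, Holm correction, bootstrap
percentile CIs (1000 resamples), and 5/25/50/75/95 percentile boxplot
summaries.

**Synthetic cohort generator**: seeded, log-normal VOC concentrations
built as outdoor ingress plus an indoor-source increment, seasonal ACR
structure, urban/rural outdoor aromatic shifts, rare painting-style
spikes, and indoor CO₂ obtained by inverting the ACR model — so every
pipeline stage is testable against known ground truth without field
data.

## Worked example

```r
library(ivoc)
cfg    <- pipeline_config(cohort = cohort_spec(n_homes = 124, seed = 1), seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
Indoor VOC exposure report: 124 homes, 18 VOCs
Seasonal median ACR (h^-1):
 season  n median  mean ci_lower ci_upper
 winter 40  0.709 0.755    0.644     0.87
 spring 38  1.076 1.202    1.060     1.35
 summer 27  1.137 1.369    1.140     1.64
 autumn 19  0.957 0.948    0.764     1.15
TVOC median: 990 ug m^-3
Seasonal median total emission rate (ug h^-1):
 season  n median
 winter 40  45543
 spring 38  74248
 summer 27  72571
 autumn 19  61416
12 record(s) excluded (see $exclusions)
```

The 124-home synthetic cohort is generated with winter/summer median
true ACRs of 0.70/1.20 h⁻¹; the report recovers medians of 0.709/1.137
from the inverted CO₂ values at these seasonal sample sizes, shows the
expected summer-high/winter-low total emission seasonality, and logs the
12 painting-spike aromatic records that the modified Z-score filter
removed. Urban/rural comparisons of the treated indoor aromatics are in
`report$tests$urban_rural_aromatics` (Brunner–Munzel relative effects
with Holm-adjusted p-values), e.g. benzene: relative effect 0.71,
adjusted p = 4.5 × 10⁻⁴, rural/urban medians 0.69/1.04 µg m⁻³.
Per-VOC LCR/HQ exceedance fractions are in `report$exceedance`.

A command-line wrapper ships at
`system.file("scripts", "ivoc-pipeline.R", package = "ivoc")`:

```sh
Rscript ivoc-pipeline.R all --seed 1 --out-dir output/
```

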