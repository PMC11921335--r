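---
title: "Methods: indoor VOC exposure analysis with ivoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indoor VOC exposure analysis with ivoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivoc)
```

`ivoc` turns per-home, time-integrated indoor/outdoor VOC measurements
into air change rates, emission rates, health-risk benchmarks and group
comparisons. This vignette explains the models behind each stage, the
parameters that matter, the design decisions that were genuinely open,
and what the bundled synthetic cohort generator does and does not
emulate.

## The CO₂ mass balance for air change rate

A home's air change rate (ACR, h⁻¹) is inferred from a steady-state
single-zone mass balance on occupant-generated CO₂: occupants are the
only indoor source, ventilation the only removal, and the sampling
period long enough that the indoor mixing ratio is at its steady value.
Then

$$\mathrm{ACR} = \frac{(n_A G_{p,A} + n_C G_{p,C})\, f_{occ} \times 0.06}
{V_{adj}\,(C_{in}-C_{ex}) \times 10^{-6}},$$

where the conversion constants are forced by dimensional analysis:
generation rates are quoted in L min⁻¹ (× 0.06 → m³ h⁻¹) and mixing
ratios in ppm (× 10⁻⁶ → volume fraction).

Parameters, held in `acr_params()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `g_adult` | 0.312 | L min⁻¹ | CO₂ generation per adult |
| `g_child` | 0.174 | L min⁻¹ | CO₂ generation per child |
| `co2_outdoor` | 450 | ppm | assumed outdoor mixing ratio |
| `furnishing_fraction` | 0.07 | — | volume occupied by furnishings |

The gross room volume is reduced by the furnishing fraction
(`adjusted_volume()`) so the dilution term reflects available diluent
air. Occupancy is adjusted by a single multiplicative fraction
`occupancy_fraction` per home — the fraction of the sampling period
occupants actually spend in the sampled room. Whether adults and
children deserve separate fractions is not decidable from our inputs; a
shared fraction is assumed and exposed as a plain input column so users
with time-use data can compute their own.

Two input conditions are rejected rather than repaired: indoor CO₂ at or
below the outdoor level, and zero occupants. Both make the steady-state
model meaningless (the quotient is non-positive or undefined), and
silently clamping them would hide bad data; `infer_acr()` errors with an
explicit message instead.

## Outlier treatment with log-scale modified Z-scores

Aromatics (BTEX and trimethylbenzenes) are emitted in intense episodic
bursts by paints and decorating products. To keep such bursts from
distorting group comparisons while tolerating the genuine skew of indoor
air, concentrations are log-transformed per VOC and scored with the
modified Z-score

$$mz_i = 0.6745\,\frac{\log x_i - \mathrm{median}(\log x)}{\mathrm{MAD}(\log x)},$$

with MAD the raw (unscaled) median absolute deviation; 0.6745 puts the
score on the ordinary-Z scale for normal data. Values with
$mz_i > 3.5$ are removed in a single pass, and retained values are
returned exactly (exponential back-transform of an untouched logarithm).

Numerical and design choices:

* **One-sided filter.** Episodic bursts are high outliers; the filter
  only removes $mz > +3.5$ by default. A `two_sided` flag exists for
  symmetric treatment.
* **Log base is irrelevant.** A base change rescales numerator and MAD
  identically; the package uses natural logs internally and the test
  suite asserts invariance to 10⁻¹².
* **MAD = 0 errors.** If at least half a group is identical, the score
  is degenerate; substituting a mean-absolute-deviation fallback would
  silently change semantics, so the function refuses.
* **Zeros are refused.** Below-detection values must be handled upstream
  (`handle_below_lod()`, policies `keep`/`half-lod`/`drop`); the
  pipeline enforces that the log-domain step never sees non-positive
  values.
* **Single pass, not idempotent.** Removing outliers changes the median
  and MAD, so re-running would flag new values; the procedure is defined
  as one pass and applied that way.
* **Scope.** By default only the aromatic classes are treated
  (configurable via `outlier_scope`); other species pass through, and
  TVOC sums use untreated concentrations.

## Time-averaged emission rates and normalisation

Under the same steady-state, ventilation-only assumptions, the emission
rate a home must sustain to hold its indoor concentration above the
outdoor level is

$$q = \mathrm{ACR} \times V_{adj} \times (C_{in} - C_{out})
\quad[\mu g\,h^{-1}].$$

This is a *time-averaged* source strength over the sampling period, not
an instantaneous rate. Negative values — outdoor exceeding indoor —
are retained and flagged (`net_ingress`), never clamped: they indicate
the home acting as a sink, which is information; a `floor_zero` option
exists for studies that prefer clamping. Records missing an outdoor
concentration are skipped with a warning rather than assuming
$C_{out}=0$.

`sensitivity_grid()` recomputes $q$ over fractional perturbations of ACR
and volume; because $q$ is multiplicative in both, the grid is exactly
the outer product $q\,(1+\delta_a)(1+\delta_v)$, which the tests assert.

Cross-VOC comparisons use min–max normalisation per VOC across homes,
$\hat X_a = (X_a - X_{a,min})/(X_{a,max} - X_{a,min}) \in [0,1]$, summed
per home (`class_total()` on `x_hat`) so that single dominant emitters
cannot drive the total. A VOC constant across homes has no scale and is
rejected by name. Working units are µg h⁻¹ throughout (matching the
magnitudes such data produce); display in g h⁻¹ is a presentation
choice left to the user.

## Risk benchmarks

Concentrations are converted to exposure concentrations with the
standard US EPA/ATSDR inhalation factors,
$EC = C\,(ET/24)(EF/365)(ED/AT)$, then benchmarked as
$LCR = IUR \times EC$ (threshold 1 × 10⁻⁶) and $HQ = EC/RfC$ (threshold
1, with $AT = ED$ for the non-cancer case). "Exceeds" means strictly
greater than the threshold. Defaults — 16 h day⁻¹ at home, 365 d y⁻¹,
ED = AT = 70 y — are a documented stand-in for population-specific
time-use values and are fully externalised in `exposure_factors()`; in
the continuous limit (ET = 24, EF = 365, ED = AT) the definition of the
IUR is recovered exactly, $LCR = IUR \times C$, which the tests assert.

The bundled risk table (`inst/extdata/risk_table.csv`) carries
IRIS-published unit risks and reference concentrations with a
provenance column. It is a convenience default: toxicity values are
never hard-coded in logic, and any VOC lacking a benchmark produces an
explicit not-assessable result — never a silent zero — and is excluded
from the corresponding exceedance summary only.

## Nonparametric comparison stack

Indoor-air concentration data are non-normal, heteroscedastic and
behaviour-driven, so group comparisons avoid location-shift and
equal-variance assumptions:

* **Brunner–Munzel** tests the relative effect
  $p = P(X<Y) + \tfrac12 P(X=Y)$ with midranks, a studentised statistic
  and Satterthwaite-type degrees of freedom; it is implemented from the
  defining statistics (no base-R equivalent exists). The default
  t-approximation is complemented by a permutation option that
  enumerates all group assignments exhaustively when
  $\binom{N}{n_1} \le 40\,000$ and samples otherwise; the test suite
  checks both against an independent first-principles oracle, and the
  t-approximation's type-I error at $\alpha = 0.05$ is verified to lie
  in [0.035, 0.065] over 2000 null replicates of two n = 30 groups.
* **Kruskal–Wallis** (ties-corrected H, χ² reference) is computed via
  base R's `kruskal.test` behind this module's result contract, with one
  defined extension: an all-equal sample yields H = 0, p = 1 ("no
  evidence") instead of NaN.
* **Dunn post hoc** pairwise z statistics from pooled midranks with the
  usual tie correction, Holm-adjusted by default. Implemented from the
  defining formula and checked against a hand-computed oracle.
* **Holm correction** wraps base `p.adjust`; two-sided tests at
  $\alpha = 0.05$ throughout.
* **Bootstrap CIs** use the percentile method (the simplest method
  consistent with resampling the plotted statistic) with 1000 resamples
  by default and a mandatory seed; coverage for the mean of n = 100
  normal samples is verified to lie in [0.93, 0.97] over 2000
  replicates.
* **Percentile conventions**: boxplot summaries report the
  5/25/50/75/95 percentiles with linear interpolation between order
  statistics (R quantile type 7) — the rule matters only here and is
  fixed and documented.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage can be tested
against known truth. Its structure mirrors the phenomena the analysis
targets:

* **Concentrations are log-normal** (positive, right-skewed), each VOC
  parameterised by a median and geometric SD for an *indoor-source*
  increment and for the outdoor concentration. Indoor values are built
  mechanistically as `outdoor + source`: at steady state with
  ventilation-only removal, outdoor air contributes its own
  concentration plus $q/(\mathrm{ACR}\,V)$, so outdoor elevation
  propagates indoors exactly as the emission model assumes.
* **Urban aromatic shift.** Urban homes have their *outdoor* BTEX/TMB
  medians multiplied by `urban_aromatic_multiplier` (default 1.69/0.78 ≈
  2.17, the ratio of urban to rural outdoor summed-BTEX medians such
  cohorts exhibit); indoor aromatic elevation then arises via ingress
  rather than by fiat.
* **Painting-style spikes.** With probability `spike_prob` (default
  0.05) a home's indoor-source aromatic term is multiplied by
  `spike_multiplier` (default 50) — multiplicative, aromatics-only, no
  attempt to model paint chemistry. Applying the multiplier to the
  source term (rather than the summed indoor value) keeps the spike
  consistent with the ingress construction; numerically the two are
  near-identical because the spiked source dominates.
* **Seasonal ACR.** True ACRs are log-normal per season with default
  medians winter 0.70, spring 1.10, summer 1.20, autumn 0.85 h⁻¹ and
  geometric SD 1.45. Winter and summer medians are the canonical
  low/high values for temperate housing stock; spring slightly below
  summer and autumn between winter and spring reproduce the
  two-phase seasonal shape (rising through spring/summer, falling
  through autumn/winter) that such cohorts show; the geometric SD puts
  the cohort range near 0.4–3 h⁻¹.
* **CO₂ by inversion.** Each home's indoor CO₂ is computed from its true
  ACR by the algebraic inverse of the mass balance (`co2_from_acr()`),
  so ACR recovery is an exact round trip — the suite asserts relative
  error ≤ 10⁻⁹ across a 124-home cohort. A multiplicative noise knob
  (`co2_noise_gsd`, default 1 = none) exists for robustness studies.
* **Occupancy.** 1–2 adults and 0–3 children uniformly, occupancy
  fraction uniform on [0.3, 0.8] — a stated stand-in for external
  time-use statistics, not a reconstruction of any population.
* **Determinism.** The generator seeds R's RNG from `spec$seed` (and
  restores the caller's RNG state); identical specs reproduce cohorts
  bit for bit.

What the generator does **not** emulate: within-home temporal dynamics
(emission events, decay), correlations between VOCs beyond the shared
ingress term, measurement error and detection limits, meteorology, and
any real population's occupancy behaviour. Passing tests therefore
demonstrate the *computational* correctness of each stage and the
recoverability of configured effects — not that real cohorts satisfy the
steady-state assumptions.

## Degenerate inputs and failure behaviour

Single-home cohorts produce degenerate summaries (median = mean, CI
collapsed to the point) and skip all group tests with a warning.
Min–max normalisation is skipped, with a warning, when any VOC has fewer
than two records. Every record dropped anywhere in the pipeline —
below-LOD drops, modified-Z outliers — lands in the report's exclusion
log with a reason code; nothing is silently lost. Below-LOD policy
defaults to `keep`; the pipeline errors if that leaves non-positive
values for the log-domain outlier step, pointing at `drop`/`half-lod`.

## Problem sizes in the test suite

The suite exercises cohorts of 124 homes (the reference cohort size),
600 homes for effect-recovery checks (urban/rural ratio within 20 %,
seasonal emission ordering), 200 homes for spike-rate recovery (flag
fraction within 3 percentage points of the configured 5 %), 2000
replicates for Brunner–Munzel calibration and bootstrap coverage, and 50
replicate cohorts for the seasonal null calibration (≥ 90 %
non-significant at α = 0.05). These sizes make the stochastic
assertions stable under their fixed seeds while keeping the default test
run fast.

## Known limitations

* The CO₂ balance ignores non-occupant CO₂ sources (gas cooking, pets)
  and assumes a single well-mixed zone; inferred ACRs are indicative.
* Emission rates attribute the entire indoor–outdoor difference to
  ventilation; oxidation and surface partitioning are deliberately out
  of scope, so $q$ is a lower-bound-style operational metric, not a
  chemical source strength.
* LCR/HQ values inherit the exposure-factor stand-ins and the
  steady-exposure assumption; they rank and flag, they do not predict
  individual health outcomes.
* The Brunner–Munzel t-approximation is asymptotic; for very small
  groups use `method = "permutation"`.
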