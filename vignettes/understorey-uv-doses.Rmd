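---
title: "Methods: spectral UV doses and seasonal flavonol trends in forest understoreys"
author: "photodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral UV doses and seasonal flavonol trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodose)
```

## The problem

Understorey plants screen ultraviolet radiation with epidermal flavonoids.
A leaf-clip optical instrument measures this non-invasively as a
dimensionless flavonol index — the leaf's UV-A absorbance at 375 nm
inferred from chlorophyll-fluorescence ratios. The index varies strongly
through the season and between forest stands, and the candidate drivers
are themselves seasonal: spectral irradiance under the canopy (which
depends on solar elevation and canopy leaf-out), air temperature, and
snowpack. `photodose` implements the full computation chain needed to
relate these quantities on a repeated-measures stand design:

1. spectra → waveband photon irradiances, biologically effective UV
   doses, and the red:far-red ratio;
2. daily weather → thermal seasons and growing-season covariates;
3. leaf surveys → community-weighted trait means;
4. inference → local-regression trend bands with CI-overlap comparison,
   correlation tables with significance brackets, and feasible GLS with
   compound-symmetry correlation.

Because the original field data are not deposited, the package includes a
first-class synthetic generator that emulates the measurement design with
planted, recoverable parameters; every stage is validated against that
generator and against closed-form oracles.

## Spectra and waveband integration

A `spectral_irradiance` holds a strictly increasing wavelength grid (nm)
and spectral photon irradiance (µmol m⁻² s⁻¹ nm⁻¹) or energy irradiance
(W m⁻² nm⁻¹). Energy units convert to photon units per wavelength by
N(λ) = E(λ)·λ/(h·c·N_A) with exact CODATA constants. Negative ingest
values — common instrument noise in the UV-B tail of calibrated field
spectra — are clipped to zero and counted rather than rejected.

Wavebands are half-open intervals [lower, upper): UV-B [280, 315),
UV-A [315, 400), PAR [400, 700), and 10-nm red [655, 665) and far-red
[725, 735) bands for the R:FR ratio. The half-open closure is a
deliberate convention: the shared boundaries at 315 and 400 nm are
counted exactly once, so UV-B + UV-A equals the [280, 400) integral to
rounding error (this is a tested invariant). Band integrals use the
trapezoid rule on the stored grid with virtual samples linearly
interpolated exactly at the band edges, so adjacent bands tile the
spectrum without double counting.

## Weighting functions and effective doses

A biological spectral weighting function (BSWF) w(λ) converts spectral
irradiance into a biologically effective dose ∫ w(λ)·E(λ) dλ. Three are
built in:

* **PG** — the plant-growth action spectrum in its closed mathematical
  formulation, spanning UV-B and UV-A up to 390 nm;
* **GEN(G)** — the mathematical formulation of the generalised plant
  action spectrum, nonzero only below 313.3 nm;
* **FLAV** — a flavonoid-accumulation weighting supplied as a node
  table with linear interpolation. The shipped table
  (`inst/extdata/bswf_flav_synthetic.csv`) is a *synthetic stand-in*:
  the published spectrum it would emulate is not redistributable here,
  so the file reproduces only the qualitative shape such spectra share
  (maximum effectiveness in the UV-B, roughly exponential decline
  through the UV-A, zero by 400 nm). No numerical claim in the package
  depends on its exact values; all FLAV results are validated
  self-consistently against an independent fine-grid quadrature of the
  same table.

All BSWFs are normalised to w = 1 at 300 nm — the common convention for
UV action spectra; since the convention is not universal, the
normalization wavelength is an argument. Doses are reported in weighted
photon units (µmol m⁻² s⁻¹), matching the waveband irradiances.

**Numerical choice.** The measured spectrum is treated as piecewise
linear on its own grid (values are never resampled), but the weight
function is evaluated on a 5× refined sub-grid with the BSWF domain
edges inserted as quadrature nodes. On a 0.5 nm instrument grid the
plain trapezoid on the stored samples leaves a relative error of order
1e-4 for GEN(G), whose support ends abruptly at 313.3 nm between grid
points; the refinement brings every built-in BSWF within 1e-4 of a
0.01 nm reference quadrature while leaving the data untouched.

## Thermal seasons and weather covariates

Seasons follow the air-temperature definition: mean daily temperature
continuously above 0 °C (spring), above +10 °C (summer), then below
+10 °C (autumn) and below 0 °C (winter). "Continuously" needs an
operational rule; we use the first run of at least `N` consecutive days
meeting the condition, searched forward from the previous season's
start, with `N = 5` days by default (one synoptic-scale weather spell;
`N` is a parameter and is reported with the segmentation). With `N = 1`
the rule reduces to first-crossing detection, which is the oracle used
in the tests.

The covariates computed per DOY are days post snowmelt, days before the
first marked snowfall, days from the start of the thermal growing
season, and the effective temperature sum Σ max(0, t_mean − T_base)
from that start. The growing season starts at the first `N`-day run
with t_mean strictly above `T_base`. `T_base` defaults to +5 °C, the
standard base for effective temperature sums in Fennoscandian practice;
the source analysis does not state its base, so the default is a
documented choice, not a reproduction. Snowmelt requires `K = 7`
consecutive snow-free days; a marked snowfall requires depth ≥ 1 cm
persisting `K` days. Both are configurable and both are unspecified in
the source design.

## Community-weighted means and group comparisons

The community-weighted mean (CWM) of the flavonol index for a
measurement point and date is Σ p̃_s · mean(index of species s), where
species means are computed from that point's records on that date and
the abundances p̃_s are renormalised over the species actually measured
there. Renormalisation keeps the CWM a proper mean (bounded by the
contributing species means — a tested invariant) when species present
in the abundance survey were not measured on a date. Species-level
means are taken per point before weighting, matching a per-point,
per-date survey design; plant-level pooling across points would weight
points by sampling effort instead.

Stand differences per date use one-way fixed-effects ANOVA; with two
groups F equals the squared pooled t statistic (cross-checked in the
tests). Leaf-side comparisons use Welch's t by default — residual
spread demonstrably differs between stands and dates, so assuming equal
variances is the riskier default — with pooled t and an exact
(enumerated) Wilcoxon rank-sum available; the Wilcoxon switches to the
tie-corrected normal approximation above 20 observations. A paired
option exists but is off by default, matching the two-sample convention
of the source analysis. No multiple-testing correction is applied
across the per-DOY ANOVA family — deliberately, matching the analysis
this package reimplements; users who want familywise control should
adjust the returned p-values themselves.

## Trend curves, confidence bands and overlap

`loess_fit()` is a from-first-principles local regression: at each
evaluation point a degree-2 polynomial is fitted by weighted least
squares with tricube weights over the ⌈span·n⌉ nearest points (span ≤
1) or over all points with the bandwidth inflated to span × the maximum
distance (span > 1, used when a trend is deliberately over-smoothed).
The fit at x₀ is a linear functional l(x₀)ᵀy of the responses, so the
pointwise standard error is σ̂‖l(x₀)‖ with σ̂² estimated from residuals
using the trace-based degrees of freedom n − 2tr(L) + tr(LᵀL); the 95%
band is fit ± t₀.₉₇₅,df · SE. Published loess implementations differ in
their CI construction; this one was chosen because it is exactly
reproducible from the definition and oracle-checkable — the test suite
verifies 93–97% pointwise coverage under linear truth over 1000
replicates, and exact reproduction of noiseless quadratics.

Two trends differ at a grid point when their bands fail to overlap
(strict inequalities); contiguous non-overlap runs are reported as DOY
intervals. The comparison is symmetric and empty for identical fits.
CI overlap is a conservative visual criterion, not a formal test; it is
implemented as stated because it is the criterion the reimplemented
analysis used.

## Correlations and feasible GLS

`pearson_r_with_test()` returns r, t = r√(n−2)/√(1−r²), the two-sided p
on n−2 degrees of freedom, and a significance bracket with thresholds
`***` p ≤ 0.001, `**` p ≤ 0.01, `*` p < 0.05 (note the strict
inequality at 0.05: p = 0.05 exactly is not significant). The
stand × quantity × position correlation table pools the point × DOY
cells of a stand (n = 16 pairs in the default four-point, four-date
design).

`fit_gls_cs()` estimates y = Xβ + e with compound-symmetry correlation
ρ within groups and, optionally, distinct residual SDs per stratum
(the varIdent-style structure). Estimation is moment-based feasible
GLS: alternate GLS for β given (ρ, σ_k) — using the closed-form inverse
of the CS block — with moment updates of σ_k from stratum residual mean
squares and of ρ from mean within-group cross-products of standardised
residuals. Moment updates are not a likelihood ascent in general, so an
update that would lower the Gaussian log-likelihood is rejected and the
iteration stops there; the log-likelihood path is therefore
non-decreasing by construction (and is returned for inspection). This
is simpler than REML, adequate for parameter recovery at the design
sizes used here (tested: slope bias < 20% and ρ within 0.15 over 200
simulated surveys of 20 groups × 8 observations), and exactly OLS when
ρ is fixed at 0 with merged strata. ρ̂ is clipped into
(−1/(m−1)+ε, 1−ε) when the moment estimate leaves the feasible region.
`select_model()` compares candidate structures by AIC computed from the
Gaussian likelihood at convergence (ties broken toward fewer
parameters); pseudo-R² is the squared correlation of fitted and
observed values.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *design* and the *statistical structure*
of the field campaign, not its numbers:

* **Solar template** (`gen_solar_spectrum`): a smooth photon-irradiance
  envelope × a logistic UV-B cut-on whose midpoint shifts to longer
  wavelengths at low solar elevation × an elevation-dependent
  amplitude. Defaults are calibrated once so midsummer-noon open-field
  band integrals are plausible (PPFD ≈ 1300 µmol m⁻² s⁻¹, UV-B:PPFD ≈
  1e-3). It is not a radiative-transfer model; spectral fine structure
  (Fraunhofer lines, water bands) is absent, so nothing downstream may
  depend on features narrower than ~10 nm.
* **Canopy filter** (`apply_canopy`): sunflecks keep the direct beam
  with weak attenuation; shade keeps the diffuse fraction times
  exp(−k·PAI) with mild UV enrichment; the leaf position multiplies
  shade by a leaf transmittance curve (low UV/PAR, green bump, high
  NIR), which depresses R:FR by construction. The evergreen stand holds
  PAI high and flat; deciduous stands ramp PAI logistically at
  leaf-out, so spring spectra diverge between canopy types.
* **Weather year** (`gen_weather_year`): sinusoid + AR(1) noise, fixed
  min/max half-ranges, and a deterministic snow accumulation/melt
  envelope. With zero noise the season boundaries are the analytic
  sinusoid crossings — the oracle used in tests.
* **Survey** (`gen_community_survey`): the index of each plant is
  β₀(species) + β_UVA · (stand-level mean shade UV-A) + γ · max(0,
  T_cold − t_min) + b(point) + ε, clipped at zero. The point effect
  b ~ N(0, σ_point²) makes within-point observations compound-symmetric
  with ρ = σ_point²/(σ_point² + σ_e²), which is what the GLS stage must
  recover. Defaults: β_UVA = 0.04 index units per µmol m⁻² s⁻¹ (spans
  roughly one index unit over the simulated shade-dose range, matching
  the observed index range), γ = 0.02 °C⁻¹ below +5 °C, σ_e = 0.15 and
  σ_point = 0.08 index units (plant-to-plant scatter a few times larger
  than the point effect).

A green test establishes that the chain recovers planted structure of
this kind; it cannot establish anything about real canopies — sunfleck
penumbra, leaf optics of specific species, interannual weather — and
the generator deliberately couples the index to *shade* dose, so the
qualitative result "shade correlations exceed sunfleck correlations" is
a designed property used to validate the statistics, not an empirical
finding.

## Degenerate inputs and tie-breaking

* Zero variance: correlations return a null row with a reason instead
  of erroring; ANOVA emits a null row when fewer than two groups have
  n ≥ 2 or the residual variance is exactly zero; a fully tied
  two-sample comparison returns p = 1 by convention, with a message.
* R:FR with a zero far-red integral is an error ("undefined R:FR"), not
  an NA, because it signals a malformed spectrum rather than a missing
  observation.
* Seasons whose condition is never met are `NA` starts, not errors; a
  missing stand × DOY spectrum simply yields no dose row and downstream
  stages propagate the gap.
* AIC ties in model selection go to the candidate with fewer
  parameters.

## Known limitations

* The GLS stage is moment-based, not REML; variance-component estimates
  are mildly biased at small group counts (the β estimates are not
  materially affected at the tested design sizes).
* The loess CI convention is one of several; conclusions that hinge on
  marginal band overlap can differ between conventions.
* The FLAV weighting is a labelled synthetic stand-in (above).
* Spectrometer calibration, hemispherical-photo PAI derivation and the
  optical instrument's fluorescence physics are out of scope; the
  package starts from calibrated spectra and measured index values.
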