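---
title: "Methods: multi-scale plant-fungal richness correlation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale plant-fungal richness correlation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`divermap` estimates how the species richness of vascular plants covaries
with that of arbuscular mycorrhizal (AM) and ectomycorrhizal (ECM) fungi
across spatial scales, and evaluates three candidate drivers of that
covariation: symbiotic coupling, shared environmental responses, and legacy
effects (paleoclimatic stability and recent human disturbance). The unit of
analysis is the grid cell of a set of co-registered single-band rasters; the
package deliberately performs no reprojection or resampling — inputs must
share one grid, and a mismatch is an error at the first cellwise operation.

The statistical building blocks are intentionally plain: Spearman rank
correlations (midrank ties) for association; Gaussian additive models with
thin-plate regression splines, REML smoothness selection and small basis
dimensions for curvature; one-sample *t*-tests for per-biome correlation
sign; Pearson chi-squared for sign concordance; and uniform perturbation
Monte Carlo for error propagation. The package's contribution is the
harmonization, masking, sampling and accounting chain that connects them.

## Consensus layers and uncertainty masks

Each taxon is represented by two independently produced richness layers.
Both are brought to a common scale by `log1p_standardize()`: log(x + 1) for
layers still on the count scale (layers distributed pre-logged skip the log
step, tracked by an explicit transform-state machine that raises an error on
a double transform), then centring and scaling. Scaling uses the *sample*
standard deviation over data cells — the convention of `scale()` and of the
raster tooling this mirrors. The consensus is the cellwise mean, missing if
either source is missing.

Masking excludes two kinds of cells before any statistic is computed:

* cells in the top 5% of each source layer's own uncertainty surface, and
* cells in the top 5% of cross-study disagreement, measured as the
  two-value CV = (|a − b|/2) / mean(a, b) between the standardized layers.

Standardized layers contain negatives, so both layers are shifted by one
common constant before the CV: `-min(a, b) + 1e-6`. The shift size changes
CV magnitudes but, with exactly two values, not their rank order, and rank
order is all the percentile exclusion consumes; the shift used is emitted as
an attribute so downstream users can audit it. Percentiles are type-7
(linear interpolation) quantiles, the default of `quantile()`; retention
uses `<=` (ties at the threshold are kept), whereas hotspot detection uses a
strict `>` (the "top tail" reading) — the asymmetry is intentional and
tested. Masks are assembled per comparison: the AM analysis combines the two
plant uncertainty masks, the two AM masks and both disagreement masks, so
plant layers are masked differently in the AM and ECM analyses.

Mask percentile thresholds are computed over all data cells of a layer; the
alternative (thresholds after land masking) is not distinguishable from the
available description of the field protocol, and the choice is recorded here.

## Sampling and correlation scan

`sample_cells()` draws masked cells uniformly *without* replacement —
with-replacement sampling would double-count cells — with one deterministic
substream per zone derived from the master seed, so a zone's sample is
independent of iteration order. Defaults follow the field protocol: 10,000
cells globally, 10,000 per biome, up to 1,000 per ecoregion, ecoregions with
fewer than 100 retained cells excluded and reported. Per-biome one-sample
*t*-tests on ecoregion correlations are two-sided and reported with raw
p-values (no multiplicity correction), matching per-biome reporting
practice; the table notes degenerate groups instead of silently dropping
them. Per-ecoregion smooths use k = 3 basis functions; their percent
deviance explained, 100·(1 − deviance/null deviance), is compared to |ρ| by
a Spearman correlation across ecoregions (`compare_metrics()`).

## Driver inference

**Partial deviance (symbiosis).** The full model smooths fungal richness on
plant richness plus temperature, precipitation, pH, SOC, nitrogen,
phosphorus and elevation (k = 3 per term); the reduced model drops the plant
term; the null model is intercept-only. The plant share is
100·(dev(reduced) − dev(full))/dev(null). Penalized refits are not exactly
nested, so a reduced deviance below the full deviance is possible in
principle; it is flagged with a warning and clipped to 0 rather than
reported negative.

**Correlation-driver model (symbiosis/legacy).** Ecoregion-level ρ is
modelled on host-plant biomass %, climate-stability index and human
development %, with environmental and richness covariate means (k = 4,
minimum 50 ecoregions). Covariate means are taken over *exactly* the sampled
cells that produced each ecoregion's ρ — enforced by passing the cell sample
through — and the "richness" covariates are the zone means of the sampled
consensus values (the aggregation of raw per-zone richness is not pinned
down by the protocol; a monotone transform of the mean is used and recorded
here). Per-term partial effects, standard errors and partial residuals are
emitted for plotting.

**Sign concordance (environment).** Within each usable ecoregion (>= 100
cells, >= 10 unique values of the environmental variable) all variables are
min-max scaled to [0, 1] using the zone sample's own range, and two linear
models are fitted: plant ~ env + fungal + host and fungal ~ env + plant +
host, the cross-richness and host terms absorbing symbiotic coupling.
Environmental coefficients with p >= 0.05 are treated as unreliable and the
zone is dropped — the filter removes rows, never alters a recorded sign.
The 2x2 table of response-sign agreement against correlation sign is tested
with a Pearson chi-squared. Whether the original protocol used the Yates
continuity correction is not stated; the uncorrected statistic is primary
and the corrected one is always reported in diagnostics, along with an
expected-count < 5 flag. Sensitivity re-runs drop zones whose within-zone
covariate collinearity exceeds |r| = 0.85 and 0.80. A Shapiro-Wilk screen
(subsampling above the test's n = 5000 validity bound) flags skewed zonal
richness distributions; it is diagnostic only and never blocks the analysis.

## Monte-Carlo error propagation

Per-cell spreads arrive in three dialects and are converted to SDs:
CV%/100 × mean; IQR-ratio%/100 × median × 1.35 (the normal-theory IQR/SD
constant — a warning notes the normality assumption this borrows, and the
median layer is treated as a mean layer downstream); SD passes through. Each
iteration perturbs the *fixed* sampled cells of each of the four study
layers with Uniform(−SD, +SD) draws — uniform, not Gaussian, by protocol
fidelity even though an SD parameterizes it — then re-applies log1p (only to
layers not distributed pre-logged), standardization, consensus averaging and
Spearman correlation. Standardization constants come from the full layer,
not the sample, so perturbed samples are measured on the layer's own scale.
Perturbed raw values below −1 would make log1p undefined; they are clamped
to −1 + 1e-9 and counted in diagnostics (the protocol leaves this case
unspecified; clamp-and-count is this package's documented policy). Because
the cell sample is reused across iterations, the spread of the ρ
distribution reflects measurement error only, not resampling. Common random
numbers (one seed, substream per iteration) make distributions comparable
across SD scale factors, which is how the attenuation-monotonicity property
is tested. The pipeline default runs the Monte Carlo at the global scale
with 1000 iterations; per-biome propagation is available by applying
`prepare_mc_inputs()`/`perturb_and_correlate()` to biome samples.

## Hotspots

Hotspots are computed on the individual study layers, not the consensus —
the union over studies (with a per-cell 1-vs-2-study agreement count) gives
a more complete picture of candidate regions. Overlap is reported primarily
as a percentage of the *fungal* hotspot area, with the plant-denominator
percentage alongside (the overlap area itself is symmetric). Biome-level
overlap is provided in both readings: globally thresholded hotspots
cross-tabulated by biome, and hotspots recomputed within each biome from
the biome's own retained cells; both are emitted with a `mode` flag since
the two answer different questions.

## The synthetic world

`make_world()` generates the inputs the pipeline assumes, with known ground
truth:

* **Richness fields.** A shared latent Gaussian field (plant) and one
  independent field per fungal guild, smoothed with a separable Gaussian
  kernel (`autocorr_length` cells, default 3), are mixed per ecoregion with
  Pearson weight 2·sin(π·ρ/6) — the bivariate-normal inversion that makes
  the *Spearman* correlation of any monotone transforms equal the target ρ.
  The link exp(μ + σz), rounded to integer counts >= 1, gives right-skewed
  richness for which the log1p chain downstream is meaningful (plants
  μ = 5.5, σ = 0.6; AM 4.5/0.5; ECM 4.0/0.5 — a few hundred plant and ~100
  fungal species per cell, a realistic order of magnitude). Default ρ
  targets span −0.76 to 0.89 across ecoregions for AM (−0.3 to 0.84 for
  ECM), the negative-to-positive regime the analysis is designed to expose;
  mixed signs make the global correlation attenuate by construction.
* **Zones.** Biomes are horizontal bands, ecoregions vertical tiles within
  bands (default 6 × 10 = 60 ecoregions on a 240 × 240 grid, ~960 cells
  each). Rectangular tiles keep zonal membership exact and testable;
  mimicking real geography is a non-goal.
* **Study replicates and uncertainty.** Each taxon gets two "study" layers.
  Raw-scale studies add heteroscedastic Gaussian noise with per-cell SD =
  `noise_cv` (default 0.15) × a smooth field in [0.5, 1.5] × true richness;
  one fungal study per guild is distributed pre-logged with SD-dialect
  uncertainty on the log scale (default 0.15), exercising the
  already-logged code path. Uncertainty layers report the true per-cell
  noise magnitude in the layer's dialect relative to the layer's own values,
  so dialect conversion recovers the SD exactly and the emitted uncertainty
  is honest (tested: empirical SD of study − truth matches within 15%
  per SD-decile at 10,000 cells).
* **Covariates.** Eleven smooth fields scaled to plausible ranges
  (temperature −10..30 °C, precipitation 100..3000 mm, pH 4..8.5, host
  biomass 0..100%, stability index 0..1, etc.). Temperature, precipitation
  and pH responses are injected additively on the latent scale before the
  link (effect 0.4 latent-SD per unit z by default), plants always positive
  and each fungal guild matching the sign of its zone's ρ target — so
  response-sign agreement and correlation sign coincide by construction,
  giving the sign-concordance test a known truth. ρ targets can instead be
  derived from a covariate (e.g. `rho_am = "climate_stability"` sets
  ρ = 0.8 × the zone-mean stability scaled to [0, 1]), giving the
  correlation-driver model a known monotone signal.

What the generator does **not** emulate: real geography and latitudinal
gradients, polygonal ecoregions, spatially correlated *errors* (study noise
is independent across cells given the SD surface), non-Gaussian error
families, and sampling-effort bias in the underlying products. Passing tests
therefore demonstrate that the machinery recovers known structure under the
stated error model — not that any particular real-world layer pair is
correctly calibrated.

## Numerical choices and degenerate inputs

* Quantiles are type-7 everywhere, for both masks and hotspots.
* Spearman uses midranks; constant vectors are an explicit error, never a
  silent 0 or NA.
* Standardization uses the sample SD; zero variance and all-missing layers
  are errors.
* mgcv REML step-failure warnings on degenerate inputs (e.g. zero residual
  variance) are suppressed and convergence is reported in the returned
  record instead.
* The copula mixes with the exact 2·sin(π·ρ/6) inversion rather than
  rank-space mixing; integer rounding of the link introduces ties that can
  shift zonal Spearman estimates by well under the sampling error at the
  default link parameters (a tie-free continuous link is available via
  `integer_richness = FALSE` for exactness checks).
* The config hash stamped into every output CSV excludes the output
  directory, so reruns into different directories compare byte-identical.
* Layer I/O uses ESRI ASCII grids (nodata −9999) with a JSON metadata
  sidecar — a plain-text, GDAL-readable raster format; integer grids
  round-trip exactly.

## Problem sizes used in validation

The test suite validates correlation recovery on a 200 × 200 world (25
ecoregions of 1,600 cells, quota 1,000) against a 400-replicate Monte-Carlo
band of the same copula-and-link estimator at n = 1000 iid pairs (the
without-replacement zone sampling only shrinks the spread, so the band is
conservative); the deviance partition on n = 10,000 synthetic samples; sign
concordance on an 80-ecoregion world (weak copula ±0.15, single injected
covariate at effect 0.8 — a construction in which the conditional
regressions are unbiased for the injected signs); Monte-Carlo properties at
200 iterations; and hotspot-overlap recovery on a 300 × 300 grid. The
acceptance script runs the full default pipeline (240 × 240 world, quotas
10,000/10,000/1,000) with the Monte Carlo at 200 iterations.

## Known limitations

Significance of zonal correlations ignores spatial autocorrelation (as does
the protocol this follows); the per-biome *t*-tests are uncorrected for
multiplicity; the correlation-driver GAM with 12 smooth terms is generous
for its default 60 ecoregions and relies on penalization (a minimum of 50
zones is enforced, more is better); and the sign-concordance construction
shows that strong copula coupling between the taxa biases the conditional
environmental coefficients — a caveat that applies equally to the field
protocol the procedure reproduces.
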