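---
title: "Methods: from incubation O2 fluxes to reef-scale production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from incubation O2 fluxes to reef-scale production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefmetab)
```

This vignette documents the models implemented by `reefmetab`, the
assumptions behind them, and the design decisions taken where the procedure
was genuinely open. Nothing here states a result that the test suite or the
acceptance script does not itself compute.

## Flux model

A closed-chamber incubation measures a concentration change
$\Delta C$ over a duration $\Delta t$. The specimen's O$_2$ flux per unit 3D
surface is

$$\mathrm{flux} \;=\; \frac{(\Delta C/\Delta t - \beta)\, V}{A_{2D}\, s},$$

with $\beta$ the mean rate of the seawater-only blanks matched on
(site, season, light/dark phase), $V$ the chamber volume (L), $A_{2D}$ the
planar specimen area (cm$^2$, converted to m$^2$), and $s \ge 1$ the group's
2D$\to$3D surface conversion factor. Concentrations are mg L$^{-1}$ by
default and converted to mmol L$^{-1}$ with the O$_2$ molar mass
31.998 g mol$^{-1}$; a `units = "umol_l"` switch accepts micromolar optode
output directly. Net production $P_n$ is the light-phase flux; respiration
$R$ is the dark-phase flux negated (stored as a positive magnitude); gross
production is the identity $P_g = P_n + R$.

Assumptions and degenerate cases:

* **Blank pooling.** Several blanks for one key are averaged; a missing
  blank is an error, never a silent zero.
* **3D normalization.** Fluxes are normalized to the 3D specimen surface
  ($A_{2D} \cdot s$). The upscaling product then multiplies by $s$ again,
  which converts the flux back to the planar footprint of the covered
  seafloor before applying coverage and rugosity; this keeps the chain
  dimensionally consistent with fluxes "per m$^2$ specimen surface area".
* **Positive dark fluxes** (net O$_2$ production in darkness) are
  physically implausible for these groups and treated as degenerate
  measurements: a warning is raised and $R$ is clamped at 0, preserving the
  $P_g$ identity. Negative *light* fluxes are legitimate (heterotrophic
  sediment) and pass through untouched.
* **Durations** enter only through per-hour rates, so 30--60 min light and
  120 min dark incubations are handled identically.
* Logger illuminance converts to PAR as $\mathrm{PAR} = k \cdot \mathrm{lx}$
  with $k = 0.0185$ by default (a common daylight approximation; the
  constant is exposed because it is instrument- and spectrum-dependent).

## Survey geometry

* A transect of length $L$ at spacing $d$ has $L/d + 1$ inclusive positions
  (50 m at 0.5 m = 101 points); non-divisible spacing is an error.
* Coverage per category is the per-transect count proportion; site--season
  coverage is the mean over transects, with the SD retained. An `other`
  category absorbs non-target benthos so proportions sum to 1 exactly; it is
  carried through coverage statistics but excluded from upscaling.
* Rugosity is the chain/linear length ratio ($\ge 1$); ratios below 1 are
  physically impossible and clamped to 1 with a warning rather than
  rejected, since they arise from chain-handling error in the field.
* The classical cover analysis is a two-way ANOVA (type-II sums of squares,
  so unbalanced transect sets are handled) with site, season and their
  interaction, preceded by a Kolmogorov--Smirnov normality check of the
  residuals against the fitted normal (no Lilliefors correction -- the
  plain KS statistic is reported and flagged as such) and a
  Brown--Forsythe/Levene check (ANOVA on absolute deviations from cell
  medians). Cover proportions are analyzed untransformed. When the
  interaction is significant at 0.05, all pairwise cell comparisons are
  reported with Bonferroni-multiplied p-values capped at 1.

## Upscaling

$$c_i = p_i \, s_i \, b_i \, r$$

applied per specimen, so the downstream inference sees per-specimen
contribution replicates. Conventions:

* $s$ for algal turfs and sand is fixed at 1 (turf area is measured
  planar-only; a sediment surface has no separate 3D skeleton).
* The two coral genera share the single `coral` cover category; their
  conversion factors are averaged with a configurable mix ratio (default
  50/50, since the survey attributes over 80% of coral cover to the two
  genera jointly without a split).
* $r$ multiplies all groups, including sand: the contribution equation
  applies the rugosity factor without exception. Whether coverage and
  rugosity jointly double-count rugose substrate for encrusting groups is
  unresolved in the field protocol; the package applies the equation as
  stated and leaves sensitivity analyses to the user.
* Daily production extrapolates to a 12 h light / 12 h dark cycle. The
  default `net_24h` convention charges the dark half-day with respiration
  (daily $P_n = 12\sum c_n - 12\sum c_R$); `net_light_only`
  (daily $P_n = 12\sum c_n$) is provided because the diel bookkeeping is a
  reporting convention, not a measurement. Gross production is always
  $12\sum c_g$. Under `net_24h`, daily $P_g$ − daily $P_n$ =
  $24\sum c_R$ exactly, which the tests assert as an identity.

## Bayesian inference engine

**Variance stabilization.** Cell variances of flux data grow with cell
means. The package fits Taylor's power law (log cell variance on log
absolute cell mean over design cells with at least two replicates) and
applies the signed power $y \mapsto \mathrm{sign}(y)\,|y|^{\lambda}$ with
$\lambda = 1 - b/2$. When $|\lambda| < 0.05$ the power law degenerates
towards the logarithm and the sign-preserving $\log(1+|y|)$ branch is used;
signed handling matters because dark-phase sediment fluxes can be negative.
Near zero the $\log(1+|y|)$ branch deviates from a pure log, so its
stabilizing action is best for responses of magnitude well above 1 -- the
regime of the flux data. All inference stays on the transformed scale; no
back-transform of coefficients is attempted.

**Candidate set.** All hierarchical (marginality-respecting) term sets over
G (group), S (site), W (season): 19 models for three factors, 2/5/167 for
1/2/4 factors -- the count of downward-closed families of nonempty subsets.
Designs use treatment (reference-level) coding; rank-deficient designs are
an error naming the aliased columns.

**Sampler.** The Gaussian linear model with priors
$\beta \sim N(0, 10^8 I)$ and $\sigma^2 \sim \mathrm{InvGamma}(0.001, 0.001)$
admits a conjugate blocked Gibbs sampler. Because the coefficient prior is
isotropic, the full conditional precision is diagonal in the SVD-rotated
coordinate system of the design matrix; the sampler iterates there in
O(p) per sweep and rotates the stored draws back once. Chains are fully
deterministic under a seed. Two profiles are built in: `full`
(650{,}000 iterations, 50{,}000 burn-in, thinning 5, 120{,}000 retained) and
`test` (6{,}500 / 500 / 5, 1{,}200 retained) for fast runs; retained count
is enforced as (iterations − burn-in)/thinning.

**DIC and averaging.** Deviance is −2 × Gaussian log-likelihood;
$\bar D$ averages over retained draws, $\hat D$ evaluates at the posterior
means of coefficients and variance, $p_D = \bar D - \hat D$ and
$\mathrm{DIC} = \bar D + p_D$. Negative $p_D$ is reported with a warning,
never hidden. Models within $\Delta\mathrm{DIC} \le 2$ of the best form the
candidate set with weights $\propto \exp(-\Delta/2)$. The boundary is
**inclusive** so that the weight pair at $\Delta = \{0, 2\}$,
$\{0.731, 0.269\}$, is well defined; a model at exactly the boundary is a
knife-edge case either way. Coefficient posterior means are averaged on the
union coefficient space with absent coefficients as 0; for contrast
inference the retained draws of the candidate models are stacked in
proportion to their weights (zero-padded on the union space). Stacking
draws, rather than only averaging point estimates, propagates model
uncertainty into the HPDs and is flagged as the package's choice where the
underlying procedure is ambiguous.

**Posterior summaries.** The HPD is the shortest contiguous window over the
sorted draws containing $\lceil 0.95 n \rceil$ of them, ties broken towards
the smallest lower endpoint (so constant samples give a degenerate
interval and fully tied windows resolve deterministically). pMCMC is twice
the smaller posterior tail probability of a contrast, floored at $2/n$
(the Monte-Carlo resolution of a two-tailed statement) and capped at 1.
The HPD and pMCMC decision rules agree up to window-placement noise: if
zero lies outside the 95% HPD then provably at most
$n - \lceil 0.95n \rceil$ draws sit beyond it, so
pMCMC $\le 2(n - \lceil 0.95 n\rceil)/n \approx 0.1$, and in practice it
lands near 0.05; the tests assert both the sharp bound and the approximate
one.

## The synthetic-data generator

The generator emulates the statistical structure of the field campaign: two
sites (exposed/sheltered) crossed with two seasons (non-upwelling /
upwelling), six incubated groups, per-cell Gaussian flux distributions,
multinomial 101-point transects, truncated-Gaussian rugosity and surface
ratios, and i.i.d. Gaussian logger series at 2-minute spacing. Anchors the
default scenario takes from the field study: coral $P_n/P_g$ 16/19 during
non-upwelling and $P_n$ 12 during upwelling; turf $P_n$ 19 during upwelling
(about double its non-upwelling rate); exposed-site coral cover 0.41/0.39;
sheltered-site macroalgal cover 0.47 during upwelling with zero macroalgae
at the exposed site before upwelling; rugosity 1.32/1.53; conversion
factors 1.34 (Montastraea-type), 2.28 (Diploria-type), 4.29 (macroalgae),
2.10 (CCA); incubation PAR regimes 146 ± 47 and 230 ± 58 µmol photons
m$^{-2}$ s$^{-1}$; specimen planar areas 13.16/1.86/15.63/7.48/1.20 cm$^2$.
Values the study does not print -- macroalgal, CCA and sediment individual
rates, respiration magnitudes, the cover of the remaining categories, blank
drift (N(±0.01, 0.005) mg L$^{-1}$ h$^{-1}$), replicate counts (10 per
cell) -- were fixed once at magnitudes consistent with the study's reported
daily ranges and typical warm-water reef values, and are configurable
through the scenario object or a YAML file.

Two design points deserve emphasis:

* **Exact invertibility.** For each specimen the generator draws a target
  flux and back-computes the end concentration through the same flux
  equation the pipeline applies, *including the realized mean blank rate*
  of the matching cell. The pipeline therefore recovers every drawn flux
  exactly (to float precision) when it uses the scenario's effective
  conversion factors, making the round trip a sharp correctness test
  rather than a statistical one.
* **Truncated ratios.** Surface-pair ratios and rugosity draws are
  truncated at 1 (a chain cannot be shorter than its tape; a 3D surface
  cannot be smaller than its shadow). The population mean ratio is
  therefore the truncated-normal mean, which exceeds the location
  parameter where the truncation bites (Montastraea-type corals:
  location 1.34, SD 0.56, effective mean ≈ 1.60).
  `scenario_s_factors()` computes these effective factors analytically and
  is the single source of truth for the generator's inversion.

What the generator does **not** emulate -- and hence what passing tests do
not demonstrate about real data: instrument noise autocorrelation, tidal
and cloud dynamics in the logger series, spatial autocorrelation along
transects, flow-dependence of chamber fluxes (closed unstirred chambers
underestimate in-situ fluxes), or seasonal covariance between cover and
individual productivity. The pipeline's statistical behaviour on such
structure is untested by construction.

## Problem sizes and numerical choices

The test suite and acceptance script run the `test` chain profile (1,200
retained draws), 200 replicates for HPD calibration, 50 replicates for the
model-selection recovery study, 200 specimens per cell for the generator
round trip, and 500--2,000 transects for coverage unbiasedness -- sizes at
which the Monte-Carlo error of each checked quantity is several times
smaller than the tolerance asserted on it. Numerical tolerances: cover
probabilities must sum to 1 within 1e-9; transect spacing must divide the
length within 1e-9; the mg- and µmol-based flux paths agree to 1e-12
relative; design-matrix rank uses a 1e-10 relative singular-value cutoff.

## Known limitations

* The Gaussian error model is assumed, not checked, by the inference stage;
  the power transform mitigates variance heterogeneity but not skew.
* DIC with vague priors approximates p + 1 effective parameters only for
  well-identified models; heavily overparameterized fits on tiny cells can
  show unstable $p_D$ (reported, not corrected).
* Model-averaged contrasts mix posteriors across models; when one model
  dominates (weight ≈ 1) this reduces to ordinary posterior inference, but
  with several near-tied models the stacked posterior is a mixture and its
  HPD should be read as such.
* Coverage, rugosity and conversion factors enter upscaling as plug-in
  constants; their sampling uncertainty is not propagated into the daily
  production totals.
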