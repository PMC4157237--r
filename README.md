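# reefmetab

Benthic primary production analysis for coral reefs, from short-term
incubation O₂ fluxes to ecosystem-scale daily production, with Bayesian
model-averaged inference.

## The problem

How much oxygen (and hence fixed carbon) does a reef's benthic community
produce, and how does that production respond to strong seasonal forcing such
as coastal upwelling? Answering this from field data takes a chain of steps,
each simple but easy to get dimensionally wrong:

1. **Organism fluxes.** Specimens of the dominant benthic autotrophs
   (scleractinian corals, frondose macroalgae, algal turfs, crustose
   coralline algae, and sediment with microphytobenthos) are incubated in
   closed chambers, once in the light and once in the dark. The change in
   dissolved O₂, corrected by seawater-only blanks, gives net production
   *P*ₙ (light), respiration *R* (dark, as a positive magnitude), and gross
   production *P*_g = *P*ₙ + *R*, each normalized to the specimen's **3D**
   surface area (planar area × a group-specific 2D→3D conversion factor
   *s*ᵢ) in mmol O₂ m⁻² h⁻¹.
2. **Upscaling.** Line-point-intercept transects give each group's planar
   seafloor cover *b*ᵢ; the chain method gives the site's rugosity factor
   *r* ≥ 1. A group's contribution to seafloor metabolism is

   *c*ᵢ = *p*ᵢ · *s*ᵢ · *b*ᵢ · *r*   (mmol O₂ m⁻² seafloor h⁻¹),

   and daily ecosystem production extrapolates the summed contributions to a
   12 h light / 12 h dark cycle (by default the dark half-day is charged
   with respiration: daily *P*ₙ = 12 Σ*c*ₙ − 12 Σ*c*_R, daily
   *P*_g = 12 Σ*c*_g).
3. **Inference.** Production responses are variance-stabilized by a power
   transform (Taylor's power law, λ = 1 − b/2), and all 19 hierarchical
   Gaussian linear models over benthic group (G), site (S) and season (W)
   are fitted by a conjugate Gibbs sampler. Models are ranked by DIC
   (= D̄ + p_D), coefficients are averaged over the ΔDIC ≤ 2 window with
   weights ∝ exp(−ΔDIC/2), and cell contrasts are summarized by shortest
   95% highest-posterior-density intervals and pMCMC (twice the smaller
   posterior tail, floored at 2/n draws).

The package implements every step plus a synthetic-data generator that
emulates all six field input tables (incubations, blanks, transects, chain
rugosity, logger series, paired 2D/3D areas) with configurable group ×
site × season means and SDs, so the full pipeline is testable without any
field data. The generator back-computes end O₂ concentrations from drawn
target fluxes, so the flux pipeline provably recovers what was drawn.

## Worked example

```r
library(reefmetab)

sc  <- default_scenario(rng_seed = 2024)        # two sites x two seasons, 6 groups
cfg <- run_config(scenario = sc, seed = 2024, out_dir = "run",
                  chain = chain_profile("test"))
res <- run_pipeline(cfg)                        # writes CSVs + hashed manifest
report_run("run")
```

The report prints, among other sections, the daily ecosystem production per
site and season:

```
== Daily production (mmol O2 m^-2 seafloor d^-1) ==
 site season daily_pn daily_pg convention
  EXP   NoUp    217.8    332.2    net_24h
  EXP     Up    193.3    372.9    net_24h
  SHE   NoUp    164.1    288.9    net_24h
  SHE     Up    288.8    489.1    net_24h
```

i.e. the exposed site fixes ~330 mmol O₂ m⁻² of gross production per day
before the upwelling season in this simulation, and the sheltered site's
production rises during upwelling as macroalgae take over the cover. The DIC
table shows the full three-way interaction model winning decisively for the
per-specimen contributions (the generator builds in group × season and
site differences), and 169 of 190 posterior cell contrasts exclude zero at
pMCMC < 0.05:

```
== Model selection (DIC) ==
                               model    Dbar    pD     DIC  delta weight
 G + S + W + G:S + G:W + S:W + G:S:W -440.29 21.14 -419.16   0.00      1
         G + S + W + G:S + G:W + S:W -337.58 17.10 -320.47  98.68      0
```

Lower-level entry points (`specimen_flux()`, `coverage_from_transects()`,
`contribution()`, `gibbs_fit()`, `hpd()`, ...) are documented individually;
the methods vignette (`vignettes/benthic-production-pipeline.Rmd`) explains
the models, parameter choices and limitations.

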