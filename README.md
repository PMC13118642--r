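# nlcoptim

Statistical workflow for optimizing and characterizing lipid-nanoparticle
drug formulations, built tidyverse-style: data frames in, tibbles out,
`tidy()`/`glance()`/`autoplot()` on every fitted object.

Formulating a nanostructured lipid carrier (NLC) means choosing amounts of
solid lipid and surfactant so that particle size, polydispersity index
(PdI) and zeta potential are all acceptable at once. The field's standard
answer is response surface methodology on a designed experiment, and that
is the core of this package:

* **Design** — rotatable central composite designs (CCD): a 2ᵏ factorial
  core, 2k axial points at coded ±α with α = (2ᵏ)^¼, and replicated centre
  runs that supply the pure-error estimate.
* **Model** — OLS polynomial surfaces (first-order, interaction, pure
  quadratic, full second-order) fitted to run means, with coefficients in
  coded and actual units, overall-model and lack-of-fit F tests
  (SS_res = SS_lof + SS_pe), and a selection rule: significant model, no
  lack of fit, highest adjusted R², ties to the smaller model.
* **Optimize** — Derringer–Suich desirability: per-response transforms
  d ∈ [0,1], overall D = (∏ dᵢ^wᵢ)^(1/Σwᵢ), maximized over the coded design
  region by a reproducible dense grid plus local polish.
* **Characterize** — %EE = (W₀ − C_fd·V_f)/W₀ × 100, %DL with an
  oil-inclusive lipid-matrix denominator, baseline-subtracted DSC endotherm
  integration, crystallinity index CI% = ΔH_disp/(ΔH_ref·c_lipid) × 100.
* **Release & PK** — the running-sum correction for fixed-volume-replacement
  dissolution sampling (C′ₙ = Cₙ + (V_s/V_t)·ΣC_i), and minimal NCA (Cmax,
  Tmax, linear-trapezoid AUC₀₋ₜ) for sparse destructive-sampling designs,
  plus formulation fold-change comparisons.
* **Simulate** — generators for replicated CCD responses, biphasic
  burst-plus-first-order release assays (including the sampling dilution the
  correction must undo), and one-compartment oral PK with lognormal
  between-animal variability.

A complete 13-run case study — an NLC co-loading stiripentol and
cannabidiol, two antiseizure drugs used together in Dravet syndrome — ships
as a packaged fixture (`nlc_study()`, `nlc_pk_parameters()`) and powers the
examples and tests.

## Worked example

```r
library(nlcoptim)

study <- nlc_study()                     # packaged 13-run CCD + responses
fit <- fit_surface(study$design, study$responses, "particle_size", "PQ")
fit
#> Response surface fit: particle_size (PQ model)
#> Coefficients (actual units):
#>     (Intercept)           lipid      surfactant      I(lipid^2) I(surfactant^2)
#>    799.05900000     -1.13565000     -2.02743000      0.00298157      0.00186261
#> R-squared 0.7603 (adj. 0.6405); model p = 0.0133; lack-of-fit p = 0.000908
```

The fitted equation says particle size is a bowl-shaped function of both
amounts: it falls with increasing lipid and surfactant at low levels (the
negative linear terms) and rises again at high levels (the positive
quadratics), with a minimum inside the design region. Evaluating at the
case study's selected settings:

```r
predict(fit, tibble::tibble(lipid = 268.4, surfactant = 553.4))
#> [1] 157.4858
```

i.e. a predicted size of about 157.5 nm at 268.4 mg lipid / 553.4 mg
surfactant. The full pipeline — per-response models, desirability
optimization over the coded region, validation against measured values —
runs as one call:

```r
pipe <- run_rsm_pipeline(
  study$design, study$responses,
  overrides = list(
    particle_size = list(model_class = "PQ"),
    pdi           = list(model_class = "SO"),
    z_potential   = list(model_class = "FO", factors = "surfactant")
  ),
  measured = c(particle_size = 175.3, pdi = 0.232, z_potential = -8.35)
)
pipe$D
#> [1] 0.7412067
pipe$optimum$settings
#> # A tibble: 2 × 4
#>   factor     unit   coded actual
#>   <chr>      <chr>  <dbl>  <dbl>
#> 1 lipid      mg    -0.490   251.
#> 2 surfactant mg    -0.173   365.
```

With the package's default anchor convention (per-response observed-range
anchors, linear ramps, equal weights, all responses minimized) the maximum
overall desirability is D = 0.741 at about 251 mg lipid / 365 mg
surfactant. This differs from the source study's reported D = 0.822 at
268.4/553.4 mg because that study did not publish its desirability anchors;
see the vignette (`vignettes/formulation-optimization.Rmd`) for the
analysis of this discrepancy and for every other methodological choice.

Characterization and PK arithmetic are one-liners:

```r
drug_loading(100, 0, 10, solid_lipid_mg = 268.4, oil_volume_ul = 50)
#> [1] 31.80662    # % drug loading for 100 mg drug in a 314.4 mg lipid matrix
crystallinity_index(0.5731)
#> [1] 9.119212    # % crystallinity vs the bulk reference lipid
```

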