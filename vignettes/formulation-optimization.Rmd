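---
title: "Response-surface optimization of lipid nanoparticle formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization of lipid nanoparticle formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nlcoptim)
```

Nanostructured lipid carriers (NLCs) are lipid nanoparticles whose solid
matrix is disordered by a liquid oil, improving the payload capacity for
lipophilic drugs. Developing one is a multi-response optimization problem:
the amounts of solid lipid and surfactant jointly determine particle size,
polydispersity (PdI) and zeta potential, and all three must be acceptable at
once. `nlcoptim` implements the statistical workflow around that problem —
designed experiments, polynomial response surfaces, desirability-based
multi-response optimization — plus the downstream characterization
arithmetic (encapsulation efficiency, drug loading, crystallinity),
dissolution-profile processing and non-compartmental pharmacokinetics. A
complete 13-run case study (an NLC co-loading stiripentol and cannabidiol)
ships with the package and drives all the examples here.

## The central composite design

A CCD augments a two-level full factorial with `2k` axial points at coded
distance $\pm\alpha$ and replicated centre points. Rotatability — prediction
variance depending only on the distance from the design centre — requires
$\alpha = (2^k)^{1/4}$, which is what `alpha = "rotatable"` resolves to:

```{r}
factors <- dplyr::bind_rows(
  ccd_factor("lipid", center = 300, step = 100, unit = "mg"),
  ccd_factor("surfactant", center = 400, step = 200, unit = "mg")
)
design <- ccd_design(factors, n_center = 5)
design
```

For two factors $\alpha = \sqrt{2} \approx 1.41421$. Reports of this design
family sometimes quote "1.412"; the printed axial levels of the case study
(158.6 = 300 − 141.4) are arithmetically consistent only with $\sqrt 2$, so
`"rotatable"` is the exact value and a literal numeric `alpha` is accepted
for sensitivity checks. Actual levels are stored at full precision;
display rounding to one decimal is left to the caller.

Coded and actual units are linked by `actual = center + coded * step`. The
five centre replicates are not cosmetic: they are the only source of a pure
experimental-error estimate, which the lack-of-fit test needs (below). The
canonical run order is factorial, axial, centre; pass `seed` to randomize
the order reproducibly, as one would when actually executing the runs.

## Response-surface models

Four nested polynomial classes are supported, in the nomenclature standard
for response-surface work: `FO` (first order), `TWI` (first order plus
two-way interactions), `PQ` (pure quadratic — no interactions) and `SO`
(full second order). Fitting is ordinary least squares on the per-run
response *means* via R's QR factorization. Fitting means rather than the
analytical replicates is deliberate: the replicates of the case study are
repeated measurements of the same preparation, so they inform measurement
noise, not run-to-run error; the proper pure-error degrees of freedom come
from the replicated centre *runs* (4 df from 5 centre points).

```{r}
study <- nlc_study()
fit <- fit_surface(study$design, study$responses, "particle_size", "PQ")
tidy(fit)
glance(fit)
```

Every fit carries coefficients in both actual units (interpretable mg-scale
equations) and coded units (comparable effect sizes); the two
parameterizations predict identically to machine precision, which the test
suite checks on randomized designs. The ANOVA record decomposes residual
variation as $SS_{res} = SS_{lack-of-fit} + SS_{pure\ error}$, with the
overall-model F test against the residual and the lack-of-fit F test
against pure error. Per-term p-values are partial (t tests in the full
model) by default; `tidy(fit, tests = "sequential")` gives type-I F tests
in canonical term order instead, since published tables use either
convention and the case study does not say which.

### Model-class selection

`select_surface()` fits each candidate class and keeps those whose overall
model is significant (`p < alpha_level`) and whose lack-of-fit test does
not reject; among these it returns the highest adjusted $R^2$, with ties
broken toward fewer terms. "Tie" is defined with an explicit tolerance
(`tie_tol`, default 1e-9) on adjusted $R^2$: whether the larger of two
nested models wins an exact adjusted-$R^2$ comparison is independent of
the noise scale (it reduces to an F statistic exceeding 1, which happens
with substantial probability even for pure noise), so without a tolerance
the parsimonious model could never win reliably, no matter how clean the
data. With the tolerance, a model whose extra terms buy nothing measurable
loses to its nested competitor, and simulation recovery of a first-order
truth succeeds in over 95% of replicates.

On the case study the rule selects `PQ` for particle size and `SO` for PdI.
For zeta potential the published model is first-order in the surfactant
amount only; since it is not recorded whether the lipid term was dropped
before or after fitting, the reproduction route is explicit:
`fit_surface(..., "FO", factors = "surfactant")`, or the `override`
argument of `select_surface()` / `run_rsm_pipeline()`.

## Desirability optimization

Each response is mapped to $[0,1]$ by a Derringer–Suich transform
(`d_minimize()`, `d_maximize()`, `d_target()`), and the overall desirability
is the weighted geometric mean
$D = (\prod_i d_i^{w_i})^{1/\sum_i w_i}$, which is zero whenever any
individual desirability is zero — no response can be traded away entirely.

`optimize_desirability()` maximizes $D$ over the coded design region in two
stages: a deterministic dense grid (default 401 points per axis over the
box $[-\alpha, \alpha]^k$, about a second of work for $k = 2$), followed by
a Nelder–Mead polish started at the best grid node and constrained to the
region. The grid stage makes results bit-for-bit reproducible; the polish
can only improve on it and is discarded if it ever does not. A `"ball"`
region (coded radius $\le \alpha$) is available; the box is the default
because the case-study optimum is interior to both.

### Anchor convention, and an honest discrepancy

The transforms need anchors. When a study does not publish them, the only
convention derivable from its data is to anchor at the observed response
range: `low` = best observed value, `high` = worst, linear ramps
($s = 1$), equal weights. That is what `desirability_spec()` builds, and
every choice can be overridden by editing the returned tibble.

Applied to the case study (all three responses minimized, including the
signed zeta potential, which is what the study's objective table states),
this convention yields a maximum $D = 0.741$ at roughly 251 mg lipid /
365 mg surfactant. The study itself reports $D = 0.822$ at 268.4 mg /
553.4 mg. The gap is attributable to the unpublished anchor set: no
convention constructible from the printed data reproduces 0.822 at those
settings (for instance, maximizing the signed zeta potential instead gives
$D = 0.892$ at yet another location). The package reports what its stated
convention produces rather than tuning hidden anchors to match a printed
number; the fitted models themselves, and the predictions at the published
settings, agree with the source to a fraction of a percent.

Validation arithmetic is separate and exact:
`relative_prediction_error(measured, predicted)` is
$|m - p| / |m| \times 100$, and `validate_optimum()` assembles the
measured-vs-predicted record.

## Characterization arithmetic

* **Entrapment efficiency**: $\%EE = (W_0 - C_{fd} V_f) / W_0 \times 100$,
  with $W_0$ the loaded drug mass (mg), $C_{fd}$ the free-drug
  concentration in the separation filtrate (mg/mL) and $V_f$ the
  formulation volume (mL). A record implying more free than loaded drug is
  rejected as inconsistent rather than clamped.
* **Drug loading**: the same entrapped mass divided by the *lipid matrix*
  mass. The matrix includes the structuring oil: mass = solid lipid (mg) +
  oil volume (µL) × density (g/mL). The default density 0.92 g/mL is the
  standard literature value for vegetable oils (the case study's oil is a
  sesame-oil drug solution); it is the only composition reading that
  reproduces both published loadings (31.8% for 100 mg stiripentol and
  1.6% for 5 mg cannabidiol over 268.4 mg solid lipid + 50 µL oil), and it
  is exposed as a parameter.
* **DSC endotherm**: `integrate_endotherm()` subtracts a straight baseline
  joining the signal at the integration-window endpoints and integrates
  over time by the trapezoidal rule. A mass-normalized signal in mW/mg
  integrated over seconds gives mJ/mg, and 1 mJ/mg ≡ 1 J/g, the scale of
  tabulated reference enthalpies — no unit factor is applied. Sigmoidal
  baselines and peak deconvolution are out of scope.
* **Crystallinity index**:
  $CI\% = \Delta H_{disp} / (\Delta H_{ref} \times c_{lipid}) \times 100$,
  with the lipid mass fraction entered as a fraction (2.68% → 0.0268).
  Defaults carry the case study's reference values
  ($\Delta H_{ref} = 234.5$ J/g, $c_{lipid} = 0.0268$).

## Release profiles and pharmacokinetics

Fixed-volume-replacement dissolution sampling removes drug with every
withdrawn aliquot; later readings under-report cumulative release unless
corrected. `cumulative_release()` applies the standard running-sum
correction
$C'_n = C_n + (V_s / V_t) \sum_{i<n} C_i$, then scales to percent of dose.
The correction is exact for this sampling scheme — the package's own
release simulator generates the dilution forward and the correction
recovers the true released fraction to rounding error. Values above 100%
are flagged, never clamped: they indicate assay problems the analyst should
see.

`nca()` is deliberately minimal non-compartmental analysis, matching what a
sparse destructive-sampling design supports: Cmax and Tmax read from the
observed means (earliest time on ties), AUC by the linear trapezoid from
dose time to the last sample, with $C(0) = 0$ assumed for extravascular
dosing (configurable). No log-linear rule and no extrapolation to infinity
are attempted. On the sparse 0.5–24 h grid typical of such studies, the
linear trapezoid overestimates a one-compartment profile's true AUC by
roughly 13% (the 8–24 h chord sits above the convex decay); the error falls
below 5% only around 24 sampling points and shrinks monotonically with
grid density — the tests pin this against the closed-form integral rather
than assuming the sparse grid is accurate. `profile_fold_change()` computes
between-formulation ratios and percent increases from two NCA results.

## Synthetic data

The generators exist so every stage is testable without lab data, and they
emulate the case study's dimensions by default:

* `sim_ccd_responses()`: replicate measurements (default 3) per design run,
  Gaussian noise around a true polynomial surface, summarized to
  mean/SD/n. Gaussian noise on these responses is the simplest model
  consistent with instrument replicates; the default truth used in tests is
  the particle-size surface fitted to the packaged study, so simulated
  studies live on a realistic scale.
* `sim_pk_profile()`: destructive sampling (each time point its own group
  of subjects, default 3 at 0.5, 1, 2, 4, 8, 24 h) around the
  one-compartment oral model
  $C(t) = \frac{F D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})$, with
  mean-preserving lognormal between-animal variability — multiplicative and
  positive, as concentrations are. The degenerate case $k_a = k_e$ is
  rejected rather than silently switched to its limiting form.
* `sim_release_curve()`: burst-plus-first-order released fraction
  $f(t) = b + (1-b)(1 - e^{-kt})$, or an immediate-release ramp complete by
  `t_complete`, converted forward into the sampled concentrations the
  replacement correction must undo.

All generators are deterministic under a seed and restore the session RNG
state. What passing tests on these generators shows is that the estimation
and correction machinery is self-consistent under the stated noise models;
they do not emulate real-data pathologies such as heteroscedastic assay
error, non-polynomial response curvature, or absorption profiles beyond one
compartment.

## Numerical choices and limitations

* OLS uses the QR path of `stats::lm`; rank deficiency raises an error
  naming the collinear terms instead of silently dropping them.
* The desirability grid default (401 per axis) makes the $k = 2$ search
  reproducible in under a second; halving the step changes the reported
  $D$ by less than $10^{-4}$ on the packaged study. For degenerate
  problems where $D = 0$ everywhere, the reported settings fall back to
  the grid argmax of the largest individual desirability, flagged.
* Predictions outside the coded radius $\alpha$ are allowed but flagged as
  extrapolation.
* Test problem sizes are chosen to keep the full suite around a minute:
  200-replicate simulation studies for selection and bias checks, a
  101-point grid for end-to-end recovery, $10^4$ random cases for the
  monotonicity properties.
* Out of scope by design: other design families (Box–Behnken,
  Plackett–Burman, D-optimal), blocking, replicate-level variance
  modelling, Box–Cox transforms, release-kinetics model fitting (Higuchi
  and relatives), compartmental PK fitting, and the routine two-group
  significance tests that accompany such studies — all standard elsewhere.
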