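#' One-compartment oral-absorption concentration
#'
#' Closed-form plasma concentration after a single extravascular dose with
#' first-order absorption and elimination:
#' `C(t) = F * D * ka / (V * (ka - ke)) * (exp(-ke t) - exp(-ka t))`.
#'
#' @param t Time(s) post dose (h).
#' @param dose Dose (mg/kg or mg; concentration units follow `v`).
#' @param f Bioavailable fraction in (0, 1].
#' @param v Volume of distribution (L/kg or L).
#' @param ka First-order absorption rate constant (1/h).
#' @param ke First-order elimination rate constant (1/h), different from `ka`.
#' @return Concentration(s) in dose/volume units (e.g. mg/L).
#' @examples
#' one_compartment_conc(c(0.5, 1, 2), dose = 10, f = 0.1, v = 2, ka = 2, ke = 0.15)
#' @export
one_compartment_conc <- function(t, dose, f, v, ka, ke) {
  stopifnot(dose > 0, f > 0, f <= 1, v > 0, ka > 0, ke > 0)
  if (ka == ke) {
    stop("`ka` must differ from `ke` (flip-flop limit not supported).",
         call. = FALSE)
  }
  f * dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Simulate replicated responses on a designed experiment
#'
#' For each design run, draws `n_rep` replicate measurements from the true
#' polynomial surface plus Gaussian noise, and summarizes them as the
#' mean/SD/n rows the fitting functions consume — the structure of a
#' replicated characterization measurement on each formulation of a design.
#'
#' @param design A `ccd_design` tibble.
#' @param truth Named list, one element per response; each element is a list
#'   with `coef` (named actual-unit coefficient vector in canonical term
#'   order), `model_class`, optional `factors` subset, and `sd` (replicate
#'   noise SD in response units, >= 0).
#' @param n_rep Replicates per run (default 3).
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return Long response tibble (`run_id`, `response`, `mean`, `sd`, `n`).
#' @examples
#' des <- ccd_design(dplyr::bind_rows(
#'   ccd_factor("lipid", 300, 100), ccd_factor("surfactant", 400, 200)
#' ))
#' truth <- list(particle_size = list(
#'   coef = c(`(Intercept)` = 798.9, lipid = -1.135, surfactant = -2.027,
#'            `I(lipid^2)` = 0.00298, `I(surfactant^2)` = 0.001862),
#'   model_class = "PQ", sd = 10
#' ))
#' sim_ccd_responses(des, truth, seed = 1)
#' @export
sim_ccd_responses <- function(design, truth, n_rep = 3, seed = NULL) {
  stopifnot(n_rep >= 1)
  ftab <- design_factors(design)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  purrr::imap_dfr(truth, function(tr, rn) {
    stopifnot(is.numeric(tr$sd), tr$sd >= 0)
    fnames <- if (!is.null(tr$factors)) tr$factors else ftab$name
    X <- surface_terms(design_levels(design, "actual")[, fnames, drop = FALSE],
                       tr$model_class)
    if (!setequal(colnames(X), names(tr$coef))) {
      stop("truth coefficients for '", rn, "' must be named exactly: ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    }
    mu <- drop(X %*% tr$coef[colnames(X)])
    reps <- matrix(stats::rnorm(length(mu) * n_rep, mean = mu, sd = tr$sd),
                   nrow = length(mu))
    tibble::tibble(
      run_id = design$run_id,
      response = rn,
      mean = rowMeans(reps),
      sd = if (n_rep > 1) apply(reps, 1L, stats::sd) else 0,
      n = n_rep
    )
  })
}

#' Simulate a destructive-sampling oral PK study
#'
#' Emulates a design where each sampling time uses its own group of animals:
#' at every time point, `n_per_time` concentrations are drawn as lognormal
#' perturbations of the one-compartment closed form (multiplicative
#' between-animal variability with coefficient of variation `cv`), then
#' summarized as mean and SEM.
#'
#' @inheritParams one_compartment_conc
#' @param cv Between-animal lognormal coefficient of variation (>= 0).
#' @param times Sampling times post dose (h), strictly increasing. Default is
#'   a sparse 0.5-24 h single-dose grid.
#' @param n_per_time Animals per time point (default 3).
#' @param seed Integer seed.
#' @return Tibble `time_h`, `conc` (mean), `sem`, `n` — ready for [nca()].
#' @examples
#' sim_pk_profile(dose = 10, f = 0.1, v = 2, ka = 2, ke = 0.15,
#'                cv = 0.2, seed = 7)
#' @export
sim_pk_profile <- function(dose, f, v, ka, ke, cv = 0.2,
                           times = c(0.5, 1, 2, 4, 8, 24), n_per_time = 3,
                           seed = NULL) {
  stopifnot(cv >= 0, n_per_time >= 1, all(diff(times) > 0), all(times > 0))
  mu <- one_compartment_conc(times, dose, f, v, ka, ke)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    # mean-preserving lognormal multiplier
    mult <- matrix(stats::rlnorm(length(times) * n_per_time,
                                 meanlog = -sdlog^2 / 2, sdlog = sdlog),
                   nrow = length(times))
    obs <- mu * mult
  } else {
    obs <- matrix(rep(mu, n_per_time), nrow = length(times))
  }
  tibble::tibble(
    time_h = times,
    conc = rowMeans(obs),
    sem = if (n_per_time > 1) apply(obs, 1L, stats::sd) / sqrt(n_per_time) else 0,
    n = n_per_time
  )
}

#' Simulate a sequential-sampling release experiment
#'
#' Generates the raw sampled concentrations a fixed-volume-replacement
#' dissolution assay would record, given a true released-fraction curve:
#' either a burst-plus-first-order profile
#' `f(t) = b + (1 - b) * (1 - exp(-k t))` or an immediate-release profile
#' (`f = 1` from `t_complete` onward, ramping linearly before). The generated
#' concentrations include the dilution from sample withdrawal and medium
#' replacement, which [cumulative_release()] must undo — applying it recovers
#' `100 * f(t)` exactly.
#'
#' @param kind `"burst_plus_first_order"` or `"immediate"`.
#' @param times Sampling times (h), strictly increasing.
#' @param v_total Vessel volume (mL).
#' @param v_sample Withdrawn volume per sample (mL).
#' @param dose_mg Drug mass in the vessel (mg).
#' @param burst Burst fraction `b` in `[0, 1]` (burst kind).
#' @param rate First-order rate `k` (1/h, > 0) (burst kind).
#' @param t_complete Time by which release is complete (immediate kind).
#' @return A list: `release` tibble (`time_h`, `conc_mg_ml`) as sampled, plus
#'   `true_fraction`, and the assay constants.
#' @examples
#' sim <- sim_release_curve("burst_plus_first_order", burst = 0.3, rate = 0.5)
#' cumulative_release(sim$release, sim$v_total, sim$v_sample, sim$dose_mg)
#' @export
sim_release_curve <- function(kind = c("burst_plus_first_order", "immediate"),
                              times = c(0.5, 1, 2, 4, 6, 8),
                              v_total = 10, v_sample = 0.5, dose_mg = 5,
                              burst = 0.2, rate = 0.5, t_complete = 2) {
  kind <- match.arg(kind)
  stopifnot(all(diff(times) > 0), all(times > 0),
            v_total > 0, v_sample >= 0, v_sample < v_total, dose_mg > 0)
  frac <- switch(kind,
    burst_plus_first_order = {
      stopifnot(burst >= 0, burst <= 1, rate > 0)
      burst + (1 - burst) * (1 - exp(-rate * times))
    },
    immediate = {
      stopifnot(t_complete > 0)
      pmin(times / t_complete, 1)
    }
  )
  # forward model of the assay: withdrawn mass is gone from later readings
  conc <- numeric(length(times))
  removed <- 0
  for (i in seq_along(times)) {
    conc[i] <- (dose_mg * frac[i] - removed) / v_total
    removed <- removed + conc[i] * v_sample
  }
  list(
    release = tibble::tibble(time_h = times, conc_mg_ml = conc),
    true_fraction = frac,
    kind = kind,
    v_total = v_total, v_sample = v_sample, dose_mg = dose_mg
  )
}
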