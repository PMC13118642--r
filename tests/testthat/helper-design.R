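# shared builders for the test suite

study_factors <- function() {
  dplyr::bind_rows(
    ccd_factor("lipid", center = 300, step = 100, unit = "mg"),
    ccd_factor("surfactant", center = 400, step = 200, unit = "mg")
  )
}

study_design <- function(n_center = 5) {
  ccd_design(study_factors(), n_center = n_center)
}

random_factor <- function(name = "x") {
  ccd_factor(name,
             center = stats::runif(1, -50, 500),
             step = stats::runif(1, 0.1, 50))
}

# truth list for the simulator: a pure-quadratic surface on the study scale
pq_truth <- function(sd = 0) {
  list(particle_size = list(
    coef = c(`(Intercept)` = 798.9, lipid = -1.135, surfactant = -2.027,
             `I(lipid^2)` = 0.00298, `I(surfactant^2)` = 0.001862),
    model_class = "PQ", sd = sd
  ))
}

# closed-form AUC of the one-compartment oral model over [0, t_end]
auc_one_compartment <- function(t_end, dose, f, v, ka, ke) {
  a <- f * dose * ka / (v * (ka - ke))
  a * ((1 - exp(-ke * t_end)) / ke - (1 - exp(-ka * t_end)) / ka)
}
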