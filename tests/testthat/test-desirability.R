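study <- nlc_study()

study_models <- function() {
  list(
    particle_size = fit_surface(study$design, study$responses,
                                "particle_size", "PQ"),
    pdi = fit_surface(study$design, study$responses, "pdi", "SO"),
    z_potential = fit_surface(study$design, study$responses, "z_potential",
                              "FO", factors = "surfactant")
  )
}

test_that("smaller-is-better transform hits its anchors and ramps linearly", {
  expect_equal(d_minimize(157.5, 157.5, 642.9), 1)
  expect_equal(d_minimize(700, 157.5, 642.9), 0)
  expect_equal(d_minimize(400.2, 157.5, 642.9), 0.5) # midpoint of the anchors
  expect_equal(d_minimize(300, 157.5, 642.9), (642.9 - 300) / 485.4,
               tolerance = 1e-12)
  # exponent bends the ramp but keeps the anchors
  expect_equal(d_minimize(400.2, 157.5, 642.9, s = 2), 0.25)
  expect_error(d_minimize(1, 10, 5), "low < high")
  expect_error(d_minimize(1, 0, 1, s = -1), "positive")
})

test_that("maximize and target transforms cover their goals", {
  expect_equal(d_maximize(c(0, 5, 10), 0, 10), c(0, 0.5, 1))
  expect_equal(d_target(c(0, 2.5, 5, 7.5, 10), 0, 5, 10),
               c(0, 0.5, 1, 0.5, 0))
  expect_error(d_target(1, 0, 5, 4), "between")
})

test_that("desirability transforms are monotone", {
  set.seed(11)
  for (i in 1:10000) {
    lo <- stats::runif(1, -10, 10)
    hi <- lo + stats::runif(1, 0.1, 10)
    s <- stats::runif(1, 0.2, 5)
    y <- sort(stats::runif(2, lo - 2, hi + 2))
    expect_gte(d_minimize(y[1], lo, hi, s), d_minimize(y[2], lo, hi, s))
    expect_lte(d_maximize(y[1], lo, hi, s), d_maximize(y[2], lo, hi, s))
  }
})

test_that("overall desirability is a weighted geometric mean with annihilation", {
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  expect_equal(overall_desirability(c(0.9, 0.9, 0)), 0)
  expect_equal(overall_desirability(c(0.8, 0.9, 0.75)),
               (0.8 * 0.9 * 0.75)^(1 / 3), tolerance = 1e-12)
  expect_equal(overall_desirability(c(0.5, 0.9), weights = c(2, 1)),
               (0.5^2 * 0.9)^(1 / 3), tolerance = 1e-12)
  # invariance to response ordering
  d <- c(0.3, 0.8, 0.6); w <- c(1, 2, 0.5); p <- c(3, 1, 2)
  expect_equal(overall_desirability(d, w), overall_desirability(d[p], w[p]))
  expect_error(overall_desirability(c(0.5, 1.2)), "0, 1")
  expect_error(overall_desirability(c(0.5, 0.5), weights = 1), "one entry")
})

test_that("default spec anchors at the observed response ranges", {
  spec <- desirability_spec(study$responses, "minimize")
  expect_equal(spec$response, c("particle_size", "pdi", "z_potential"))
  expect_equal(spec$low, c(157.5, 0.177, -16.7))
  expect_equal(spec$high, c(642.9, 0.672, -7.0))
  expect_true(all(spec$s == 1) && all(spec$weight == 1))
})

test_that("optimizer grid stage matches exhaustive enumeration", {
  models <- study_models()
  spec <- desirability_spec(study$responses, "minimize")
  opt <- optimize_desirability(models, spec, n_grid = 41)

  # independent enumeration: evaluate the polynomials directly
  alpha <- sqrt(2)
  g <- seq(-alpha, alpha, length.out = 41)
  best <- 0
  b_pq <- models$particle_size$coef_actual
  b_so <- models$pdi$coef_actual
  b_li <- models$z_potential$coef_actual
  for (c1 in g) for (c2 in g) {
    x1 <- 300 + 100 * c1; x2 <- 400 + 200 * c2
    y1 <- b_pq[1] + b_pq[2] * x1 + b_pq[3] * x2 + b_pq[4] * x1^2 + b_pq[5] * x2^2
    y2 <- b_so[1] + b_so[2] * x1 + b_so[3] * x2 + b_so[4] * x1 * x2 +
      b_so[5] * x1^2 + b_so[6] * x2^2
    y3 <- b_li[1] + b_li[2] * x2
    dd <- c(min(max((spec$high[1] - y1) / (spec$high[1] - spec$low[1]), 0), 1),
            min(max((spec$high[2] - y2) / (spec$high[2] - spec$low[2]), 0), 1),
            min(max((spec$high[3] - y3) / (spec$high[3] - spec$low[3]), 0), 1))
    best <- max(best, prod(dd)^(1 / 3))
  }
  expect_equal(opt$diagnostics$grid_D, best, tolerance = 1e-12)
})

test_that("local polish never degrades the grid optimum", {
  des <- study_design()
  set.seed(5)
  for (i in 1:20) {
    truth <- list(y = list(
      coef = stats::setNames(c(stats::rnorm(3, 0, 50), stats::rnorm(3, 0, 0.01)),
                             colnames(surface_terms(
                               design_levels(des, "actual"), "SO"))),
      model_class = "SO", sd = 0))
    resp <- sim_ccd_responses(des, truth, seed = i)
    fit <- fit_surface(des, resp, "y", "SO")
    spec <- desirability_spec(resp, "minimize")
    opt <- optimize_desirability(list(y = fit), spec, n_grid = 41)
    expect_gte(opt$D, opt$diagnostics$grid_D - 1e-12)
  }
})

test_that("reported optimum is stable under grid refinement", {
  models <- study_models()
  spec <- desirability_spec(study$responses, "minimize")
  d1 <- optimize_desirability(models, spec, n_grid = 201)$D
  d2 <- optimize_desirability(models, spec, n_grid = 401)$D
  expect_lt(abs(d1 - d2), 1e-4)
})

test_that("a response pinned at full desirability yields D = 1 at the first grid node", {
  des <- study_design()
  resp <- sim_ccd_responses(des, list(y = list(
    coef = c(`(Intercept)` = 5, lipid = 0, surfactant = 0),
    model_class = "FO", sd = 0)), seed = 1)
  fit <- fit_surface(des, resp, "y", "FO")
  spec <- tibble::tibble(response = "y", goal = "minimize", low = 6, high = 7,
                         target = NA_real_, s = 1, weight = 1)
  opt <- optimize_desirability(list(y = fit), spec, n_grid = 21)
  expect_equal(opt$D, 1)
  expect_equal(opt$settings$coded, c(-sqrt(2), -sqrt(2)), tolerance = 1e-9)
})

test_that("an unreachable goal is flagged degenerate with D = 0", {
  des <- study_design()
  resp <- sim_ccd_responses(des, list(y = list(
    coef = c(`(Intercept)` = 5, lipid = 0, surfactant = 0),
    model_class = "FO", sd = 0)), seed = 1)
  fit <- fit_surface(des, resp, "y", "FO")
  spec <- tibble::tibble(response = "y", goal = "minimize", low = 1, high = 2,
                         target = NA_real_, s = 1, weight = 1)
  opt <- optimize_desirability(list(y = fit), spec, n_grid = 21)
  expect_equal(opt$D, 0)
  expect_true(opt$diagnostics$degenerate)
})

test_that("relative prediction errors reproduce the published validation record", {
  expect_equal(relative_prediction_error(175.3, 157.5), 10.2, tolerance = 0.01)
  expect_equal(relative_prediction_error(0.232, 0.231), 0.43, tolerance = 0.01)
  expect_equal(relative_prediction_error(-8.35, -9.75), 16.8, tolerance = 0.01)
  expect_equal(relative_prediction_error(5, 5), 0)
  expect_error(relative_prediction_error(0, 1), "undefined")
})
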