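study <- nlc_study()

test_that("refit of the packaged study recovers the published coefficients", {
  pq <- fit_surface(study$design, study$responses, "particle_size", "PQ")
  expect_equal(unname(pq$coef_actual),
               c(798.9, -1.135, -2.027, 0.00298, 0.001862),
               tolerance = 0.01)
  so <- fit_surface(study$design, study$responses, "pdi", "SO")
  expect_equal(unname(so$coef_actual),
               c(0.9387, -0.00318, -0.00078, -3.40e-6, 8.14e-6, 1.62e-6),
               tolerance = 0.01)
  lin <- fit_surface(study$design, study$responses, "z_potential", "FO",
                     factors = "surfactant")
  expect_equal(unname(lin$coef_actual), c(-17.87, 0.01467), tolerance = 0.01)
})

test_that("term expansion has canonical order and class-specific width", {
  x <- design_levels(study$design, "coded")
  expect_equal(colnames(surface_terms(x, "FO")),
               c("(Intercept)", "lipid", "surfactant"))
  expect_equal(colnames(surface_terms(x, "TWI")),
               c("(Intercept)", "lipid", "surfactant", "lipid:surfactant"))
  expect_equal(colnames(surface_terms(x, "PQ")),
               c("(Intercept)", "lipid", "surfactant",
                 "I(lipid^2)", "I(surfactant^2)"))
  expect_equal(colnames(surface_terms(x, "SO")),
               c("(Intercept)", "lipid", "surfactant", "lipid:surfactant",
                 "I(lipid^2)", "I(surfactant^2)"))
  expect_error(surface_terms(x, "cubic"), "model_class")
})

test_that("OLS is exact on noise-free synthetic surfaces", {
  des <- study_design()
  resp <- sim_ccd_responses(des, pq_truth(sd = 0), seed = 1)
  fit <- fit_surface(des, resp, "particle_size", "PQ")
  expect_equal(unname(fit$coef_actual),
               unname(pq_truth()$particle_size$coef),
               tolerance = 1e-9)
})

test_that("coded and actual parameterizations agree on random designs", {
  set.seed(99)
  for (i in 1:100) {
    factors <- dplyr::bind_rows(
      ccd_factor("a", stats::runif(1, 10, 100), stats::runif(1, 1, 20)),
      ccd_factor("b", stats::runif(1, 10, 100), stats::runif(1, 1, 20))
    )
    des <- ccd_design(factors, n_center = 3)
    truth <- list(y = list(
      coef = stats::setNames(stats::rnorm(6),
                             colnames(surface_terms(
                               design_levels(des, "actual"), "SO"))),
      model_class = "SO", sd = 1
    ))
    resp <- sim_ccd_responses(des, truth, seed = i)
    fit <- fit_surface(des, resp, "y", "SO")

    # decode the coded-unit coefficients to actual units by expansion
    m <- factors$center; s <- factors$step
    cc <- fit$coef_coded
    dec <- c(
      cc[1] - cc[2] * m[1] / s[1] - cc[3] * m[2] / s[2] +
        cc[4] * m[1] * m[2] / (s[1] * s[2]) +
        cc[5] * m[1]^2 / s[1]^2 + cc[6] * m[2]^2 / s[2]^2,
      cc[2] / s[1] - cc[4] * m[2] / (s[1] * s[2]) - 2 * cc[5] * m[1] / s[1]^2,
      cc[3] / s[2] - cc[4] * m[1] / (s[1] * s[2]) - 2 * cc[6] * m[2] / s[2]^2,
      cc[4] / (s[1] * s[2]),
      cc[5] / s[1]^2,
      cc[6] / s[2]^2
    )
    expect_equal(unname(dec), unname(fit$coef_actual), tolerance = 1e-8)

    nd <- tibble::tibble(a = stats::runif(5, 10, 100),
                         b = stats::runif(5, 10, 100))
    expect_equal(as.vector(suppressWarnings(predict(fit, nd))),
                 as.vector(suppressWarnings(predict(fit, nd, coded = TRUE))),
                 tolerance = 1e-8)
  }
})

test_that("residuals are orthogonal to the model matrix on study fits", {
  for (spec in list(c("particle_size", "PQ"), c("pdi", "SO"),
                    c("z_potential", "FO"))) {
    fit <- fit_surface(study$design, study$responses, spec[1], spec[2])
    X <- stats::model.matrix(fit$fit)
    r <- stats::residuals(fit$fit)
    expect_lt(max(abs(crossprod(X, r))), 1e-6)
  }
})

test_that("ANOVA sums of squares partition and degrees of freedom add up", {
  for (mc in c("FO", "TWI", "PQ", "SO")) {
    fit <- fit_surface(study$design, study$responses, "particle_size", mc)
    a <- fit$anova
    g <- function(src, col) a[[col]][a$source == src]
    expect_equal(g("residual", "sumsq"),
                 g("lack_of_fit", "sumsq") + g("pure_error", "sumsq"),
                 tolerance = 1e-8)
    expect_equal(g("total", "sumsq"),
                 g("model", "sumsq") + g("residual", "sumsq"),
                 tolerance = 1e-8)
    expect_equal(g("residual", "df"), g("lack_of_fit", "df") + g("pure_error", "df"))
    expect_equal(g("total", "df"), g("model", "df") + g("residual", "df"))
    # pure error comes from the 5 centre replicates regardless of model
    expect_equal(g("pure_error", "df"), 4)
  }
})

test_that("QR fit matches a brute-force normal-equations solve", {
  des <- study_design()
  resp <- sim_ccd_responses(des, pq_truth(sd = 15), seed = 3)
  fit <- fit_surface(des, resp, "particle_size", "FO")
  X <- surface_terms(design_levels(des, "actual"), "FO")
  y <- resp$mean[match(des$run_id, resp$run_id)]
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef_actual), as.vector(beta), tolerance = 1e-10)
})

test_that("predictions at the reported optimum match the published values", {
  pq <- fit_surface(study$design, study$responses, "particle_size", "PQ")
  so <- fit_surface(study$design, study$responses, "pdi", "SO")
  lin <- fit_surface(study$design, study$responses, "z_potential", "FO",
                     factors = "surfactant")
  opt <- tibble::tibble(lipid = 268.4, surfactant = 553.4)
  expect_equal(as.vector(predict(pq, opt)), 157.5, tolerance = 0.005)
  expect_equal(as.vector(predict(so, opt)), 0.231, tolerance = 0.005)
  expect_equal(as.vector(predict(lin, opt)), -9.75, tolerance = 0.005)
})

test_that("prediction flags extrapolation beyond the axial radius", {
  pq <- fit_surface(study$design, study$responses, "particle_size", "PQ")
  expect_warning(
    p <- predict(pq, tibble::tibble(lipid = 600, surfactant = 400)),
    "outside the design region"
  )
  expect_true(attr(p, "extrapolated"))
  p_in <- predict(pq, tibble::tibble(lipid = 300, surfactant = 400))
  expect_false(attr(p_in, "extrapolated"))
  # intercept-only surface predicts its intercept at the centre
  des <- study_design()
  resp <- sim_ccd_responses(des, list(y = list(
    coef = c(`(Intercept)` = 5, lipid = 0, surfactant = 0),
    model_class = "FO", sd = 0)), seed = 1)
  flat <- fit_surface(des, resp, "y", "FO")
  expect_equal(as.vector(predict(flat, tibble::tibble(lipid = 300, surfactant = 400))),
               5, tolerance = 1e-9)
})

test_that("model selection honours single candidates and overrides", {
  sel1 <- select_surface(study$design, study$responses, "pdi",
                         candidates = "PQ")
  expect_equal(sel1$model_class, "PQ")
  sel2 <- select_surface(study$design, study$responses, "z_potential",
                         factors = "surfactant", override = "FO")
  expect_equal(sel2$model_class, "FO")
  expect_equal(length(sel2$fit$coef_actual), 2L)
  expect_error(select_surface(study$design, study$responses, "pdi",
                              candidates = character(0)), "nonempty")
})

test_that("selection recovers a first-order truth under small noise", {
  des <- study_design()
  truth <- list(y = list(
    coef = c(`(Intercept)` = 100, lipid = 0.5, surfactant = -0.2),
    model_class = "FO", sd = 1e-3
  ))
  hits <- 0L
  for (seed in 1:200) {
    resp <- sim_ccd_responses(des, truth, seed = seed)
    sel <- select_surface(des, resp, "y", candidates = c("FO", "SO"))
    if (sel$model_class == "FO") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("rank-deficient model matrices raise a singular-design error", {
  des <- study_design()
  # force perfect collinearity: second factor is a copy of the first
  des$surfactant_coded <- des$lipid_coded
  des$surfactant_actual <- des$lipid_actual
  resp <- tibble::tibble(run_id = des$run_id, response = "y",
                         mean = rnorm(13), sd = 0, n = 1)
  expect_error(fit_surface(des, resp, "y", "SO"),
               "Singular design.*surfactant")
})

test_that("tidy and glance expose the fit in standard form", {
  pq <- fit_surface(study$design, study$responses, "particle_size", "PQ")
  td <- tidy(pq)
  expect_equal(td$term, pq$terms)
  expect_equal(td$estimate, unname(pq$coef_actual))
  expect_true(all(c("std.error", "statistic", "p.value") %in% names(td)))
  ts <- tidy(pq, tests = "sequential")
  expect_equal(nrow(ts), length(pq$terms) - 1L)
  expect_equal(sum(ts$sumsq), pq$anova$sumsq[pq$anova$source == "model"],
               tolerance = 1e-8)
  gl <- glance(pq)
  expect_equal(gl$nobs, 13L)
  expect_equal(gl$r.squared, pq$r_squared)
})
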