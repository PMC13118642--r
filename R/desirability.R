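#' Derringer-Suich individual desirability transforms
#'
#' Map a response value onto the `[0, 1]` desirability scale according to an
#' optimization goal.
#'
#' `d_minimize()` is the smaller-is-better transform: 1 at or below `low`,
#' 0 at or above `high`, `((high - y) / (high - low))^s` in between.
#' `d_maximize()` is its mirror image, and `d_target()` rises from `low` to 1
#' at `target` and falls back to 0 at `high`.
#'
#' @param y Numeric vector of response values.
#' @param low,high Anchors in response units, `low < high`.
#' @param target Target value for `d_target()`, inside `(low, high)`.
#' @param s Shape exponent (> 0); 1 gives the linear ramp. `d_target()` takes
#'   `s_low` / `s_high` for the two flanks.
#' @param s_low,s_high Flank exponents for `d_target()`.
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @examples
#' d_minimize(300, low = 157.5, high = 642.9) # 0.7068...
#' d_maximize(c(0, 5, 10), 0, 10)
#' d_target(5, 0, 5, 10)
#' @export
d_minimize <- function(y, low, high, s = 1) {
  check_anchors(low, high, s)
  d <- ((high - y) / (high - low))^s
  d[y <= low] <- 1
  d[y >= high] <- 0
  d
}

#' @rdname d_minimize
#' @export
d_maximize <- function(y, low, high, s = 1) {
  check_anchors(low, high, s)
  d <- ((y - low) / (high - low))^s
  d[y <= low] <- 0
  d[y >= high] <- 1
  d
}

#' @rdname d_minimize
#' @export
d_target <- function(y, low, target, high, s_low = 1, s_high = 1) {
  check_anchors(low, high, s_low)
  check_anchors(low, high, s_high)
  if (!is.numeric(target) || target <= low || target >= high) {
    stop("`target` must lie strictly between `low` and `high`.", call. = FALSE)
  }
  d <- numeric(length(y))
  up <- y > low & y <= target
  down <- y > target & y < high
  d[up] <- ((y[up] - low) / (target - low))^s_low
  d[down] <- ((high - y[down]) / (high - target))^s_high
  d
}

check_anchors <- function(low, high, s) {
  if (!is.numeric(low) || !is.numeric(high) || !is.finite(low) ||
      !is.finite(high) || low >= high) {
    stop("Anchors must satisfy low < high.", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("Shape exponent `s` must be a positive number.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Overall desirability
#'
#' Combines individual desirabilities into the weighted geometric mean
#' `D = (prod d_i^w_i)^(1/sum w_i)`. `D` is zero whenever any individual
#' desirability is zero.
#'
#' @param d Numeric vector of individual desirabilities in `[0, 1]`, or a
#'   matrix with one column per response (rows are combined independently).
#' @param weights Positive importance weights, one per response; equal by
#'   default.
#' @return Single value (vector input) or vector (matrix input) in `[0, 1]`.
#' @examples
#' overall_desirability(c(0.8, 0.9, 0.75))
#' @export
overall_desirability <- function(d, weights = NULL) {
  m <- if (is.matrix(d)) d else matrix(d, nrow = 1L)
  if (is.null(weights)) weights <- rep(1, ncol(m))
  if (length(weights) != ncol(m)) {
    stop("`weights` must have one entry per response.", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("`weights` must be positive.", call. = FALSE)
  }
  if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE)) {
    stop("Individual desirabilities must lie in [0, 1].", call. = FALSE)
  }
  m <- pmin(pmax(m, 0), 1)
  # log-scale geometric mean; a zero d annihilates D
  out <- exp(as.vector(log(pmax(m, .Machine$double.xmin)) %*% weights) / sum(weights))
  out[apply(m == 0, 1L, any)] <- 0
  if (is.matrix(d)) out else out[[1L]]
}

#' Build a desirability specification from observed responses
#'
#' The conventional anchor choice when nothing else is stated: per response,
#' `low` and `high` are the observed minimum and maximum in the experimental
#' data, the ramp is linear (`s = 1`) and weights are equal. Any column can be
#' overridden afterwards by editing the returned tibble.
#'
#' @param responses Long response table (`run_id`, `response`, `mean`).
#' @param goals Named character vector mapping each response to
#'   `"minimize"`, `"maximize"` or `"target"`; a single unnamed value is
#'   recycled to every response.
#' @param targets Optional named numeric vector of targets for
#'   `goal = "target"` responses.
#' @return A tibble with columns `response`, `goal`, `low`, `high`, `target`,
#'   `s`, `weight` — the format [optimize_desirability()] expects.
#' @examples
#' study <- nlc_study()
#' desirability_spec(study$responses, "minimize")
#' @export
desirability_spec <- function(responses, goals = "minimize", targets = NULL) {
  resp_names <- unique(responses$response)
  if (length(goals) == 1L && is.null(names(goals))) {
    goals <- stats::setNames(rep(goals, length(resp_names)), resp_names)
  }
  if (!all(resp_names %in% names(goals))) {
    stop("`goals` must name every response.", call. = FALSE)
  }
  purrr::map_dfr(resp_names, function(rn) {
    v <- responses$mean[responses$response == rn]
    tibble::tibble(
      response = rn,
      goal = unname(goals[[rn]]),
      low = min(v),
      high = max(v),
      target = if (!is.null(targets) && rn %in% names(targets))
        unname(targets[[rn]]) else NA_real_,
      s = 1,
      weight = 1
    )
  })
}

apply_desirability <- function(y, spec_row) {
  switch(spec_row$goal,
         minimize = d_minimize(y, spec_row$low, spec_row$high, spec_row$s),
         maximize = d_maximize(y, spec_row$low, spec_row$high, spec_row$s),
         target = d_target(y, spec_row$low, spec_row$target, spec_row$high,
                           spec_row$s, spec_row$s),
         stop("Unknown goal '", spec_row$goal, "'.", call. = FALSE))
}

#' Maximize overall desirability over the design region
#'
#' Evaluates every fitted response surface on a dense regular grid in coded
#' units, transforms predictions through the per-response desirability
#' functions, and takes the weighted geometric mean. The grid stage makes the
#' search reproducible; the best grid point then seeds a Nelder-Mead polish
#' constrained to the region.
#'
#' @param models Named list of `surface_fit` objects, one per spec row; names
#'   must match `spec$response`.
#' @param spec Desirability specification tibble (see [desirability_spec()]).
#' @param region `"box"` (coded hypercube `[-alpha, alpha]^k`, default) or
#'   `"ball"` (coded hypersphere of radius alpha).
#' @param n_grid Grid points per axis (default 401).
#' @return A `desirability_optimum` object: `settings` tibble (actual and
#'   coded factor levels at the optimum), `responses` tibble (prediction and
#'   individual desirability per response), overall desirability `D`, and
#'   optimizer diagnostics including the pre-polish grid maximum.
#' @examples
#' study <- nlc_study()
#' fits <- list(
#'   particle_size = fit_surface(study$design, study$responses, "particle_size", "PQ"),
#'   pdi = fit_surface(study$design, study$responses, "pdi", "SO"),
#'   z_potential = fit_surface(study$design, study$responses, "z_potential",
#'                             "FO", factors = "surfactant")
#' )
#' opt <- optimize_desirability(fits, desirability_spec(study$responses, "minimize"),
#'                              n_grid = 101)
#' opt$D
#' @export
optimize_desirability <- function(models, spec, region = c("box", "ball"),
                                  n_grid = 401) {
  region <- match.arg(region)
  if (!all(spec$response %in% names(models))) {
    stop("`models` must contain a fit for every spec response.", call. = FALSE)
  }
  models <- models[spec$response]
  ftab <- design_factors_of_models(models)
  alpha <- models[[1]]$alpha
  k <- nrow(ftab)

  g <- seq(-alpha, alpha, length.out = n_grid)
  coded_grid <- as.matrix(expand.grid(rep(list(g), k)))
  colnames(coded_grid) <- ftab$name
  if (region == "ball") {
    keep <- sqrt(rowSums(coded_grid^2)) <= alpha + 1e-12
    coded_grid <- coded_grid[keep, , drop = FALSE]
  }

  eval_D <- function(coded) {
    actual <- decode_matrix(coded, ftab)
    d <- matrix(NA_real_, nrow = nrow(coded), ncol = nrow(spec))
    for (i in seq_len(nrow(spec))) {
      yhat <- predict_at(models[[spec$response[i]]], actual)
      d[, i] <- apply_desirability(yhat, spec[i, ])
    }
    list(D = overall_desirability(d, spec$weight), d = d)
  }

  grid_eval <- eval_D(coded_grid)
  best_i <- which.max(grid_eval$D)
  grid_best <- coded_grid[best_i, , drop = FALSE]
  grid_D <- grid_eval$D[best_i]
  degenerate <- grid_D == 0
  if (degenerate) {
    # nothing to trade off: fall back to the largest single desirability
    best_i <- which.max(apply(grid_eval$d, 1L, max))
    grid_best <- coded_grid[best_i, , drop = FALSE]
  }

  obj <- function(x) {
    if (any(abs(x) > alpha)) return(Inf)
    if (region == "ball" && sqrt(sum(x^2)) > alpha) return(Inf)
    -eval_D(matrix(x, nrow = 1L, dimnames = list(NULL, ftab$name)))$D
  }
  polish <- stats::optim(as.vector(grid_best), obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
  use_polish <- !degenerate && is.finite(polish$value) && -polish$value >= grid_D
  coded_opt <- if (use_polish) polish$par else as.vector(grid_best)
  coded_opt <- matrix(coded_opt, nrow = 1L, dimnames = list(NULL, ftab$name))
  final <- eval_D(coded_opt)

  actual_opt <- decode_matrix(coded_opt, ftab)
  settings <- tibble::tibble(
    factor = ftab$name,
    unit = ftab$unit,
    coded = as.vector(coded_opt),
    actual = as.vector(actual_opt)
  )
  preds <- vapply(seq_len(nrow(spec)), function(i) {
    predict_at(models[[spec$response[i]]], actual_opt)
  }, numeric(1))
  responses <- tibble::tibble(
    response = spec$response,
    goal = spec$goal,
    predicted = preds,
    desirability = as.vector(final$d),
    weight = spec$weight
  )
  on_boundary <- any(abs(abs(coded_opt) - alpha) < 1e-8) ||
    (region == "ball" && abs(sqrt(sum(coded_opt^2)) - alpha) < 1e-8)

  structure(list(
    settings = settings,
    responses = responses,
    D = if (degenerate) 0 else final$D,
    diagnostics = list(method = "grid+Nelder-Mead", region = region,
                       n_grid = n_grid, grid_D = grid_D,
                       evaluations = nrow(coded_grid) + polish$counts[["function"]],
                       boundary = on_boundary, degenerate = degenerate)
  ), class = "desirability_optimum")
}

design_factors_of_models <- function(models) {
  all_f <- purrr::map(models, "factors")
  merged <- dplyr::distinct(dplyr::bind_rows(all_f))
  if (anyDuplicated(merged$name)) {
    stop("Models disagree on factor definitions.", call. = FALSE)
  }
  merged
}

decode_matrix <- function(coded, ftab) {
  actual <- coded
  for (j in seq_len(nrow(ftab))) {
    actual[, j] <- decode_value(coded[, j], ftab[j, ])
  }
  colnames(actual) <- ftab$name
  actual
}

# matrix-input prediction, tolerating models using a factor subset
predict_at <- function(model, actual) {
  nd <- tibble::as_tibble(as.data.frame(actual))
  p <- suppressWarnings(predict(model, nd))
  as.vector(p)
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat(sprintf("Overall desirability D = %.4f%s\n", x$D,
              if (isTRUE(x$diagnostics$degenerate)) " (degenerate: D = 0 everywhere)" else ""))
  cat("Optimal settings:\n"); print(x$settings)
  cat("Responses at the optimum:\n"); print(x$responses)
  invisible(x)
}

#' @method tidy desirability_optimum
#' @export
tidy.desirability_optimum <- function(x, ...) {
  x$responses
}

#' @method glance desirability_optimum
#' @export
glance.desirability_optimum <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    region = x$diagnostics$region,
    n_grid = x$diagnostics$n_grid,
    grid_D = x$diagnostics$grid_D,
    evaluations = x$diagnostics$evaluations,
    boundary = x$diagnostics$boundary,
    degenerate = x$diagnostics$degenerate
  )
}

#' Relative prediction error
#'
#' Percent disagreement between a measured value and a model prediction,
#' `|measured - predicted| / |measured| * 100`.
#'
#' @param measured Nonzero measured value(s).
#' @param predicted Predicted value(s).
#' @return Percent error, same length as the inputs.
#' @examples
#' relative_prediction_error(175.3, 157.5) # 10.2
#' @export
relative_prediction_error <- function(measured, predicted) {
  if (any(measured == 0)) {
    stop("Relative prediction error is undefined for measured = 0.", call. = FALSE)
  }
  abs(measured - predicted) / abs(measured) * 100
}

#' Compare measured values with model predictions at the optimum
#'
#' @param optimum A `desirability_optimum`.
#' @param measured Named numeric vector of measured response values.
#' @return Tibble with `response`, `measured`, `predicted` and
#'   `relative_error_pct`.
#' @export
validate_optimum <- function(optimum, measured) {
  resp <- optimum$responses
  if (!all(resp$response %in% names(measured))) {
    stop("`measured` must name every optimized response.", call. = FALSE)
  }
  m <- as.numeric(measured[resp$response])
  tibble::tibble(
    response = resp$response,
    measured = m,
    predicted = resp$predicted,
    relative_error_pct = relative_prediction_error(m, resp$predicted)
  )
}
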