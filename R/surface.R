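#' Polynomial term expansion for response-surface models
#'
#' Expands factor settings into the model matrix of one of the four standard
#' response-surface model classes:
#' \describe{
#'   \item{FO}{first order: intercept + linear terms}
#'   \item{TWI}{first order + two-way interactions}
#'   \item{PQ}{pure quadratic: first order + squared terms, no interactions}
#'   \item{SO}{full second order: linear + interactions + squared terms}
#' }
#' Column order is canonical: intercept, linear terms in factor order,
#' interactions in lexicographic pair order, quadratics in factor order.
#'
#' @param levels Numeric matrix or data frame of factor settings, columns
#'   named by factor.
#' @param model_class One of `"FO"`, `"TWI"`, `"PQ"`, `"SO"`.
#' @return Numeric model matrix with named columns, first column the intercept.
#' @examples
#' x <- cbind(lipid = c(200, 400), surfactant = c(200, 600))
#' colnames(surface_terms(x, "SO"))
#' @export
surface_terms <- function(levels, model_class = c("FO", "TWI", "PQ", "SO")) {
  if (!is.character(model_class) ||
      !all(model_class %in% c("FO", "TWI", "PQ", "SO")) ||
      length(model_class) < 1L) {
    stop("Unknown model_class; must be one of FO, TWI, PQ, SO.", call. = FALSE)
  }
  model_class <- match.arg(model_class)
  levels <- as.matrix(levels)
  nm <- colnames(levels)
  if (is.null(nm)) stop("`levels` must have named columns.", call. = FALSE)
  k <- ncol(levels)

  cols <- list(`(Intercept)` = rep(1, nrow(levels)))
  for (j in seq_len(k)) cols[[nm[j]]] <- levels[, j]
  if (model_class %in% c("TWI", "SO") && k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        cols[[paste0(nm[i], ":", nm[j])]] <- levels[, i] * levels[, j]
      }
    }
  }
  if (model_class %in% c("PQ", "SO")) {
    for (j in seq_len(k)) {
      cols[[paste0("I(", nm[j], "^2)")]] <- levels[, j]^2
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' Fit a polynomial response surface by ordinary least squares
#'
#' Fits the requested model class to per-run response means via QR-based OLS
#' ([stats::lm()]). Coefficients are reported in both actual units and coded
#' units (the two parameterizations predict identically). The ANOVA record
#' decomposes residual variation into lack of fit and pure error, the latter
#' estimated from runs with identical factor settings — in a CCD, the
#' replicated centre points.
#'
#' @param design A `ccd_design` tibble (see [ccd_design()]).
#' @param responses Long response table with columns `run_id`, `response`,
#'   `mean` (and optionally `sd`, `n`), one row per run and response.
#' @param response Name of the response to fit.
#' @param model_class One of `"FO"`, `"TWI"`, `"PQ"`, `"SO"`.
#' @param factors Optional character vector restricting the model to a subset
#'   of factors (e.g. a single-factor linear model); defaults to all design
#'   factors.
#'
#' @return A `surface_fit` object: coefficients in both unit systems, fit
#'   statistics and the lack-of-fit ANOVA. Use [generics::tidy()],
#'   [generics::glance()], [predict()][predict.surface_fit] and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' study <- nlc_study()
#' fit <- fit_surface(study$design, study$responses, "particle_size", "PQ")
#' tidy(fit)
#' glance(fit)
#' @export
fit_surface <- function(design, responses, response,
                        model_class = c("FO", "TWI", "PQ", "SO"),
                        factors = NULL) {
  model_class <- match.arg(model_class)
  ftab <- design_factors(design)
  if (is.null(factors)) factors <- ftab$name
  if (!all(factors %in% ftab$name)) {
    stop("Unknown factor(s): ",
         paste(setdiff(factors, ftab$name), collapse = ", "), call. = FALSE)
  }
  resp <- responses[!is.na(responses$response) &
                      responses$response == response, , drop = FALSE]
  if (!nrow(resp)) stop("Response '", response, "' not found.", call. = FALSE)
  if (anyDuplicated(resp$run_id)) {
    stop("Duplicate run_id for response '", response, "'.", call. = FALSE)
  }
  idx <- match(design$run_id, resp$run_id)
  if (anyNA(idx)) {
    stop("Responses missing for run_id(s): ",
         paste(design$run_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  y <- resp$mean[idx]
  if (any(!is.finite(y))) stop("Response means must be finite.", call. = FALSE)

  actual <- design_levels(design, "actual")[, factors, drop = FALSE]
  coded <- design_levels(design, "coded")[, factors, drop = FALSE]
  X <- surface_terms(actual, model_class)
  Xc <- surface_terms(coded, model_class)
  if (nrow(X) < ncol(X)) {
    stop("Fewer runs (", nrow(X), ") than model terms (", ncol(X), ").",
         call. = FALSE)
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("Singular design: collinear term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  fit <- stats::lm(y ~ X - 1)
  fit_coded <- stats::lm(y ~ Xc - 1)
  coef_actual <- stats::setNames(stats::coef(fit), colnames(X))
  coef_coded <- stats::setNames(stats::coef(fit_coded), colnames(Xc))

  n <- length(y)
  p <- ncol(X)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1L
  df_res <- n - p

  # pure error from replicated identical settings
  key <- apply(design_levels(design, "actual"), 1L, paste, collapse = "\r")
  groups <- split(y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- sum(vapply(groups, length, integer(1)) - 1L)
  ss_lof <- ss_res - ss_pe
  df_lof <- df_res - df_pe

  f_mod <- if (df_mod > 0 && df_res > 0) (ss_mod / df_mod) / (ss_res / df_res) else NA_real_
  p_mod <- if (is.finite(f_mod)) stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE) else NA_real_
  f_lof <- if (df_lof > 0 && df_pe > 0) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
  p_lof <- if (is.finite(f_lof)) stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE) else NA_real_

  anova_tbl <- tibble::tibble(
    source = c("model", "residual", "lack_of_fit", "pure_error", "total"),
    df = c(df_mod, df_res, df_lof, df_pe, n - 1L),
    sumsq = c(ss_mod, ss_res, ss_lof, ss_pe, ss_tot),
    meansq = c(ss_mod / df_mod, ss_res / df_res,
               if (df_lof > 0) ss_lof / df_lof else NA_real_,
               if (df_pe > 0) ss_pe / df_pe else NA_real_,
               ss_tot / (n - 1L)),
    statistic = c(f_mod, NA, f_lof, NA, NA),
    p.value = c(p_mod, NA, p_lof, NA, NA)
  )

  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (ss_res / df_res) / (ss_tot / (n - 1L))

  structure(
    list(
      response = response,
      model_class = model_class,
      factors = ftab[match(factors, ftab$name), , drop = FALSE],
      alpha = design_alpha(design),
      terms = colnames(X),
      coef_actual = coef_actual,
      coef_coded = coef_coded,
      r_squared = r2,
      adj_r_squared = adj_r2,
      sigma = sqrt(ss_res / max(df_res, 1L)),
      anova = anova_tbl,
      fit = fit,
      fit_coded = fit_coded,
      data = tibble::as_tibble(cbind(tibble::as_tibble(actual), .y = y))
    ),
    class = "surface_fit"
  )
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("Response surface fit: %s (%s model)\n", x$response, x$model_class))
  cat("Coefficients (actual units):\n")
  print(signif(x$coef_actual, 6))
  cat(sprintf("R-squared %.4f (adj. %.4f); model p = %.3g; lack-of-fit p = %.3g\n",
              x$r_squared, x$adj_r_squared,
              x$anova$p.value[x$anova$source == "model"],
              x$anova$p.value[x$anova$source == "lack_of_fit"]))
  invisible(x)
}

#' Tidy a response-surface fit
#'
#' @param x A `surface_fit`.
#' @param tests `"partial"` (default; t tests from the full model) or
#'   `"sequential"` (type-I F tests in canonical term order).
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate` (actual
#'   units), `estimate_coded`, `std.error`, `statistic`, `p.value`.
#' @method tidy surface_fit
#' @export
tidy.surface_fit <- function(x, tests = c("partial", "sequential"), ...) {
  tests <- match.arg(tests)
  if (tests == "partial") {
    s <- summary(x$fit)$coefficients
    tibble::tibble(
      term = x$terms,
      estimate = unname(x$coef_actual),
      estimate_coded = unname(x$coef_coded),
      std.error = s[, "Std. Error"],
      statistic = s[, "t value"],
      p.value = s[, "Pr(>|t|)"]
    )
  } else {
    X <- stats::model.matrix(x$fit)
    y <- stats::model.response(stats::model.frame(x$fit))
    dat <- as.data.frame(X[, -1, drop = FALSE])
    names(dat) <- paste0("t", seq_len(ncol(dat)))
    dat$.y <- y
    seq_fit <- stats::lm(.y ~ ., data = dat)
    a <- stats::anova(seq_fit)
    idx <- seq_len(length(x$terms) - 1L)
    tibble::tibble(
      term = x$terms[-1],
      estimate = unname(x$coef_actual[-1]),
      estimate_coded = unname(x$coef_coded[-1]),
      df = a$Df[idx],
      sumsq = a$`Sum Sq`[idx],
      statistic = a$`F value`[idx],
      p.value = a$`Pr(>F)`[idx]
    )
  }
}

#' @rdname tidy.surface_fit
#' @return `glance()` returns a one-row tibble of fit summaries, including the
#'   overall-model and lack-of-fit F tests.
#' @method glance surface_fit
#' @export
glance.surface_fit <- function(x, ...) {
  a <- x$anova
  g <- function(src, col) a[[col]][a$source == src]
  tibble::tibble(
    response = x$response,
    model_class = x$model_class,
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    sigma = x$sigma,
    statistic = g("model", "statistic"),
    p.value = g("model", "p.value"),
    df = g("model", "df"),
    df.residual = g("residual", "df"),
    lof.statistic = g("lack_of_fit", "statistic"),
    lof.p.value = g("lack_of_fit", "p.value"),
    nobs = g("total", "df") + 1L
  )
}

#' Predict from a response-surface fit
#'
#' Evaluates the fitted polynomial at new factor settings given in actual
#' units. Settings outside the coded design region (coded radius greater than
#' the axial distance) are flagged as extrapolation via the `"extrapolated"`
#' attribute and a warning.
#'
#' @param object A `surface_fit`.
#' @param newdata Data frame with one actual-unit column per model factor
#'   (e.g. `lipid`, `surfactant`).
#' @param coded Set `TRUE` to evaluate through the coded-unit coefficient
#'   vector instead; results are identical to machine precision.
#' @param ... Unused.
#' @return Numeric vector of predictions with an `"extrapolated"` logical
#'   attribute.
#' @examples
#' study <- nlc_study()
#' fit <- fit_surface(study$design, study$responses, "particle_size", "PQ")
#' predict(fit, tibble::tibble(lipid = 268.4, surfactant = 553.4))
#' @export
predict.surface_fit <- function(object, newdata, coded = FALSE, ...) {
  ftab <- object$factors
  missing <- setdiff(ftab$name, names(newdata))
  if (length(missing)) {
    stop("`newdata` is missing factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  actual <- as.matrix(newdata[ftab$name])
  coded_m <- actual
  for (j in seq_len(nrow(ftab))) {
    coded_m[, j] <- code_value(actual[, j], ftab[j, ])
  }
  if (coded) {
    pred <- drop(surface_terms(coded_m, object$model_class) %*% object$coef_coded)
  } else {
    pred <- drop(surface_terms(actual, object$model_class) %*% object$coef_actual)
  }
  extrap <- sqrt(rowSums(coded_m^2)) > object$alpha + 1e-9
  if (any(extrap)) {
    warning(sum(extrap), " prediction point(s) outside the design region ",
            "(coded radius > alpha).", call. = FALSE)
  }
  attr(pred, "extrapolated") <- unname(extrap)
  pred
}

MODEL_CLASSES <- c("FO", "TWI", "PQ", "SO")

n_model_terms <- function(model_class, k) {
  switch(model_class,
         FO = k + 1L,
         TWI = k + 1L + choose(k, 2L),
         PQ = 2L * k + 1L,
         SO = 1L + 2L * k + choose(k, 2L),
         stop("Unknown model_class.", call. = FALSE))
}

#' Select a response-surface model class
#'
#' Fits each candidate class and applies the default selection rule: among
#' candidates whose overall-model F test is significant (`p < alpha_level`)
#' and whose lack-of-fit test does not reject (`p >= alpha_level` or is not
#' estimable), return the one with the highest adjusted R-squared, breaking
#' ties toward fewer terms. Adjusted R-squared values within `tie_tol` of the
#' best are treated as tied, so a nested model is preferred whenever the
#' extra terms buy nothing real. If no candidate qualifies, the best
#' candidate by adjusted R-squared is returned flagged
#' `no_significant_model`. An explicit `override` bypasses the rule and fits
#' that class directly, for reproducing a documented model choice.
#'
#' @inheritParams fit_surface
#' @param candidates Character vector of model classes to consider.
#' @param alpha_level Significance level for the F tests (default 0.05).
#' @param tie_tol Adjusted R-squared margin treated as a tie (default 1e-9).
#' @param override Optional model class string that short-circuits selection.
#' @return A list of class `surface_selection`: `fit` (the chosen
#'   `surface_fit`), `model_class`, `candidates` (per-candidate diagnostics
#'   tibble) and `no_significant_model` flag.
#' @examples
#' study <- nlc_study()
#' sel <- select_surface(study$design, study$responses, "particle_size")
#' sel$model_class
#' @export
select_surface <- function(design, responses, response,
                           candidates = MODEL_CLASSES, alpha_level = 0.05,
                           factors = NULL, tie_tol = 1e-9, override = NULL) {
  if (!length(candidates)) stop("`candidates` must be nonempty.", call. = FALSE)
  if (!is.null(override)) {
    fit <- fit_surface(design, responses, response, override, factors = factors)
    return(structure(list(fit = fit, model_class = override,
                          candidates = glance(fit),
                          no_significant_model = FALSE),
                     class = "surface_selection"))
  }
  fits <- lapply(candidates, function(mc) {
    tryCatch(fit_surface(design, responses, response, mc, factors = factors),
             error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (!length(fits)) stop("No candidate model could be fitted.", call. = FALSE)
  tab <- purrr::map_dfr(fits, glance)
  k <- if (is.null(factors)) nrow(design_factors(design)) else length(factors)
  tab$n_terms <- vapply(tab$model_class, n_model_terms, numeric(1), k = k)
  tab$passes <- !is.na(tab$p.value) & tab$p.value < alpha_level &
    (is.na(tab$lof.p.value) | tab$lof.p.value >= alpha_level)
  pool <- if (any(tab$passes)) which(tab$passes) else seq_len(nrow(tab))
  top <- max(tab$adj.r.squared[pool])
  finalists <- pool[tab$adj.r.squared[pool] >= top - tie_tol]
  best <- finalists[order(tab$n_terms[finalists],
                          -tab$adj.r.squared[finalists])][1]
  structure(list(fit = fits[[best]],
                 model_class = tab$model_class[best],
                 candidates = tab,
                 no_significant_model = !any(tab$passes)),
            class = "surface_selection")
}

#' @export
print.surface_selection <- function(x, ...) {
  cat(sprintf("Selected model class: %s%s\n", x$model_class,
              if (x$no_significant_model) " (no significant model)" else ""))
  print(x$candidates[, c("model_class", "adj.r.squared", "p.value", "lof.p.value")])
  invisible(x)
}
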