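#' Declare a design factor
#'
#' A factor is described by the actual-unit value of its centre point and the
#' step between coded 0 and coded ±1. All coded/actual conversions in the
#' package derive from these two numbers via `actual = center + coded * step`.
#'
#' @param name Factor name (used as a column prefix in design tibbles).
#' @param center Actual-unit value at coded level 0. Must be finite.
#' @param step Actual-unit distance from coded 0 to coded ±1. Must be > 0.
#' @param unit Measurement unit label (informational).
#'
#' @return A one-row tibble with columns `name`, `unit`, `center`, `step`.
#'   Bind several together with [dplyr::bind_rows()] to form a factor table.
#' @examples
#' lipid <- ccd_factor("lipid", center = 300, step = 100, unit = "mg")
#' surf  <- ccd_factor("surfactant", center = 400, step = 200, unit = "mg")
#' dplyr::bind_rows(lipid, surf)
#' @export
ccd_factor <- function(name, center, step, unit = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop("`center` must be a single finite number.", call. = FALSE)
  }
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop("`step` must be a single positive number.", call. = FALSE)
  }
  tibble::tibble(name = name, unit = as.character(unit),
                 center = as.numeric(center), step = as.numeric(step))
}

check_factors <- function(factors) {
  req <- c("name", "center", "step")
  if (!is.data.frame(factors) || !all(req %in% names(factors))) {
    stop("`factors` must be a data frame with columns name, center, step ",
         "(see `ccd_factor()`).", call. = FALSE)
  }
  if (anyDuplicated(factors$name)) {
    stop("Factor names must be unique.", call. = FALSE)
  }
  if (any(!is.finite(factors$center)) || any(!is.finite(factors$step)) ||
      any(factors$step <= 0)) {
    stop("Factor centers must be finite and steps positive.", call. = FALSE)
  }
  factors
}

#' Axial distance of a rotatable central composite design
#'
#' For a two-level factorial core in `k` factors, rotatability (prediction
#' variance depending only on distance from the design centre) requires the
#' axial points to sit at `(2^k)^(1/4)` in coded units.
#'
#' @param k Number of factors (positive integer).
#' @return The rotatable axial distance, a single number.
#' @examples
#' rotatable_alpha(2) # sqrt(2)
#' rotatable_alpha(4) # 2
#' @export
rotatable_alpha <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) ||
      k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1.", call. = FALSE)
  }
  (2^k)^(1 / 4)
}

#' Convert between coded and actual factor levels
#'
#' `code_value()` maps actual-unit settings to coded units
#' (`(x - center) / step`); `decode_value()` is its inverse.
#'
#' @param x Numeric vector of values to convert.
#' @param factor A one-row factor tibble from [ccd_factor()] (or any list with
#'   `center` and `step`).
#' @return Numeric vector of converted values.
#' @examples
#' lipid <- ccd_factor("lipid", 300, 100)
#' code_value(441.4, lipid)   # 1.414
#' decode_value(-1, ccd_factor("surfactant", 400, 200)) # 200
#' @export
code_value <- function(x, factor) {
  (x - factor$center[[1]]) / factor$step[[1]]
}

#' @rdname code_value
#' @export
decode_value <- function(x, factor) {
  factor$center[[1]] + x * factor$step[[1]]
}

#' Build a central composite design
#'
#' Constructs the standard CCD run list: a full two-level factorial core
#' (coded ±1), `2k` axial points at coded `±alpha`, and `n_center` replicated
#' centre runs. Centre replication is what provides a pure-error estimate for
#' the lack-of-fit test in [fit_surface()].
#'
#' Runs are emitted in canonical order (factorial, axial, center); supply
#' `seed` to randomize the run order reproducibly.
#'
#' @param factors Factor table built from [ccd_factor()] rows; `k = nrow(factors)`,
#'   at least 2.
#' @param n_center Number of centre replicates (>= 1).
#' @param alpha Either the string `"rotatable"` (axial distance
#'   `(2^k)^(1/4)`) or an explicit numeric axial distance >= 1.
#' @param seed Optional integer; if given, run order is shuffled with this seed.
#'
#' @return A `ccd_design` tibble with columns `run_id`, `point_type`
#'   (factorial/axial/center) and, per factor, `<name>_coded` and
#'   `<name>_actual`. The factor table and resolved alpha travel along as
#'   attributes `factors` and `alpha`.
#' @examples
#' factors <- dplyr::bind_rows(
#'   ccd_factor("lipid", 300, 100, "mg"),
#'   ccd_factor("surfactant", 400, 200, "mg")
#' )
#' des <- ccd_design(factors, n_center = 5)
#' table(des$point_type)
#' @export
ccd_design <- function(factors, n_center = 5, alpha = "rotatable", seed = NULL) {
  factors <- check_factors(factors)
  k <- nrow(factors)
  if (k < 2) stop("A central composite design needs k >= 2 factors.", call. = FALSE)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1 ||
      n_center != round(n_center)) {
    stop("`n_center` must be a positive integer.", call. = FALSE)
  }
  if (identical(alpha, "rotatable")) {
    alpha_val <- rotatable_alpha(k)
  } else if (is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
             alpha >= 1) {
    alpha_val <- as.numeric(alpha)
  } else {
    stop("`alpha` must be \"rotatable\" or a single number >= 1.", call. = FALSE)
  }

  # factorial core: all +/-1 combinations, first factor varying fastest
  core <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha_val
    axial[2L * j, j] <- alpha_val
  }
  center <- matrix(0, nrow = n_center, ncol = k)

  coded <- rbind(core, axial, center)
  colnames(coded) <- factors$name
  point_type <- rep(c("factorial", "axial", "center"),
                    c(nrow(core), nrow(axial), n_center))

  ord <- seq_len(nrow(coded))
  if (!is.null(seed)) {
    ord <- local({
      old <- .Random.seed_exists()
      on.exit(restore_seed(old), add = TRUE)
      set.seed(as.integer(seed))
      sample.int(nrow(coded))
    })
  }
  coded <- coded[ord, , drop = FALSE]
  point_type <- point_type[ord]

  out <- tibble::tibble(run_id = seq_len(nrow(coded)), point_type = point_type)
  for (j in seq_len(k)) {
    f <- factors[j, ]
    out[[paste0(f$name, "_coded")]] <- coded[, j]
    out[[paste0(f$name, "_actual")]] <- decode_value(coded[, j], f)
  }
  new_ccd_design(out, factors, alpha_val)
}

new_ccd_design <- function(tbl, factors, alpha) {
  structure(tbl,
            factors = factors,
            alpha = alpha,
            class = c("ccd_design", class(tibble::as_tibble(tbl))))
}

# save/restore the RNG state so seeded shuffles don't disturb the session RNG
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ccd_design <- function(x, ...) {
  factors <- attr(x, "factors")
  cat(sprintf("Central composite design: %d factors, %d runs (alpha = %.6g)\n",
              nrow(factors), nrow(x), attr(x, "alpha")))
  NextMethod()
}

#' Factor table and axial distance of a design
#'
#' @param design A `ccd_design` tibble.
#' @return `design_factors()` returns the factor tibble; `design_alpha()` the
#'   numeric axial distance.
#' @export
design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("Not a ccd_design: no factor table attached.", call. = FALSE)
  f
}

#' @rdname design_factors
#' @export
design_alpha <- function(design) {
  a <- attr(design, "alpha")
  if (is.null(a)) stop("Not a ccd_design: no alpha attached.", call. = FALSE)
  a
}

#' Coded and actual level matrices of a design
#'
#' @param design A `ccd_design` (or compatible) tibble.
#' @param which `"coded"` or `"actual"`.
#' @return Numeric matrix, runs by factors, columns named by factor.
#' @keywords internal
design_levels <- function(design, which = c("coded", "actual")) {
  which <- match.arg(which)
  factors <- design_factors(design)
  cols <- paste0(factors$name, "_", which)
  missing <- setdiff(cols, names(design))
  if (length(missing)) {
    stop("Design is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(design[cols])
  colnames(m) <- factors$name
  m
}

#' Write/read a design as CSV
#'
#' The CSV schema is `run_id, point_type, <name>_coded, <name>_actual` per
#' factor. `read_design_csv()` reconstructs the factor table (center and step)
#' from the coded/actual column pairs, so the round trip is lossless.
#'
#' @param design A `ccd_design` tibble.
#' @param path File path.
#' @return `write_design_csv()` returns `path` invisibly; `read_design_csv()`
#'   returns a `ccd_design`.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design), path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("run_id", "point_type")
  if (!all(req %in% names(tbl))) {
    stop("Design CSV must have run_id and point_type columns.", call. = FALSE)
  }
  coded_cols <- grep("_coded$", names(tbl), value = TRUE)
  fnames <- sub("_coded$", "", coded_cols)
  if (!length(fnames) || !all(paste0(fnames, "_actual") %in% names(tbl))) {
    stop("Design CSV must have <factor>_coded and <factor>_actual column pairs.",
         call. = FALSE)
  }
  factors <- purrr::map_dfr(fnames, function(nm) {
    coded <- tbl[[paste0(nm, "_coded")]]
    actual <- tbl[[paste0(nm, "_actual")]]
    # actual = center + coded*step: recover by least squares on the two columns
    fit <- stats::lm.fit(cbind(1, coded), actual)
    ccd_factor(nm, center = fit$coefficients[[1]], step = fit$coefficients[[2]])
  })
  coded <- as.matrix(tbl[paste0(fnames, "_coded")])
  r <- sqrt(rowSums(coded^2))
  alpha_val <- max(r[tbl$point_type == "axial"], 1)
  new_ccd_design(tbl, factors, alpha_val)
}
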