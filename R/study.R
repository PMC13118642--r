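#' Read a combined design/response table
#'
#' Parses a wide CSV holding one row per design run: `run_id`, `point_type`,
#' `<factor>_coded` / `<factor>_actual` column pairs, and per response a
#' `<response>_mean` column (optionally `<response>_sd` and a shared
#' `replicates` count). Columns are matched by header name, so column order is
#' irrelevant.
#'
#' @param path CSV file path.
#' @param factors Optional factor table from [ccd_factor()] rows; if omitted,
#'   centers and steps are reconstructed from the coded/actual column pairs.
#' @param alpha Optional axial distance; if omitted, taken as the largest
#'   coded radius among axial runs.
#' @return A list with elements `design` (a `ccd_design`) and `responses`
#'   (long tibble `run_id`, `response`, `mean`, `sd`, `n`).
#' @examples
#' study <- read_design_table(
#'   system.file("extdata", "nlc_ccd_study.csv", package = "nlcoptim")
#' )
#' study$design
#' @export
read_design_table <- function(path, factors = NULL, alpha = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(point_type = "c", .default = "d"))
  prob <- readr::problems(tbl)
  if (nrow(prob)) {
    bad_col <- if (is.numeric(prob$col[1])) names(tbl)[prob$col[1]] else prob$col[1]
    stop("Malformed cell in ", path, ": row ", prob$row[1], ", column '",
         bad_col, "' (expected ", prob$expected[1], ").", call. = FALSE)
  }
  req <- c("run_id", "point_type")
  missing <- setdiff(req, names(tbl))
  if (length(missing)) {
    stop("Missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(tbl)) stop("Design table is empty.", call. = FALSE)
  if (anyDuplicated(tbl$run_id)) {
    stop("Duplicate run_id: ",
         paste(unique(tbl$run_id[duplicated(tbl$run_id)]), collapse = ", "),
         call. = FALSE)
  }
  coded_cols <- grep("_coded$", names(tbl), value = TRUE)
  fnames <- sort(sub("_coded$", "", coded_cols)) # header-keyed: order-free
  if (!length(fnames) || !all(paste0(fnames, "_actual") %in% names(tbl))) {
    stop("Need <factor>_coded and <factor>_actual column pairs.", call. = FALSE)
  }
  for (col in names(tbl)[names(tbl) != "point_type"]) {
    if (anyNA(tbl[[col]])) {
      stop("Non-numeric or missing cell in column '", col, "', row ",
           which(is.na(tbl[[col]]))[1], ".", call. = FALSE)
    }
  }

  if (is.null(factors)) {
    factors <- purrr::map_dfr(fnames, function(nm) {
      fit <- stats::lm.fit(cbind(1, tbl[[paste0(nm, "_coded")]]),
                           tbl[[paste0(nm, "_actual")]])
      ccd_factor(nm, center = fit$coefficients[[1]], step = fit$coefficients[[2]])
    })
  } else {
    factors <- check_factors(factors)
  }
  if (is.null(alpha)) {
    coded <- as.matrix(tbl[paste0(fnames, "_coded")])
    r <- sqrt(rowSums(coded^2))
    alpha <- max(r[tbl$point_type == "axial"], 1)
  }
  design_cols <- c("run_id", "point_type",
                   as.vector(rbind(paste0(fnames, "_coded"),
                                   paste0(fnames, "_actual"))))
  design <- new_ccd_design(tbl[design_cols], factors, alpha)

  mean_cols <- grep("_mean$", names(tbl), value = TRUE)
  rnames <- sort(sub("_mean$", "", mean_cols))
  responses <- purrr::map_dfr(rnames, function(rn) {
    tibble::tibble(
      run_id = tbl$run_id,
      response = rn,
      mean = tbl[[paste0(rn, "_mean")]],
      sd = if (paste0(rn, "_sd") %in% names(tbl)) tbl[[paste0(rn, "_sd")]] else NA_real_,
      n = if ("replicates" %in% names(tbl)) as.integer(tbl$replicates) else NA_integer_
    )
  })
  list(design = design, responses = responses)
}

#' Packaged 13-run formulation optimization study
#'
#' The central composite design used to optimize an NLC formulation of
#' stiripentol and cannabidiol: two factors (solid lipid amount, centre 300 mg,
#' step 100 mg; surfactant amount, centre 400 mg, step 200 mg), four factorial
#' runs, four axial runs at coded +/-1.414 and five centre replicates, with
#' three measured responses per run (particle size, nm; polydispersity index;
#' zeta potential, mV), each the mean +/- SD of three analytical replicates.
#'
#' @return A list with `design` (a `ccd_design`) and `responses` (long tibble).
#' @examples
#' study <- nlc_study()
#' dplyr::count(study$design, point_type)
#' @export
nlc_study <- function() {
  path <- system.file("extdata", "nlc_ccd_study.csv", package = "nlcoptim")
  factors <- dplyr::bind_rows(
    ccd_factor("lipid", center = 300, step = 100, unit = "mg"),
    ccd_factor("surfactant", center = 400, step = 200, unit = "mg")
  )
  read_design_table(path, factors = factors, alpha = rotatable_alpha(2))
}

#' Packaged single-dose oral PK parameter table
#'
#' Non-compartmental parameters (Cmax mg/L, Tmax h, AUC 0-24 h mg.h/L)
#' for stiripentol and cannabidiol after single oral doses of the optimized
#' NLC formulation and of the corresponding commercial products, as reported
#' in the source study.
#'
#' @return Tibble with columns `drug`, `formulation`, `cmax`, `tmax`, `auc`.
#' @examples
#' nlc_pk_parameters()
#' @export
nlc_pk_parameters <- function() {
  readr::read_csv(
    system.file("extdata", "nlc_pk_parameters.csv", package = "nlcoptim"),
    show_col_types = FALSE
  )
}

#' Run the full design-to-optimum workflow
#'
#' Chains the analysis stages on a design/response study: per-response model
#' selection (or an explicit per-response override), desirability construction
#' from observed response ranges, optimization over the coded design region,
#' and (optionally) validation against measured values at the optimum.
#'
#' @param design A `ccd_design`.
#' @param responses Long response tibble (`run_id`, `response`, `mean`, ...).
#' @param goals Goal per response for [desirability_spec()] (default
#'   `"minimize"` for all).
#' @param candidates Model classes considered during selection.
#' @param alpha_level Significance level for selection F tests.
#' @param overrides Optional named list, one entry per response to pin:
#'   `list(model_class = , factors = )`.
#' @param region,n_grid Passed to [optimize_desirability()].
#' @param measured Optional named numeric vector of measured responses for a
#'   validation record.
#' @return An `rsm_pipeline` list: `models`, `selection` (per-candidate
#'   diagnostics), `optimum`, `validation` (or `NULL`), `D`.
#' @examples
#' study <- nlc_study()
#' pipe <- run_rsm_pipeline(
#'   study$design, study$responses,
#'   overrides = list(
#'     particle_size = list(model_class = "PQ"),
#'     pdi = list(model_class = "SO"),
#'     z_potential = list(model_class = "FO", factors = "surfactant")
#'   ),
#'   n_grid = 101
#' )
#' pipe$D
#' @export
run_rsm_pipeline <- function(design, responses, goals = "minimize",
                             candidates = MODEL_CLASSES, alpha_level = 0.05,
                             overrides = NULL, region = "box", n_grid = 401,
                             measured = NULL) {
  resp_names <- unique(responses$response)
  models <- list()
  selection <- list()
  for (rn in resp_names) {
    ov <- overrides[[rn]]
    sel <- tryCatch(
      if (!is.null(ov)) {
        select_surface(design, responses, rn, alpha_level = alpha_level,
                       factors = ov$factors, override = ov$model_class)
      } else {
        select_surface(design, responses, rn, candidates = candidates,
                       alpha_level = alpha_level)
      },
      error = function(e) {
        stop("Model stage failed for response '", rn, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    models[[rn]] <- sel$fit
    selection[[rn]] <- dplyr::mutate(sel$candidates, selected =
                                       .data$model_class == sel$model_class)
  }
  spec <- desirability_spec(responses, goals)
  optimum <- optimize_desirability(models, spec, region = region,
                                   n_grid = n_grid)
  validation <- if (!is.null(measured)) validate_optimum(optimum, measured)
  structure(list(models = models,
                 selection = dplyr::bind_rows(selection),
                 spec = spec,
                 optimum = optimum,
                 validation = validation,
                 D = optimum$D),
            class = "rsm_pipeline")
}

#' @export
print.rsm_pipeline <- function(x, ...) {
  cat("Response-surface optimization pipeline\n")
  for (rn in names(x$models)) {
    m <- x$models[[rn]]
    cat(sprintf("  %s: %s model, adj. R2 = %.3f\n",
                rn, m$model_class, m$adj_r_squared))
  }
  print(x$optimum)
  if (!is.null(x$validation)) {
    cat("Validation:\n"); print(x$validation)
  }
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' Writes models (class, coefficients in both unit systems, ANOVA), the
#' optimum (settings, predictions, desirabilities, D) and any validation
#' record. Numbers keep full precision, so repeated runs with the same inputs
#' produce byte-identical files.
#'
#' @param pipeline An `rsm_pipeline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_json <- function(pipeline, path) {
  payload <- list(
    models = purrr::map(pipeline$models, function(m) {
      list(response = m$response,
           model_class = m$model_class,
           terms = m$terms,
           coef_actual = as.list(m$coef_actual),
           coef_coded = as.list(m$coef_coded),
           r_squared = m$r_squared,
           adj_r_squared = m$adj_r_squared,
           anova = m$anova)
    }),
    desirability_spec = pipeline$spec,
    optimum = list(settings = pipeline$optimum$settings,
                   responses = pipeline$optimum$responses,
                   D = pipeline$optimum$D,
                   diagnostics = pipeline$optimum$diagnostics[
                     c("method", "region", "n_grid", "grid_D", "boundary")]),
    validation = pipeline$validation
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
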