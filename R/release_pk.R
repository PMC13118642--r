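#' Cumulative release from sequential-sampling dissolution data
#'
#' In a fixed-volume-replacement release assay, each withdrawn sample removes
#' drug that later concentration readings no longer see. The standard
#' running-sum correction restores the mass balance:
#' `C'_n = C_n + (V_sample / V_total) * sum_{i<n} C_i`, and the cumulative
#' released percent is `C'_n * V_total / dose * 100`.
#'
#' Values exceeding 100 % (beyond `tolerance`) are flagged, not clamped:
#' they usually indicate assay or mass-balance problems worth seeing.
#'
#' @param release Data frame with columns `time_h` (strictly increasing) and
#'   `conc_mg_ml` (sampled in-vessel concentration, mg/mL).
#' @param v_total Vessel volume (mL).
#' @param v_sample Withdrawn sample volume (mL), `0 <= v_sample < v_total`.
#' @param dose_mg Drug mass initially present in the vessel (mg), > 0.
#' @param tolerance Percent slack above 100 before flagging (default 0.5).
#' @return The input tibble with added columns `conc_corrected`,
#'   `cumulative_pct` and `over_release` (logical flag).
#' @examples
#' rel <- tibble::tibble(time_h = c(0.5, 1, 2), conc_mg_ml = c(0.2, 0.35, 0.5))
#' cumulative_release(rel, v_total = 10, v_sample = 0.5, dose_mg = 5)
#' @export
cumulative_release <- function(release, v_total, v_sample, dose_mg,
                               tolerance = 0.5) {
  req <- c("time_h", "conc_mg_ml")
  if (!all(req %in% names(release))) {
    stop("`release` needs columns time_h and conc_mg_ml.", call. = FALSE)
  }
  stopifnot(v_total > 0, v_sample >= 0, v_sample < v_total, dose_mg > 0)
  if (any(diff(release$time_h) <= 0)) {
    stop("time_h must be strictly increasing.", call. = FALSE)
  }
  if (any(release$conc_mg_ml < 0)) {
    stop("Concentrations must be nonnegative.", call. = FALSE)
  }
  conc <- release$conc_mg_ml
  prior <- c(0, cumsum(conc)[-length(conc)])
  corrected <- conc + (v_sample / v_total) * prior
  pct <- corrected * v_total / dose_mg * 100
  out <- tibble::as_tibble(release)
  out$conc_corrected <- corrected
  out$cumulative_pct <- pct
  out$over_release <- pct > 100 + tolerance
  if (any(out$over_release)) {
    warning(sum(out$over_release),
            " time point(s) exceed 100% cumulative release.", call. = FALSE)
  }
  out
}

#' Non-compartmental pharmacokinetic summary
#'
#' Model-free summary of a mean concentration-time profile: maximum observed
#' concentration (Cmax), its time (Tmax, earliest on ties), and the area under
#' the curve by the linear trapezoidal rule from time 0 to the last sampling
#' time. For extravascular dosing the concentration at the dosing instant is
#' taken as zero (`assume_zero_at_dose = TRUE`, the default) unless a
#' measurement at t = 0 is supplied.
#'
#' @param profile Data frame with columns `time_h` (strictly increasing,
#'   nonnegative) and `conc` (mean concentration, e.g. mg/L); at least two
#'   time points.
#' @param assume_zero_at_dose Prepend C(0) = 0 when the first sample is after
#'   t = 0 (default `TRUE`).
#' @return One-row tibble: `cmax`, `tmax`, `auc` (concentration-units x h),
#'   `t_last`, `n_points`.
#' @examples
#' prof <- tibble::tibble(time_h = c(0.5, 1, 2, 4, 8, 24),
#'                        conc = c(0.8, 1.27, 1.1, 0.7, 0.35, 0.05))
#' nca(prof)
#' @export
nca <- function(profile, assume_zero_at_dose = TRUE) {
  req <- c("time_h", "conc")
  if (!all(req %in% names(profile))) {
    stop("`profile` needs columns time_h and conc.", call. = FALSE)
  }
  t <- profile$time_h
  c_ <- profile$conc
  if (length(t) < 2L) stop("At least two time points are required.", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time_h must be strictly increasing.", call. = FALSE)
  if (any(t < 0) || any(c_ < 0)) {
    stop("Times and concentrations must be nonnegative.", call. = FALSE)
  }
  i_max <- which.max(c_) # which.max returns the earliest maximum
  cmax <- c_[i_max]
  tmax <- t[i_max]
  if (assume_zero_at_dose && t[1] > 0) {
    t <- c(0, t)
    c_ <- c(0, c_)
  }
  auc <- sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
  tibble::tibble(cmax = cmax, tmax = tmax, auc = auc,
                 t_last = max(t), n_points = nrow(profile))
}

#' Fold change between two NCA results
#'
#' Per-parameter ratios `a / b` and percent increases `100 * (a - b) / b`,
#' e.g. an optimized formulation (`a`) against a reference product (`b`).
#'
#' @param a,b One-row NCA tibbles (see [nca()]) or named lists/vectors with
#'   `cmax`, `tmax`, `auc`.
#' @return Tibble with one row per parameter: `parameter`, `a`, `b`, `ratio`,
#'   `increase_pct`.
#' @examples
#' profile_fold_change(list(cmax = 1.27, tmax = 1, auc = 8.0),
#'                     list(cmax = 0.61, tmax = 0.5, auc = 5.4))
#' @export
profile_fold_change <- function(a, b) {
  params <- c("cmax", "tmax", "auc")
  av <- vapply(params, function(p) as.numeric(a[[p]]), numeric(1))
  bv <- vapply(params, function(p) as.numeric(b[[p]]), numeric(1))
  if (any(!is.finite(bv)) || any(bv == 0)) {
    stop("Reference parameters must be nonzero for fold changes.", call. = FALSE)
  }
  av <- unname(av)
  bv <- unname(bv)
  tibble::tibble(
    parameter = params,
    a = av,
    b = bv,
    ratio = av / bv,
    increase_pct = 100 * (av - bv) / bv
  )
}
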