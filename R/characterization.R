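#' Entrapment efficiency
#'
#' Percent of the loaded drug that is not found free in the external aqueous
#' phase after separating the nanoparticles:
#' `%EE = (W0 - Cfd * Vf) / W0 * 100`.
#'
#' @param w0 Initial drug mass loaded into the formulation (mg), > 0.
#' @param c_fd Free-drug concentration measured in the filtrate (mg/mL).
#' @param v_f Final formulation volume (mL).
#' @return Entrapment efficiency in percent.
#' @examples
#' entrapment_efficiency(w0 = 100, c_fd = 0.05, v_f = 10) # 99.5
#' @export
entrapment_efficiency <- function(w0, c_fd, v_f) {
  stopifnot(w0 > 0, c_fd >= 0, v_f >= 0)
  free <- c_fd * v_f
  if (any(free > w0 + 1e-9)) {
    stop("Free drug mass (Cfd * Vf) exceeds the loaded mass W0: ",
         "inconsistent formulation record.", call. = FALSE)
  }
  (w0 - free) / w0 * 100
}

#' Total lipid-matrix mass of a formulation
#'
#' Solid lipid mass plus the mass contributed by the structuring oil
#' (volume times density).
#'
#' @param solid_lipid_mg Solid lipid mass (mg).
#' @param oil_volume_ul Oil volume (microlitre); default 0.
#' @param oil_density Oil density in g/mL (default 0.92, a typical
#'   vegetable-oil value).
#' @return Lipid mass in mg.
#' @examples
#' lipid_mass(268.4, oil_volume_ul = 50) # 314.4
#' @export
lipid_mass <- function(solid_lipid_mg, oil_volume_ul = 0, oil_density = 0.92) {
  stopifnot(solid_lipid_mg >= 0, oil_volume_ul >= 0, oil_density > 0)
  solid_lipid_mg + oil_volume_ul * oil_density # uL * g/mL == mg
}

#' Drug loading
#'
#' Entrapped drug mass relative to the lipid-matrix mass:
#' `%DL = (W0 - Cfd * Vf) / lipid_mass * 100`, where the lipid mass includes
#' both the solid lipid and the oil phase (see [lipid_mass()]).
#'
#' @inheritParams entrapment_efficiency
#' @inheritParams lipid_mass
#' @return Drug loading in percent.
#' @examples
#' drug_loading(100, 0, 10, solid_lipid_mg = 268.4, oil_volume_ul = 50) # 31.8
#' drug_loading(5, 0, 10, solid_lipid_mg = 268.4, oil_volume_ul = 50)   # 1.6
#' @export
drug_loading <- function(w0, c_fd, v_f, solid_lipid_mg, oil_volume_ul = 0,
                         oil_density = 0.92) {
  lm_mg <- lipid_mass(solid_lipid_mg, oil_volume_ul, oil_density)
  if (lm_mg <= 0) stop("Lipid mass must be positive.", call. = FALSE)
  entrapped <- w0 - c_fd * v_f
  if (any(entrapped < -1e-9)) {
    stop("Free drug mass exceeds the loaded mass W0.", call. = FALSE)
  }
  entrapped / lm_mg * 100
}

#' Integrate a DSC endotherm
#'
#' Enthalpy of a melting event from a mass-normalized heat-flow signal:
#' within the requested temperature window, a straight baseline joining the
#' signal at the window endpoints is subtracted, and the remainder is
#' integrated over time by the trapezoidal rule. Because the heating rate is
#' constant, integration over time (s) of a mW/mg signal yields mJ/mg, and
#' 1 mJ/mg is identically 1 J/g — the scale on which reference melting
#' enthalpies are tabulated.
#'
#' @param thermogram Data frame with columns `time_s` (strictly increasing),
#'   `temp_c` (affine in time) and `heat_flow` (mW/mg).
#' @param window Length-2 numeric temperature interval (degrees C) inside the
#'   thermogram range.
#' @return Enthalpy in J/g (positive for a peak above the baseline).
#' @examples
#' tg <- tibble::tibble(
#'   time_s = 0:300, temp_c = 20 + (0:300) / 3,
#'   heat_flow = pmax(0, 1 - abs(0:300 - 150) / 60)
#' )
#' integrate_endotherm(tg, window = c(40, 100))
#' @export
integrate_endotherm <- function(thermogram, window) {
  req <- c("time_s", "temp_c", "heat_flow")
  if (!all(req %in% names(thermogram))) {
    stop("`thermogram` needs columns time_s, temp_c, heat_flow.", call. = FALSE)
  }
  t <- thermogram$time_s
  temp <- thermogram$temp_c
  hf <- thermogram$heat_flow
  if (any(diff(t) <= 0)) stop("time_s must be strictly increasing.", call. = FALSE)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("`window` must be an increasing temperature interval.", call. = FALSE)
  }
  if (window[1] < min(temp) || window[2] > max(temp)) {
    stop("`window` endpoints lie outside the thermogram range.", call. = FALSE)
  }
  sel <- temp >= window[1] & temp <= window[2]
  ts <- t[sel]
  hs <- hf[sel]
  if (sum(sel) < 2L) stop("Window contains fewer than 2 samples.", call. = FALSE)
  # linear baseline joining the window endpoints
  base <- hs[1] + (hs[length(hs)] - hs[1]) * (ts - ts[1]) / (ts[length(ts)] - ts[1])
  net <- hs - base
  sum(diff(ts) * (utils::head(net, -1) + utils::tail(net, -1)) / 2) # mJ/mg == J/g
}

#' Crystallinity index
#'
#' Melting enthalpy of the lipid in the nanoparticle dispersion relative to
#' the reference enthalpy of the pure lipid, corrected for the lipid fraction
#' of the dispersion: `CI% = dH_dispersion / (dH_reference * lipid_fraction) * 100`.
#'
#' @param dh_dispersion Melting enthalpy measured on the dispersion (J/g of
#'   sample).
#' @param dh_reference Melting enthalpy of the pure (fully crystalline) lipid
#'   (J/g of lipid), > 0. Default 234.5 J/g, the reference value for myristyl
#'   myristate.
#' @param lipid_fraction Mass fraction of lipid in the dispersion, in (0, 1].
#'   Default 0.0268 (a 2.68 % w/w lipid phase).
#' @return Crystallinity index in percent.
#' @examples
#' crystallinity_index(0.5731) # 9.12
#' @export
crystallinity_index <- function(dh_dispersion, dh_reference = 234.5,
                                lipid_fraction = 0.0268) {
  stopifnot(dh_reference > 0, lipid_fraction > 0, lipid_fraction <= 1)
  dh_dispersion / (dh_reference * lipid_fraction) * 100
}
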