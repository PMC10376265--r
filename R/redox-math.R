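# Core ratiometric redox algebra: calibration state, degree of oxidation,
# and Nernst potentials for the roGFP2 probe and the glutathione couple.

#' Physical and probe constants for the Nernst equation
#'
#' Bundles the gas constant, absolute temperature, electron count and Faraday
#' constant used to convert a degree of oxidation into a redox potential,
#' together with the probe and glutathione-couple midpoint potentials and the
#' total glutathione concentration.  With the defaults, `RT/zF` evaluates to
#' approximately 12.848 mV.
#'
#' The probe midpoint default (-279.2 mV) sits in the accepted roGFP2
#' literature range (about -280 mV) and is shared by the synthetic-data
#' generator so that simulated scenarios and their analysis are
#' self-consistent; override it for instruments calibrated against a
#' different reference.
#'
#' @param e0_probe_mV Midpoint potential of the roGFP2 probe, mV.
#' @param e0_gsh_mV Midpoint potential of the glutathione couple, mV.
#' @param gsh_total_M Total glutathione concentration, molar.
#' @param temp_K Absolute temperature, K.
#'
#' @return An object of class `nernst_constants`: a list with the constants
#'   and the derived slope `rt_zf_mV` (mV per natural-log unit).
#' @examples
#' nc <- nernst_constants()
#' nc$rt_zf_mV # ~ 12.848
#' @export
nernst_constants <- function(e0_probe_mV = -279.2,
                             e0_gsh_mV = -240,
                             gsh_total_M = 2.5e-3,
                             temp_K = 298.15) {
  stopifnot(is.numeric(e0_probe_mV), is.numeric(e0_gsh_mV),
            gsh_total_M > 0, temp_K > 0)
  out <- list(
    r_gas = 8.315,        # J K^-1 mol^-1
    temp_K = temp_K,
    z = 2,                # electrons exchanged
    faraday = 9.648e4,    # C mol^-1
    e0_probe_mV = e0_probe_mV,
    e0_gsh_mV = e0_gsh_mV,
    gsh_total_M = gsh_total_M
  )
  out$rt_zf_mV <- 1000 * out$r_gas * out$temp_K / (out$z * out$faraday)
  structure(out, class = "nernst_constants")
}

#' Calibration state of the roGFP2 probe
#'
#' Holds the two calibration endpoints of the excitation ratio and the
#' instrument factor `k`.  `r_red` and `r_ox` are the 405/488 ratios of the
#' fully reduced (DTT-treated) and fully oxidised (H2O2-treated) probe.
#' `i488_min` and `i488_max` are the 488-nm excitation intensities of the
#' probe in the states where that signal is minimal and maximal: 488-nm
#' fluorescence is weakest for the oxidised probe, so `i488_min` comes from
#' the oxidised reference set and `i488_max` from the reduced one, and
#' `k = i488_min / i488_max` is the factor that makes the degree-of-oxidation
#' formula satisfy OxD(r_red) = 0 and OxD(r_ox) = 1.
#'
#' @param r_red,r_ox Ratios of the fully reduced / fully oxidised probe.
#' @param i488_min,i488_max 488-nm intensities of the oxidised / reduced
#'   probe (arbitrary units).  May be omitted when `k` is given directly.
#' @param k Instrument factor `i488_min / i488_max`; computed from the
#'   intensities when not supplied.
#'
#' @return An object of class `calibration_state`.
#' @examples
#' calibration_state(r_red = 0.2, r_ox = 2.0, k = 0.5)
#' @export
calibration_state <- function(r_red, r_ox, i488_min = NULL, i488_max = NULL,
                              k = NULL) {
  if (is.null(k)) {
    if (is.null(i488_min) || is.null(i488_max)) {
      stop("supply either `k` or both `i488_min` and `i488_max`",
           call. = FALSE)
    }
    k <- i488_min / i488_max
  }
  out <- structure(
    list(r_red = r_red, r_ox = r_ox,
         i488_min = i488_min %||% NA_real_,
         i488_max = i488_max %||% NA_real_,
         k = k),
    class = "calibration_state"
  )
  validate_calibration(out)
  out
}

validate_calibration <- function(calib) {
  if (!inherits(calib, "calibration_state")) {
    stop("`calib` must be a calibration_state object", call. = FALSE)
  }
  if (!is.finite(calib$k) || calib$k <= 0) {
    stop("invalid calibration: instrument factor k must be > 0",
         call. = FALSE)
  }
  if (!(calib$r_ox > calib$r_red)) {
    stop("invalid calibration: r_ox must exceed r_red ",
         "(signals swapped or failed calibration treatments?)",
         call. = FALSE)
  }
  if (!is.na(calib$i488_min) && calib$i488_min <= 0) {
    stop("invalid calibration: i488_min must be positive", call. = FALSE)
  }
  if (!is.na(calib$i488_max) && calib$i488_max <= 0) {
    stop("invalid calibration: i488_max must be positive", call. = FALSE)
  }
  invisible(calib)
}

#' @export
print.calibration_state <- function(x, ...) {
  cat("<calibration_state>\n")
  cat(sprintf("  r_red = %.6g, r_ox = %.6g, k = %.6g\n", x$r_red, x$r_ox, x$k))
  if (!is.na(x$i488_min)) {
    cat(sprintf("  i488_min (oxidised) = %.6g, i488_max (reduced) = %.6g\n",
                x$i488_min, x$i488_max))
  }
  invisible(x)
}

#' Degree of oxidation from a calibrated excitation ratio
#'
#' Converts 405/488 excitation ratios into the fraction of roGFP2 molecules
#' in the oxidised state:
#'
#' \deqn{OxD = \frac{R - R_{red}}{k\,(R_{ox} - R) + (R - R_{red})}}
#'
#' which satisfies OxD(`r_red`) = 0 and OxD(`r_ox`) = 1 and is strictly
#' increasing in between.  Ratios outside the calibrated range arise
#' routinely from noise; they are clamped to the endpoints with a warning
#' rather than rejected.
#'
#' @param r Numeric vector of 405/488 ratios.
#' @param calib A [calibration_state()].
#' @param clamp Clamp out-of-range ratios to `[r_red, r_ox]` (default) instead
#'   of returning values outside `[0, 1]`.
#' @return Numeric vector of oxidation degrees in `[0, 1]`.
#' @examples
#' cal <- calibration_state(0.2, 2.0, k = 0.5)
#' compute_oxd(1.1, cal) # 0.6667
#' @export
compute_oxd <- function(r, calib, clamp = TRUE) {
  validate_calibration(calib)
  if (clamp) {
    n_out <- sum(r < calib$r_red | r > calib$r_ox, na.rm = TRUE)
    if (n_out > 0) {
      warning(sprintf(
        "%d ratio(s) outside the calibrated range [%.4g, %.4g] were clamped",
        n_out, calib$r_red, calib$r_ox))
      r <- pmin(pmax(r, calib$r_red), calib$r_ox)
    }
  }
  num <- r - calib$r_red
  num / (calib$k * (calib$r_ox - r) + num)
}

#' Excitation ratio corresponding to a degree of oxidation
#'
#' Algebraic inverse of [compute_oxd()], used by the synthetic-data generator
#' to paint pixels whose downstream analysis recovers a known oxidation
#' degree:
#' \deqn{R = \frac{(1-OxD)\,R_{red} + OxD\,k\,R_{ox}}{(1-OxD) + OxD\,k}}
#'
#' @param oxd Numeric vector of oxidation degrees in `[0, 1]`.
#' @inheritParams compute_oxd
#' @return Numeric vector of ratios in `[r_red, r_ox]`.
#' @examples
#' cal <- calibration_state(0.2, 2.0, k = 0.5)
#' invert_ratio(2 / 3, cal) # 1.1
#' compute_oxd(invert_ratio(0.37, cal), cal) # round-trips
#' @export
invert_ratio <- function(oxd, calib) {
  validate_calibration(calib)
  if (any(oxd < 0 | oxd > 1, na.rm = TRUE)) {
    stop("`oxd` must lie in [0, 1]", call. = FALSE)
  }
  ((1 - oxd) * calib$r_red + oxd * calib$k * calib$r_ox) /
    ((1 - oxd) + oxd * calib$k)
}

#' Probe redox potential from the degree of oxidation
#'
#' Nernst equation for the roGFP2 probe:
#' \deqn{E = E^{0'}_{probe} - \frac{RT}{zF}\,
#'       \ln\frac{1 - OxD}{OxD}}
#' The potential is undefined at the boundaries; callers working with noisy
#' estimates should clamp OxD into `[eps, 1 - eps]` first (as
#' [run_redox_timecourse()] does).
#'
#' @param oxd Oxidation degrees strictly inside (0, 1).
#' @param constants A [nernst_constants()].
#' @return Potentials in mV (more negative = more reduced).
#' @examples
#' compute_e_probe(0.5, nernst_constants()) # equals the midpoint potential
#' @export
compute_e_probe <- function(oxd, constants = nernst_constants()) {
  stopifnot(inherits(constants, "nernst_constants"))
  if (any(oxd <= 0 | oxd >= 1, na.rm = TRUE)) {
    stop("potential undefined: `oxd` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  constants$e0_probe_mV - constants$rt_zf_mV * log((1 - oxd) / oxd)
}

#' Glutathione-couple redox potential from its degree of oxidation
#'
#' Concentration-dependent Nernst equation for the 2GSH/GSSG couple:
#' \deqn{E_{GSH} = E^{0'}_{GSH} - \frac{RT}{zF}\,
#'       \ln\frac{2\,[GSH]_{tot}\,(1 - OxD)^2}{OxD}}
#' with the total glutathione concentration in molar.  Assuming probe-couple
#' equilibration, the probe OxD is used as the couple OxD.
#'
#' @inheritParams compute_e_probe
#' @param oxd_gsh Oxidation degree of the glutathione couple, strictly in
#'   (0, 1).
#' @return Potentials in mV.
#' @export
compute_e_gsh <- function(oxd_gsh, constants = nernst_constants()) {
  stopifnot(inherits(constants, "nernst_constants"),
            constants$gsh_total_M > 0)
  if (any(oxd_gsh <= 0 | oxd_gsh >= 1, na.rm = TRUE)) {
    stop("potential undefined: `oxd_gsh` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  arg <- 2 * constants$gsh_total_M * (1 - oxd_gsh)^2 / oxd_gsh
  constants$e0_gsh_mV - constants$rt_zf_mV * log(arg)
}

# logit helpers used throughout the generator (kept explicit so that the
# truth-trajectory algebra reads like the equations in the vignette)
logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)
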