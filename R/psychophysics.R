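#' Odor activity value
#'
#' OAV is the ratio of an odorant's gas-phase concentration to its odor
#' threshold; `OAV = 1` marks the perception threshold.
#'
#' @param concentration concentration in mg/m\eqn{^3}, `>= 0`.
#' @param threshold odor threshold in mg/m\eqn{^3}, `> 0`.
#' @return `concentration / threshold` (dimensionless), vectorized.
#' @examples
#' oav(0.38, 0.19)
#' @export
oav <- function(concentration, threshold) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("`concentration` must be finite and >= 0.", "odormix_domain_error")
  }
  if (any(!is.finite(threshold)) || any(threshold <= 0)) {
    abort("`threshold` must be finite and > 0.", "odormix_domain_error")
  }
  concentration / threshold
}

#' Natural logarithm of an odor activity value
#'
#' The psychophysical law and the mixture models all work on the natural-log
#' scale (`lnOAV`), never log10.
#'
#' @param oav_value dimensionless OAV, `> 0`.
#' @return `log(oav_value)`, vectorized.
#' @examples
#' ln_oav(2)
#' @export
ln_oav <- function(oav_value) {
  if (any(!is.finite(oav_value)) || any(oav_value <= 0)) {
    abort(paste0(
      "`oav_value` must be > 0: lnOAV is undefined at zero concentration. ",
      "Treat such a component as absent (see the sub-threshold policy of ",
      "`predict_oi()`)."), "odormix_domain_error")
  }
  log(oav_value)
}

#' Individual-odorant odor intensity
#'
#' The log-linear psychophysical law `OI = k * lnOAV`: each ln-unit of odor
#' activity adds `k` units of perceived intensity on the odor intensity
#' referencing scale (OIRS). The default slope `k = 1.07` was fitted on
#' aromatic compounds; other chemical families need their own calibration
#' (see [calibrate()]). Sub-threshold input (`ln_oav < 0`) yields a negative
#' value, reported faithfully; clamping is the caller's policy.
#'
#' @param ln_oav dimensionless lnOAV, finite; vectorized.
#' @param k psychophysical slope, `> 0`.
#' @return Odor intensity on the OIRS scale.
#' @examples
#' oi_individual(3.83)          # the strongest component of an E+P+S mixture
#' oi_individual(0)             # at threshold, OI = 0
#' @export
oi_individual <- function(ln_oav, k = 1.07) {
  check_slope_k(k)
  if (any(!is.finite(ln_oav))) {
    abort("`ln_oav` must be finite.", "odormix_domain_error")
  }
  k * ln_oav
}

#' Convert a gas-phase mixing ratio (ppm) to mg/m3
#'
#' Ideal-gas conversion `mg/m3 = ppm * MW * P / (R * T)` with
#' `R = 0.082057 L atm mol^-1 K^-1`; at 298.15 K and 1 atm this is the
#' familiar `ppm * MW / 24.465`. Convenience for users whose monitoring data
#' are in ppm; thresholds in the registry are always mg/m\eqn{^3}.
#'
#' @param ppm mixing ratio in parts per million, `>= 0`.
#' @param molecular_weight g/mol, `> 0`.
#' @param temperature Kelvin, `> 0`.
#' @param pressure atm, `> 0`.
#' @return Concentration in mg/m\eqn{^3}, vectorized.
#' @examples
#' ppm_to_mg_m3(1, 92.14)   # 1 ppm toluene at 25 degC, 1 atm
#' @export
ppm_to_mg_m3 <- function(ppm, molecular_weight, temperature = 298.15,
                         pressure = 1) {
  if (any(!is.finite(ppm)) || any(ppm < 0)) {
    abort("`ppm` must be finite and >= 0.", "odormix_domain_error")
  }
  if (any(molecular_weight <= 0) || any(temperature <= 0) ||
      any(pressure <= 0)) {
    abort("molecular weight, temperature and pressure must all be > 0.",
          "odormix_domain_error")
  }
  ppm * molecular_weight * pressure / (0.082057 * temperature)
}
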