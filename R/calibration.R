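#' Least-squares slope through the origin
#'
#' Fits the proportional law `y = slope * x` with no intercept:
#' `slope = sum(x*y) / sum(x^2)`. Both calibration fits use this form — the
#' psychophysical law must pass through `OI = 0` at `lnOAV = 0` (an odorant
#' at its threshold is just perceivable), and the counteraction law through
#' `OI_mea = 0` at `OI_sum = 0`.
#'
#' @param x,y numeric vectors of equal length, `>= 2` points.
#' @return A list with `slope`, `residual_rms` (root-mean-square residual in
#'   `y` units) and `n`.
#' @examples
#' fit_origin_slope(c(1, 2), c(2, 3))   # slope 8/5
#' @export
fit_origin_slope <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", "odormix_domain_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    abort("need at least 2 finite points to fit a slope.",
          "odormix_domain_error")
  }
  sxx <- sum(x^2)
  if (sxx <= 0) {
    abort("degenerate fit: all x are zero, the origin slope is undefined.",
          "odormix_degenerate_fit_error")
  }
  slope <- sum(x * y) / sxx
  list(slope = slope,
       residual_rms = sqrt(mean((y - slope * x)^2)),
       n = length(x))
}

#' Interaction coefficient from the binary counteraction slope
#'
#' When equal-intensity binary mixtures follow `OI_mix = beta (OI_a + OI_b)`,
#' substituting into the Vector Model's cosine relation collapses the
#' pairwise `cos(alpha)` to the single closed form
#' `cos(alpha) = 2 beta^2 - 1`. `beta = 1` gives perfect additivity
#' (`cos(alpha) = 1`), `beta = 1/sqrt(2)` orthogonality, and the aromatic
#' compounds' `beta = 0.66` a mild counteraction of `-0.129`.
#'
#' @param beta counteraction slope in `[0, 1]`; values above 1 would imply
#'   `cos(alpha) > 1`, which is geometrically invalid, and raise an error.
#' @return `2 * beta^2 - 1`, in `[-1, 1]`.
#' @examples
#' derive_cos_alpha(0.66)
#' @export
derive_cos_alpha <- function(beta) {
  stopifnot_scalar_number(beta, "beta")
  if (beta < 0 || beta > 1) {
    abort(sprintf(
      "`beta` must lie in [0, 1]; got %g (beta > 1 would give cos(alpha) > 1).",
      beta), "odormix_domain_error")
  }
  2 * beta^2 - 1
}

#' Counteraction slope implied by an interaction coefficient
#'
#' Inverse of [derive_cos_alpha()]: `beta = sqrt((1 + cos(alpha)) / 2)`.
#' Used by the synthetic-study generator to turn a generating `cos(alpha)`
#' back into the slope its binary mixtures must follow.
#'
#' @param cos_alpha interaction coefficient in `[-1, 1]`.
#' @return `beta` in `[0, 1]`.
#' @export
beta_from_cos_alpha <- function(cos_alpha) {
  check_cos_alpha(cos_alpha)
  sqrt((1 + cos_alpha) / 2)
}

#' Calibrate the model constants from sensory-panel data
#'
#' Estimates the two constants of the modified Vector Model:
#' \itemize{
#'   \item the psychophysical slope `k`, from individual-odorant points
#'     `(lnOAV, panel-mean OI)`;
#'   \item the counteraction slope `beta`, from binary-mixture points
#'     `(OI_sum, OI_mea)`, converted to the shared interaction coefficient
#'     `cos(alpha) = 2 beta^2 - 1`.
#' }
#' Both fits are regressions through the origin ([fit_origin_slope()]).
#' Mixture rows are *not* valid input for the `k` fit: the individual file
#' must contain single-odorant samples only, otherwise `k` absorbs the very
#' interaction `cos(alpha)` is meant to capture.
#'
#' @param individual data frame with columns `ln_oav` and `oi_measured`
#'   (single-odorant samples).
#' @param binary data frame with columns `oi_sum` and `oi_measured`
#'   (binary-mixture samples).
#' @return An object of class `odor_calibration`: a list with `k`, `beta`,
#'   `cos_alpha`, point counts and residual RMS diagnostics for both fits.
#' @examples
#' ind <- data.frame(ln_oav = 1:4, oi_measured = 1.07 * (1:4))
#' bin <- data.frame(oi_sum = c(4, 6, 8), oi_measured = 0.66 * c(4, 6, 8))
#' calibrate(ind, bin)
#' @export
calibrate <- function(individual, binary) {
  fit_k <- tryCatch(
    fit_origin_slope(individual$ln_oav, individual$oi_measured),
    odormix_error = function(e) {
      abort(paste0("individual-odorant fit (k) failed: ",
                   conditionMessage(e)), class(e)[1])
    })
  fit_b <- tryCatch(
    fit_origin_slope(binary$oi_sum, binary$oi_measured),
    odormix_error = function(e) {
      abort(paste0("binary-mixture fit (beta) failed: ",
                   conditionMessage(e)), class(e)[1])
    })
  if (fit_b$slope < 0) {
    abort(sprintf("fitted beta is negative (%g); mixture OI cannot decrease with OI_sum.",
                  fit_b$slope), "odormix_domain_error")
  }
  structure(list(
    k = fit_k$slope,
    beta = fit_b$slope,
    cos_alpha = derive_cos_alpha(min(fit_b$slope, 1)),
    n_points_k = fit_k$n,
    n_points_beta = fit_b$n,
    residual_rms_k = fit_k$residual_rms,
    residual_rms_beta = fit_b$residual_rms
  ), class = "odor_calibration")
}

#' @export
print.odor_calibration <- function(x, ...) {
  cat("Odor-mixture model calibration\n")
  cat(sprintf("  k         = %.2f  (psychophysical slope; %d points, residual rms %.3f)\n",
              x$k, x$n_points_k, x$residual_rms_k))
  cat(sprintf("  beta      = %.2f  (counteraction slope; %d points, residual rms %.3f)\n",
              x$beta, x$n_points_beta, x$residual_rms_beta))
  cat(sprintf("  cos(alpha) = %.3f  (= 2 beta^2 - 1)\n", x$cos_alpha))
  invisible(x)
}

#' Write calibrated constants to YAML
#'
#' @param calibration an `odor_calibration` (or any list with `k`, `beta`,
#'   `cos_alpha`).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  yaml::write_yaml(unclass(calibration), path)
  invisible(path)
}

#' Read calibrated constants from YAML
#'
#' @param path YAML file with at least keys `k` and `cos_alpha` (and
#'   optionally `beta` and diagnostics), as written by [write_calibration()].
#' @return An `odor_calibration` list.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("calibration file not found: '%s'.", path),
          "odormix_io_error")
  }
  obj <- yaml::read_yaml(path)
  if (is.null(obj$k) || is.null(obj$cos_alpha)) {
    abort("calibration YAML must contain `k` and `cos_alpha`.",
          "odormix_validation_error")
  }
  check_slope_k(obj$k)
  check_cos_alpha(obj$cos_alpha)
  structure(obj, class = "odor_calibration")
}
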