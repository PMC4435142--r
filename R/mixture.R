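# Mixture odor-intensity models.
#
# All models take per-component intensities on the lnOAV (or OI) scale and
# return a single non-negative mixture OI. The quadratic-form models signal
# a clamped negative radicand through a classed warning
# ("odormix_clamp_warning") so that callers such as predict_oi() can record
# the clamp without losing the numeric result.

warn_clamp <- function(message) {
  warning(structure(
    class = c("odormix_clamp_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# shared quadratic form: sum(x_i^2) + 2 * sum_{i<j} c_ij x_i x_j
# `interactions` is a scalar or a symmetric matrix aligned with x
quadratic_form <- function(x, interactions) {
  n <- length(x)
  if (length(interactions) == 1L) {
    sum(x^2) + interactions * (sum(x)^2 - sum(x^2))
  } else {
    cross <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        cross <- cross + interactions[i, j] * x[i] * x[j]
      }
    }
    sum(x^2) + 2 * cross
  }
}

check_interaction_matrix <- function(interactions, n) {
  if (!is.matrix(interactions) || nrow(interactions) != n ||
      ncol(interactions) != n) {
    abort(sprintf(
      "`interactions` must be a scalar or a %d x %d symmetric matrix covering every component pair.",
      n, n), "odormix_config_error")
  }
  if (anyNA(interactions[upper.tri(interactions)])) {
    abort("`interactions` has missing entries for some component pair.",
          "odormix_config_error")
  }
  off <- interactions[upper.tri(interactions)]
  if (any(abs(interactions - t(interactions)) > 1e-12, na.rm = TRUE)) {
    abort("`interactions` must be symmetric: cos(alpha)_ab = cos(alpha)_ba.",
          "odormix_config_error")
  }
  if (any(off < -1 | off > 1)) {
    abort("all pairwise cos(alpha) values must lie in [-1, 1].",
          "odormix_config_error")
  }
  invisible(interactions)
}

#' Classic Vector Model
#'
#' Mixture OI as the diagonal of the parallelogram whose sides are the
#' unmixed components' odor intensities:
#' `OI_mix^2 = sum(OI_i^2) + 2 * sum_{i<j} cos(alpha_ij) OI_i OI_j`.
#' Each pairwise `cos(alpha)` quantifies the interaction between two
#' components (1 = perfect additivity, 0 = orthogonal, negative =
#' counteraction) and is classically measured per pair from equal-intensity
#' binary tests (see [cos_alpha_from_pair()]).
#'
#' @param oi numeric vector of component odor intensities, all `>= 0`.
#' @param interactions a single shared `cos(alpha)` or an `n x n` symmetric
#'   matrix of pairwise values, each in `[-1, 1]` (diagonal unused).
#' @return Mixture OI, `>= 0`. A negative radicand (possible for strongly
#'   negative interactions) is clamped to 0 with a warning of class
#'   `odormix_clamp_warning`.
#' @examples
#' vector_model(c(3, 3), 1)        # collinear vectors add
#' vector_model(c(3, 3), -0.129)
#' @export
vector_model <- function(oi, interactions) {
  if (length(oi) == 0) {
    abort("`oi` must contain at least one component.", "odormix_domain_error")
  }
  if (any(!is.finite(oi)) || any(oi < 0)) {
    abort("component odor intensities must be finite and >= 0.",
          "odormix_domain_error")
  }
  if (length(interactions) == 1L) {
    check_cos_alpha(as.numeric(interactions))
  } else {
    check_interaction_matrix(interactions, length(oi))
  }
  radicand <- quadratic_form(oi, interactions)
  if (radicand < 0) {
    warn_clamp(sprintf(
      "negative radicand (%g) in the Vector Model; mixture OI clamped to 0.",
      radicand))
    return(0)
  }
  sqrt(radicand)
}

#' Modified Vector Model
#'
#' The mixture model at the heart of this package: component intensities are
#' replaced by `k * lnOAV` and every pair shares the single interaction
#' coefficient `cos(alpha)`, so
#' `OI_mix = k * sqrt( sum(x_i^2) + 2 cos(alpha) sum_{i<j} x_i x_j )`
#' with `x_i = lnOAV_i`. With the aromatic-compound defaults `k = 1.07` and
#' `cos(alpha) = -0.129` the pairwise cross terms carry the familiar
#' coefficient `-0.258`. For a single component the model reduces to the
#' individual law `k * lnOAV`.
#'
#' Callers are expected to pass supra-threshold components (`lnOAV >= 0`);
#' [predict_oi()] applies the sub-threshold policy before calling this.
#'
#' @param ln_oav numeric vector of component lnOAV values, finite.
#' @param k psychophysical slope, `> 0`.
#' @param cos_alpha shared interaction coefficient in `[-1, 1]`.
#' @return Mixture OI, `>= 0`; a negative radicand (e.g. many equal
#'   components under counteraction) is clamped to 0 with a
#'   `odormix_clamp_warning`.
#' @examples
#' modified_vector_model(c(3.36, 3.54))       # binary toluene + ethylbenzene
#' modified_vector_model(c(2.34, 3.54, 2.80)) # ternary
#' @export
modified_vector_model <- function(ln_oav, k = 1.07, cos_alpha = -0.129) {
  if (length(ln_oav) == 0) {
    abort("`ln_oav` must contain at least one component.",
          "odormix_domain_error")
  }
  if (any(!is.finite(ln_oav))) {
    abort("`ln_oav` values must all be finite.", "odormix_domain_error")
  }
  check_slope_k(k)
  check_cos_alpha(cos_alpha)
  radicand <- quadratic_form(ln_oav, cos_alpha)
  if (radicand < 0) {
    warn_clamp(sprintf(
      "negative radicand (%g) in the modified Vector Model; OI clamped to 0.",
      radicand))
    return(0)
  }
  k * sqrt(radicand)
}

#' Strongest Component Model
#'
#' Baseline predicting mixture OI as the intensity of the single strongest
#' component, `k * max(lnOAV)`, ignoring all interaction. Clamped at 0 if
#' the strongest component is sub-threshold.
#'
#' @inheritParams modified_vector_model
#' @return Mixture OI, `>= 0`.
#' @examples
#' strongest_component_model(c(3.54, 2.20, 3.83))  # 1.07 * 3.83
#' @export
strongest_component_model <- function(ln_oav, k = 1.07) {
  if (length(ln_oav) == 0) {
    abort("`ln_oav` must contain at least one component.",
          "odormix_domain_error")
  }
  if (any(!is.finite(ln_oav))) {
    abort("`ln_oav` values must all be finite.", "odormix_domain_error")
  }
  check_slope_k(k)
  max(k * max(ln_oav), 0)
}

#' Intensity-summation baseline
#'
#' Complete additivity: the sum of the unmixed components' individual odor
#' intensities, `sum(k * max(lnOAV_i, 0))`. This is the `OI_sum` axis against
#' which the counteraction slope `beta` is fitted during calibration; real
#' mixtures fall below it whenever `cos(alpha) < 1`.
#'
#' @inheritParams modified_vector_model
#' @return Summed OI, `>= 0`.
#' @examples
#' summation_model(c(3.36, 3.54))
#' @export
summation_model <- function(ln_oav, k = 1.07) {
  if (length(ln_oav) == 0) {
    abort("`ln_oav` must contain at least one component.",
          "odormix_domain_error")
  }
  if (any(!is.finite(ln_oav))) {
    abort("`ln_oav` values must all be finite.", "odormix_domain_error")
  }
  check_slope_k(k)
  sum(k * pmax(ln_oav, 0))
}

#' Pairwise interaction coefficient from a measured binary mixture
#'
#' The classic (unsimplified) route to `cos(alpha)` for one specific pair:
#' solve the binary Vector Model for the cosine,
#' `cos(alpha_ab) = (OI_ab^2 - OI_a^2 - OI_b^2) / (2 OI_a OI_b)`,
#' from a measured mixture intensity and the two unmixed intensities.
#' Classically the two components are prepared at equal perceived intensity.
#' Contrast with [derive_cos_alpha()], which derives one shared coefficient
#' from the pooled binary counteraction slope.
#'
#' @param oi_ab measured OI of the binary mixture, `>= 0`.
#' @param oi_a,oi_b unmixed component intensities, `> 0`.
#' @return `cos(alpha_ab)`. Values outside `[-1, 1]` indicate measurements
#'   inconsistent with the Vector Model and raise a domain error.
#' @examples
#' cos_alpha_from_pair(oi_ab = 3.9595, oi_a = 3, oi_b = 3)
#' @export
cos_alpha_from_pair <- function(oi_ab, oi_a, oi_b) {
  stopifnot_scalar_number(oi_ab, "oi_ab")
  stopifnot_scalar_number(oi_a, "oi_a")
  stopifnot_scalar_number(oi_b, "oi_b")
  if (oi_ab < 0 || oi_a <= 0 || oi_b <= 0) {
    abort("`oi_ab` must be >= 0 and `oi_a`, `oi_b` > 0.",
          "odormix_domain_error")
  }
  ca <- (oi_ab^2 - oi_a^2 - oi_b^2) / (2 * oi_a * oi_b)
  if (ca < -1 || ca > 1) {
    abort(sprintf(
      "measured intensities give cos(alpha) = %g outside [-1, 1]; they are inconsistent with the Vector Model.",
      ca), "odormix_domain_error")
  }
  ca
}
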