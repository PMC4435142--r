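# Sample-level prediction: resolve lnOAV per component, apply the
# sub-threshold policy, dispatch to a mixture model and collect warnings.

MODEL_NAMES <- c("mvm", "scm", "sum", "vm")

# Resolve one sample's components to lnOAV values. Returns list(ln_oav,
# component, dropped, warnings).
resolve_ln_oav <- function(comp, registry, tol = 1e-6) {
  n <- nrow(comp)
  x <- rep(NA_real_, n)
  warnings <- character()
  dropped <- logical(n)
  has_ln <- if ("ln_oav" %in% names(comp)) !is.na(comp$ln_oav) else
    rep(FALSE, n)
  has_conc <- if ("concentration_mg_m3" %in% names(comp))
    !is.na(comp$concentration_mg_m3) else rep(FALSE, n)
  for (i in seq_len(n)) {
    name <- comp$component[i]
    if (has_ln[i]) {
      x[i] <- comp$ln_oav[i]
      if (has_conc[i] && !is.null(registry)) {
        thr <- get_odorant(registry, name)$odor_threshold_mg_m3
        if (comp$concentration_mg_m3[i] > 0) {
          implied <- log(comp$concentration_mg_m3[i] / thr)
          if (abs(implied - x[i]) > tol) {
            abort(sprintf(
              "component '%s': supplied ln_oav (%g) disagrees with ln(concentration/threshold) (%g).",
              name, x[i], implied), "odormix_validation_error")
          }
        }
      }
    } else if (has_conc[i]) {
      if (comp$concentration_mg_m3[i] == 0) {
        dropped[i] <- TRUE
        warnings <- c(warnings, sprintf(
          "component '%s' dropped: concentration 0 has undefined lnOAV.",
          name))
        next
      }
      if (is.null(registry)) {
        abort(sprintf(
          "component '%s' gives a concentration but no ln_oav; a threshold registry is required.",
          name), "odormix_config_error")
      }
      thr <- get_odorant(registry, name)$odor_threshold_mg_m3
      x[i] <- log(oav(comp$concentration_mg_m3[i], thr))
    } else {
      abort(sprintf(
        "component '%s' has neither ln_oav nor concentration_mg_m3.",
        name), "odormix_validation_error")
    }
  }
  list(ln_oav = x, dropped = dropped, warnings = warnings)
}

apply_subthreshold_policy <- function(x, component, policy) {
  sub <- !is.na(x) & x < 0
  if (!any(sub)) {
    return(list(keep = !is.na(x), warnings = character()))
  }
  switch(policy,
    drop = list(
      keep = !is.na(x) & x >= 0,
      warnings = sprintf(
        "component '%s' dropped: sub-threshold (lnOAV = %g < 0).",
        component[sub], x[sub])),
    keep = list(keep = !is.na(x), warnings = character()),
    error = abort(sprintf(
      "sub-threshold component(s) %s with policy 'error'.",
      paste(sprintf("'%s'", component[sub]), collapse = ", ")),
      "odormix_domain_error")
  )
}

#' Predict mixture odor intensity for sample tables
#'
#' Takes mixture samples in long format (one row per component), resolves
#' each component to its lnOAV — either given directly or computed as
#' `ln(concentration / threshold)` through an odorant registry — applies the
#' sub-threshold policy, and predicts each sample's OI under the requested
#' model.
#'
#' Sub-threshold components (`OAV < 1`, i.e. `lnOAV < 0`) are excluded by
#' default (`subthreshold = "drop"`): the mixture models were calibrated on
#' supra-threshold components only, and negative lnOAV values entering the
#' quadratic form would let the cross terms *raise* the predicted intensity,
#' contrary to their physical reading. `"keep"` includes them anyway;
#' `"error"` refuses. Components at zero concentration have undefined lnOAV
#' and are always dropped (with a warning recorded in the result).
#'
#' @param samples data frame with columns `sample_id`, `component`, and at
#'   least one of `ln_oav` or `concentration_mg_m3`; optional `measured_oi`
#'   (repeated within a sample). See [read_samples()].
#' @param model one of `"mvm"` (modified Vector Model), `"scm"` (Strongest
#'   Component Model), `"sum"` (intensity summation) or `"vm"` (classic
#'   Vector Model; requires `interactions`).
#' @param k psychophysical slope, `> 0`.
#' @param cos_alpha shared interaction coefficient for `"mvm"`, in `[-1, 1]`.
#' @param interactions for `"vm"`: a scalar or a symmetric matrix with
#'   dimnames naming the components, pairwise `cos(alpha)` values.
#' @param registry an [odorant_registry()]; required when any component is
#'   specified by concentration.
#' @param subthreshold `"drop"`, `"keep"` or `"error"`.
#' @return A tibble with one row per sample: `sample_id`, `model`,
#'   `predicted_oi` (full precision), `predicted_oi_1dp` (half-up rounding,
#'   as tabulated in reports), `clamped` (negative radicand clamped to 0),
#'   `n_components`, `n_dropped`, `warnings` (`;`-joined, `""` if none) and,
#'   when present in the input, `measured_oi`.
#' @examples
#' predict_oi(aromatic_mixtures(), model = "mvm")
#' @export
predict_oi <- function(samples, model = c("mvm", "scm", "sum", "vm"),
                       k = 1.07, cos_alpha = -0.129, interactions = NULL,
                       registry = NULL,
                       subthreshold = c("drop", "keep", "error")) {
  model <- match.arg(model)
  subthreshold <- match.arg(subthreshold)
  check_slope_k(k)
  check_cos_alpha(cos_alpha)
  samples <- validate_samples(samples)

  ids <- unique(samples$sample_id)
  rows <- lapply(ids, function(id) {
    comp <- samples[samples$sample_id == id, ]
    if (anyDuplicated(comp$component)) {
      abort(sprintf("sample '%s' lists a component more than once.", id),
            "odormix_validation_error")
    }
    res <- resolve_ln_oav(comp, registry)
    ok <- !res$dropped
    pol <- apply_subthreshold_policy(res$ln_oav[ok], comp$component[ok],
                                     subthreshold)
    x <- res$ln_oav[ok][pol$keep]
    names(x) <- comp$component[ok][pol$keep]
    warns <- c(res$warnings, pol$warnings)
    clamped <- FALSE
    if (length(x) == 0) {
      oi_hat <- 0
      warns <- c(warns, "all components dropped; predicted OI set to 0.")
    } else {
      oi_hat <- withCallingHandlers(
        switch(model,
          mvm = modified_vector_model(x, k = k, cos_alpha = cos_alpha),
          scm = strongest_component_model(x, k = k),
          sum = summation_model(x, k = k),
          vm  = {
            inter <- interactions
            if (is.null(inter)) {
              abort("model 'vm' needs `interactions` (scalar or named matrix).",
                    "odormix_config_error")
            }
            if (is.matrix(inter)) {
              if (is.null(dimnames(inter)) ||
                  !all(names(x) %in% rownames(inter)) ||
                  !all(names(x) %in% colnames(inter))) {
                abort(sprintf(
                  "`interactions` matrix must have dimnames covering components %s.",
                  paste(names(x), collapse = ", ")), "odormix_config_error")
              }
              inter <- inter[names(x), names(x), drop = FALSE]
            }
            vector_model(oi_individual(x, k = k), inter)
          }),
        warning = function(w) {
          if (inherits(w, "odormix_clamp_warning")) {
            clamped <<- TRUE
            warns <<- c(warns, conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        })
    }
    out <- tibble::tibble(
      sample_id = id, model = model,
      predicted_oi = unname(oi_hat),
      predicted_oi_1dp = round_half_up(unname(oi_hat), 1),
      clamped = clamped,
      n_components = nrow(comp),
      n_dropped = nrow(comp) - length(x),
      warnings = paste(warns, collapse = "; ")
    )
    if ("measured_oi" %in% names(comp) && !all(is.na(comp$measured_oi))) {
      out$measured_oi <- comp$measured_oi[!is.na(comp$measured_oi)][1]
    }
    out
  })
  dplyr::bind_rows(rows)
}
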