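#' Predictive coefficient
#'
#' The ratio `OI_predicted / OI_measured`; 1.0 indicates perfect prediction,
#' below 1 under-prediction. The mean predictive coefficient over a sample
#' set is the headline comparison statistic between mixture models.
#'
#' @param oi_pre predicted OI, `>= 0`; vectorized.
#' @param oi_mea measured OI, `> 0`; vectorized.
#' @return `oi_pre / oi_mea`.
#' @examples
#' predictive_coefficient(4.9, 5.4)
#' @export
predictive_coefficient <- function(oi_pre, oi_mea) {
  if (any(!is.finite(oi_mea)) || any(oi_mea <= 0)) {
    abort("`oi_mea` must be finite and > 0 (a ratio to a zero measurement is undefined).",
          "odormix_domain_error")
  }
  if (any(!is.finite(oi_pre)) || any(oi_pre < 0)) {
    abort("`oi_pre` must be finite and >= 0.", "odormix_domain_error")
  }
  oi_pre / oi_mea
}

#' Score mixture models against panel measurements
#'
#' Predicts every sample under each requested model, computes per-sample
#' predictive coefficients against the measured OI, and averages them per
#' model. Root-mean-square error and mean absolute error are reported as
#' additional diagnostics (they are extensions beyond the classical mean
#' ratio).
#'
#' Two rounding modes control the arithmetic, not the model:
#' \describe{
#'   \item{`"table"`}{predictions are rounded half-up to one decimal before
#'     the ratio is taken, mirroring how published comparison tables are
#'     computed from their printed one-decimal predictions. Use this to
#'     reproduce tabulated results.}
#'   \item{`"full"`}{ratios use full-precision predictions; preferable for
#'     new data.}
#' }
#'
#' @param samples long-format sample tibble; every sample must carry
#'   `measured_oi > 0`.
#' @param models character subset of `c("mvm", "scm", "sum", "vm")`.
#' @param rounding `"table"` or `"full"`.
#' @inheritParams predict_oi
#' @return An object of class `oi_evaluation`: list with `rows` (per-sample
#'   tibble: `sample_id`, `measured_oi`, then `oi_<model>` and
#'   `ratio_<model>` per model), `averages` (per-model tibble with
#'   `mean_predictive_coefficient`, `rmse`, `mae`) and `rounding`.
#' @examples
#' ev <- evaluate_table(aromatic_mixtures(), models = c("mvm", "scm"),
#'                      rounding = "table")
#' ev$averages
#' @export
evaluate_table <- function(samples, models = c("mvm", "scm"), k = 1.07,
                           cos_alpha = -0.129,
                           rounding = c("table", "full"),
                           interactions = NULL, registry = NULL,
                           subthreshold = c("drop", "keep", "error")) {
  rounding <- match.arg(rounding)
  subthreshold <- match.arg(subthreshold)
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  samples <- validate_samples(samples)
  if (!"measured_oi" %in% names(samples)) {
    abort("evaluation needs `measured_oi` for every sample.",
          "odormix_validation_error")
  }

  rows <- NULL
  averages <- NULL
  for (m in models) {
    pred <- predict_oi(samples, model = m, k = k, cos_alpha = cos_alpha,
                       interactions = interactions, registry = registry,
                       subthreshold = subthreshold)
    if (!"measured_oi" %in% names(pred) || anyNA(pred$measured_oi)) {
      abort("every sample needs a non-missing `measured_oi`.",
            "odormix_validation_error")
    }
    oi_used <- if (rounding == "table") pred$predicted_oi_1dp else
      pred$predicted_oi
    ratio <- predictive_coefficient(oi_used, pred$measured_oi)
    cols <- tibble::tibble(pred$sample_id, pred$measured_oi, oi_used, ratio)
    names(cols) <- c("sample_id", "measured_oi", paste0("oi_", m),
                     paste0("ratio_", m))
    rows <- if (is.null(rows)) cols else
      dplyr::left_join(rows, cols, by = c("sample_id", "measured_oi"))
    averages <- dplyr::bind_rows(averages, tibble::tibble(
      model = m,
      mean_predictive_coefficient = mean(ratio),
      rmse = sqrt(mean((oi_used - pred$measured_oi)^2)),
      mae = mean(abs(oi_used - pred$measured_oi))
    ))
  }
  structure(list(rows = rows, averages = averages, rounding = rounding),
            class = "oi_evaluation")
}

#' @export
print.oi_evaluation <- function(x, ...) {
  cat(sprintf("Odor-intensity evaluation (%d samples, rounding mode '%s')\n",
              nrow(x$rows), x$rounding))
  print(x$rows, n = nrow(x$rows))
  cat("\nMean predictive coefficient (OI_pre / OI_mea):\n")
  for (i in seq_len(nrow(x$averages))) {
    cat(sprintf("  %-4s %.2f   (rmse %.2f, mae %.2f)\n",
                x$averages$model[i],
                round_half_up(x$averages$mean_predictive_coefficient[i], 2),
                x$averages$rmse[i], x$averages$mae[i]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-sample rows go to CSV; per-model averages to a YAML summary.
#'
#' @param evaluation an `oi_evaluation`.
#' @param csv_path per-row CSV output path.
#' @param yaml_path optional YAML summary path.
#' @return `csv_path`, invisibly.
#' @export
write_evaluation <- function(evaluation, csv_path, yaml_path = NULL) {
  readr::write_csv(evaluation$rows, csv_path)
  if (!is.null(yaml_path)) {
    yaml::write_yaml(list(
      rounding = evaluation$rounding,
      n_samples = nrow(evaluation$rows),
      averages = lapply(seq_len(nrow(evaluation$averages)), function(i)
        as.list(evaluation$averages[i, ]))
    ), yaml_path)
  }
  invisible(csv_path)
}
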