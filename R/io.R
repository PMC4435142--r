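# CSV / YAML interchange formats.
#
# Samples travel in long format, one row per component:
#   sample_id,component,concentration_mg_m3,ln_oav,measured_oi
# with measured_oi repeated within a sample (or blank). Calibration inputs
# are `odorant,ln_oav,oi_measured` (individuals) and
# `sample_id,oi_sum,oi_measured` (binary mixtures). Fitted constants go to
# YAML with keys k, beta, cos_alpha.

#' Read a mixture-sample table
#'
#' @param path CSV with columns
#'   `sample_id,component,concentration_mg_m3,ln_oav,measured_oi`; the two
#'   concentration encodings may be mixed row by row, blanks allowed.
#' @return A tibble in the long sample format used by [predict_oi()].
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("sample file not found: '%s'.", path), "odormix_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           component = readr::col_character(),
                           concentration_mg_m3 = readr::col_double(),
                           ln_oav = readr::col_double(),
                           measured_oi = readr::col_double()
                         ))
  validate_samples(tibble::as_tibble(raw))
}

validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) {
    abort("no samples: the sample table is empty.", "odormix_validation_error")
  }
  need <- c("sample_id", "component")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample table lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          "odormix_validation_error")
  }
  if (!any(c("ln_oav", "concentration_mg_m3") %in% names(samples))) {
    abort("sample table needs `ln_oav` and/or `concentration_mg_m3`.",
          "odormix_validation_error")
  }
  samples
}

#' Write a mixture-sample table
#'
#' @param samples long-format sample tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  for (col in c("concentration_mg_m3", "ln_oav", "measured_oi")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
  }
  readr::write_csv(samples[, c("sample_id", "component",
                               "concentration_mg_m3", "ln_oav",
                               "measured_oi")], path, na = "")
  invisible(path)
}

#' Read individual-odorant calibration points
#'
#' @param path CSV with columns `odorant,ln_oav,oi_measured`: panel-mean OI
#'   of single-odorant samples against their lnOAV, the data behind the
#'   `OI = k * lnOAV` fit.
#' @return A tibble.
#' @export
read_individual_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("individual calibration file not found: '%s'.", path),
          "odormix_io_error")
  }
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(odorant = readr::col_character(),
                            ln_oav = readr::col_double(),
                            oi_measured = readr::col_double())))
}

#' Read binary-mixture calibration points
#'
#' @param path CSV with columns `sample_id,oi_sum,oi_measured`: measured
#'   mixture OI against the summed unmixed-constituent OI, the data behind
#'   the counteraction slope `beta`.
#' @return A tibble.
#' @export
read_binary_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("binary calibration file not found: '%s'.", path),
          "odormix_io_error")
  }
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(sample_id = readr::col_character(),
                            oi_sum = readr::col_double(),
                            oi_measured = readr::col_double())))
}

#' Table of aromatic-mixture validation samples
#'
#' Fifteen binary, ternary and quaternary mixtures of the
#' [aromatic_odorants()] set, with per-component lnOAV values and
#' panel-measured OI, shipped as `extdata/aromatic_mixtures.csv`. These are
#' the samples on which the packaged constants were validated; running
#' [evaluate_table()] on them reproduces the published comparison of the
#' modified Vector Model against the Strongest Component Model.
#'
#' @return A long-format sample tibble (see [read_samples()]).
#' @examples
#' head(aromatic_mixtures())
#' @export
aromatic_mixtures <- function() {
  read_samples(system.file("extdata", "aromatic_mixtures.csv",
                           package = "odormix", mustWork = TRUE))
}
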