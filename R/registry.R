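#' Build an odorant threshold registry
#'
#' An odorant registry maps each odorant to its odor threshold, the lowest
#' concentration perceivable by the human nose. Thresholds are stored in
#' mg/m\eqn{^3} and are the denominator of every odor-activity-value (OAV)
#' computation. Abbreviations are case-sensitive single-letter codes and must
#' be unique; CAS registry numbers provide an alternative lookup key.
#'
#' @param name character; odorant names.
#' @param abbreviation character; unique single-letter codes.
#' @param cas character; CAS registry numbers (`"NNNNN-NN-N"` style).
#' @param odor_threshold_mg_m3 numeric; odor thresholds in mg/m\eqn{^3},
#'   strictly positive.
#' @return A tibble of class `odorant_registry` with one row per odorant.
#' @seealso [load_thresholds()], [get_odorant()], [aromatic_odorants()]
#' @examples
#' odorant_registry("Styrene", "S", "100-42-5", 0.19)
#' @export
odorant_registry <- function(name, abbreviation, cas, odor_threshold_mg_m3) {
  reg <- tibble::tibble(
    name = as.character(name),
    abbreviation = as.character(abbreviation),
    cas = as.character(cas),
    odor_threshold_mg_m3 = as.numeric(odor_threshold_mg_m3)
  )
  validate_registry(reg)
}

validate_registry <- function(reg) {
  bad <- which(!is.finite(reg$odor_threshold_mg_m3) |
                 reg$odor_threshold_mg_m3 <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "odor threshold must be a positive number; offending row(s): %s.",
      paste(sprintf("%d (%s)", bad, reg$abbreviation[bad]), collapse = ", ")),
      "odormix_validation_error")
  }
  dup <- reg$abbreviation[duplicated(reg$abbreviation)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate odorant abbreviation(s): %s.",
                  paste(unique(dup), collapse = ", ")),
          "odormix_validation_error")
  }
  if (anyNA(reg$abbreviation) || any(reg$abbreviation == "")) {
    abort("every odorant needs a non-empty abbreviation.",
          "odormix_validation_error")
  }
  class(reg) <- c("odorant_registry", class(tibble::tibble()))
  reg
}

#' Read an odorant threshold table from CSV
#'
#' The file must have a header row with columns
#' `abbreviation,name,cas,odor_threshold_mg_m3` (UTF-8, dot decimal
#' separator). Rows with missing or non-positive thresholds, or duplicate
#' abbreviations, are rejected with an error naming the offender.
#'
#' @param path path to a threshold CSV.
#' @return An [odorant_registry()].
#' @examples
#' path <- system.file("extdata", "aromatic_thresholds.csv", package = "odormix")
#' load_thresholds(path)
#' @export
load_thresholds <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("threshold file not found: '%s'.", path), "odormix_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           abbreviation = readr::col_character(),
                           name = readr::col_character(),
                           cas = readr::col_character(),
                           odor_threshold_mg_m3 = readr::col_double()
                         ))
  validate_registry(tibble::as_tibble(raw)[, c("name", "abbreviation", "cas",
                                               "odor_threshold_mg_m3")])
}

#' Write an odorant threshold table to CSV
#'
#' Inverse of [load_thresholds()]; a save/load round trip reproduces the
#' thresholds exactly at the stored decimal precision.
#'
#' @param registry an [odorant_registry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_thresholds <- function(registry, path) {
  registry <- validate_registry(registry)
  out <- registry[, c("abbreviation", "name", "cas", "odor_threshold_mg_m3")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Look up an odorant by abbreviation or CAS number
#'
#' @param registry an [odorant_registry()].
#' @param key a single abbreviation (case-sensitive) or CAS number.
#' @return The matching one-row registry slice.
#' @examples
#' get_odorant(aromatic_odorants(), "T")
#' get_odorant(aromatic_odorants(), "108-88-3")
#' @export
get_odorant <- function(registry, key) {
  stopifnot(is.character(key), length(key) == 1L)
  hit <- registry$abbreviation == key | registry$cas == key
  if (!any(hit)) {
    abort(sprintf(
      "no odorant with abbreviation or CAS '%s'; available: %s.",
      key, paste(registry$abbreviation, collapse = ", ")),
      "odormix_lookup_error")
  }
  registry[hit, ]
}

#' Aromatic-compound threshold registry
#'
#' The seven aromatic indoor-air pollutants on which the packaged model
#' constants (`k = 1.07`, `cos(alpha) = -0.129`) were calibrated: benzene,
#' toluene, ethylbenzene, n-propylbenzene, o-xylene, m-xylene and styrene,
#' with panel-measured odor thresholds in mg/m\eqn{^3}. Shipped as
#' `extdata/aromatic_thresholds.csv`.
#'
#' @return An [odorant_registry()] with seven rows.
#' @examples
#' aromatic_odorants()
#' @export
aromatic_odorants <- function() {
  load_thresholds(system.file("extdata", "aromatic_thresholds.csv",
                              package = "odormix", mustWork = TRUE))
}
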