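# Synthetic sensory panel: OIRS-style ratings with assessor noise,
# discretized to the scale step and averaged over the panel, so that
# calibration and evaluation can be validated without human assessors.

#' Sensory-panel configuration
#'
#' @param n_assessors panel size (default 9, a typical trained panel).
#' @param rating_noise_sd per-assessor Gaussian rating noise in OIRS units.
#'   The default 0.25 puts the commonly acknowledged repeat-test fluctuation
#'   of about 0.5 OIRS units at the +/- 2 sd band.
#' @param rating_step OIRS discretization step; assessors report in 0.5-unit
#'   increments by default.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_assessors = 9, rating_noise_sd = 0.25,
                         rating_step = 0.5) {
  if (n_assessors < 1 || n_assessors != round(n_assessors)) {
    abort("`n_assessors` must be a positive integer.", "odormix_domain_error")
  }
  if (!is.finite(rating_noise_sd) || rating_noise_sd < 0) {
    abort("`rating_noise_sd` must be >= 0.", "odormix_domain_error")
  }
  if (!is.finite(rating_step) || rating_step <= 0) {
    abort("`rating_step` must be > 0.", "odormix_domain_error")
  }
  structure(list(n_assessors = n_assessors,
                 rating_noise_sd = rating_noise_sd,
                 rating_step = rating_step),
            class = "panel_config")
}

#' Simulate a panel-mean odor intensity rating
#'
#' Each assessor perceives `true_oi` plus Gaussian noise, reports the
#' nearest OIRS step (half-up), negative reports are clamped to 0, and the
#' sample's OI is the panel mean — mirroring how panel scores are averaged
#' in practice. Deterministic given the RNG state (wrap in
#' [withr::with_seed()] or `set.seed()` for reproducibility).
#'
#' @param true_oi true odor intensity, `>= 0`; vectorized.
#' @param config a [panel_config()].
#' @return Panel-mean OI per element of `true_oi`.
#' @examples
#' withr::with_seed(1, simulate_panel_mean(4.0))
#' @export
simulate_panel_mean <- function(true_oi, config = panel_config()) {
  if (any(!is.finite(true_oi)) || any(true_oi < 0)) {
    abort("`true_oi` must be finite and >= 0.", "odormix_domain_error")
  }
  n <- config$n_assessors
  noise <- matrix(rnorm(length(true_oi) * n, 0, config$rating_noise_sd),
                  nrow = n)
  perceived <- sweep(noise, 2, true_oi, "+")
  step <- config$rating_step
  scores <- pmax(step * floor(perceived / step + 0.5), 0)
  colMeans(matrix(scores, nrow = n))
}

default_mixture_designs <- function() {
  list(c("B", "T"), c("B", "E"), c("T", "E"), c("E", "O"))
}

#' Generate a synthetic calibration/validation study
#'
#' Builds a complete synthetic study with the structure of a real sensory
#' campaign: individual-odorant samples whose true OI follows
#' `k * lnOAV`, and mixture samples whose true OI follows the modified
#' Vector Model with the generating `(true_k, true_cos_alpha)`; every true
#' intensity is then rated by the simulated panel. Binary mixtures are
#' generated at equal component intensity (both components share one lnOAV),
#' matching the classical protocol for determining the interaction
#' coefficient; their unmixed constituents are rated too, yielding the
#' `(OI_sum, OI_mea)` pairs that [calibrate()] consumes.
#'
#' @param true_k,true_cos_alpha generating constants.
#' @param registry an [odorant_registry()] naming the odorants used.
#' @param n_individual_per_odorant individual samples per odorant (default 4
#'   concentration levels).
#' @param mixture_designs list of character vectors of registry
#'   abbreviations (2-4 components each); the default is four binary
#'   designs B+T, B+E, T+E, E+O. Designs with more than two components
#'   contribute validation samples but not calibration pairs.
#' @param n_samples_per_mixture samples per design (default 8 concentration
#'   levels).
#' @param lnoav_range range the generated lnOAV values are drawn from,
#'   uniform; must lie within `(0, 6]` (supra-threshold, as in the
#'   validation mixtures, whose lnOAV span 1.65-4.53).
#' @param misspecification_delta half-width of a uniform perturbation added
#'   to each mixture's true OI (0 = generate exactly under the model); for
#'   robustness studies.
#' @param config a [panel_config()].
#' @param seed optional integer; the study is bit-reproducible given a seed.
#' @return An object of class `synthetic_study`: list with `individual`
#'   (tibble `odorant, ln_oav, oi_measured`), `binary`
#'   (tibble `sample_id, oi_sum, oi_measured`, binary designs only),
#'   `samples` (long-format mixture table usable by [predict_oi()] /
#'   [evaluate_table()]), the generating constants and the config.
#' @examples
#' study <- generate_study(seed = 42)
#' calibrate(study$individual, study$binary)
#' @export
generate_study <- function(true_k = 1.07, true_cos_alpha = -0.129,
                           registry = aromatic_odorants(),
                           n_individual_per_odorant = 4,
                           mixture_designs = default_mixture_designs(),
                           n_samples_per_mixture = 8,
                           lnoav_range = c(1.65, 4.53),
                           misspecification_delta = 0,
                           config = panel_config(), seed = NULL) {
  check_slope_k(true_k)
  check_cos_alpha(true_cos_alpha)
  if (length(lnoav_range) != 2 || lnoav_range[1] <= 0 ||
      lnoav_range[2] > 6 || lnoav_range[1] > lnoav_range[2]) {
    abort("`lnoav_range` must lie within (0, 6] (supra-threshold).",
          "odormix_domain_error")
  }
  for (d in mixture_designs) {
    for (ab in d) get_odorant(registry, ab)  # lookup error if unknown
    if (length(d) < 2 || length(d) > 4 || anyDuplicated(d)) {
      abort("each mixture design needs 2-4 distinct odorants.",
            "odormix_domain_error")
    }
  }

  run <- function() {
    draw <- function(n) runif(n, lnoav_range[1], lnoav_range[2])

    individual <- tibble::tibble(
      odorant = rep(registry$abbreviation, each = n_individual_per_odorant),
      ln_oav = draw(nrow(registry) * n_individual_per_odorant)
    )
    individual$oi_measured <- simulate_panel_mean(
      oi_individual(individual$ln_oav, k = true_k), config)

    binary <- tibble::tibble(sample_id = character(), oi_sum = double(),
                             oi_measured = double())
    samples <- NULL
    for (di in seq_along(mixture_designs)) {
      d <- mixture_designs[[di]]
      for (si in seq_len(n_samples_per_mixture)) {
        id <- sprintf("%s-%02d", paste(d, collapse = ""), si)
        x <- if (length(d) == 2) rep(draw(1), 2) else draw(length(d))
        true_mix <- modified_vector_model(x, k = true_k,
                                          cos_alpha = true_cos_alpha)
        if (misspecification_delta > 0) {
          true_mix <- max(true_mix + runif(1, -misspecification_delta,
                                           misspecification_delta), 0)
        }
        oi_mea <- simulate_panel_mean(true_mix, config)
        samples <- dplyr::bind_rows(samples, tibble::tibble(
          sample_id = id, component = d, concentration_mg_m3 = NA_real_,
          ln_oav = x, measured_oi = oi_mea))
        if (length(d) == 2) {
          constituents <- simulate_panel_mean(
            oi_individual(x, k = true_k), config)
          binary <- dplyr::bind_rows(binary, tibble::tibble(
            sample_id = id, oi_sum = sum(constituents),
            oi_measured = oi_mea))
        }
      }
    }
    if (is.null(samples)) {
      samples <- tibble::tibble(sample_id = character(),
                                component = character(),
                                concentration_mg_m3 = double(),
                                ln_oav = double(), measured_oi = double())
    }
    structure(list(true_k = true_k, true_cos_alpha = true_cos_alpha,
                   individual = individual, binary = binary,
                   samples = samples, config = config),
              class = "synthetic_study")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a synthetic study to the standard CSV formats
#'
#' Emits `individual.csv` and `binary.csv` (the [calibrate()] inputs) and
#' `samples.csv` (the [predict_oi()] / [evaluate_table()] input) into a
#' directory, so the full pipeline runs end-to-end on simulated data.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$individual, file.path(dir, "individual.csv"))
  readr::write_csv(study$binary, file.path(dir, "binary.csv"))
  readr::write_csv(study$samples, file.path(dir, "samples.csv"), na = "")
  invisible(dir)
}
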