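#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.05 -> 0.1`), the
#' convention used when tabulating odor intensities, rather than R's
#' round-half-even. A tiny epsilon absorbs binary floating-point
#' representation error so that values printed as exact ties round up.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(c(0.25, 0.35, -0.25), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# stop() wrapper giving errors a package condition class so tests can target
# them precisely
abort <- function(message, class) {
  stop(structure(
    class = c(class, "odormix_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          "odormix_domain_error")
  }
  invisible(x)
}

check_cos_alpha <- function(cos_alpha) {
  stopifnot_scalar_number(cos_alpha, "cos_alpha")
  if (cos_alpha < -1 || cos_alpha > 1) {
    abort(sprintf(
      "`cos_alpha` must lie in [-1, 1] (it is the cosine of the interaction angle); got %g.",
      cos_alpha), "odormix_config_error")
  }
  invisible(cos_alpha)
}

check_slope_k <- function(k) {
  stopifnot_scalar_number(k, "k")
  if (k <= 0) {
    abort(sprintf("psychophysical slope `k` must be > 0; got %g.", k),
          "odormix_domain_error")
  }
  invisible(k)
}
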