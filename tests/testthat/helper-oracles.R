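# Independent oracles: literal transcriptions of the published binary,
# ternary and quaternary mixture formulas, written as one-line arithmetic so
# they stay independent of the package's generalized quadratic form.

oracle_mvm2 <- function(a, b) {
  1.07 * sqrt(a^2 + b^2 - 0.258 * a * b)
}

oracle_mvm3 <- function(a, b, c) {
  1.07 * sqrt(a^2 + b^2 + c^2 - 0.258 * a * b - 0.258 * a * c -
                0.258 * b * c)
}

oracle_mvm4 <- function(a, b, c, d) {
  1.07 * sqrt(a^2 + b^2 + c^2 + d^2 - 0.258 * a * b - 0.258 * a * c -
                0.258 * a * d - 0.258 * b * c - 0.258 * b * d -
                0.258 * c * d)
}

# Published validation table: per-sample lnOAV values, panel-measured OI and
# the tabulated one-decimal predictions of the modified Vector Model (MVM)
# and the Strongest Component Model (SCM).
published_table <- function() {
  list(
    ln_oav = list(
      `TE-1` = c(3.36, 3.54), `TE-2` = c(3.03, 2.44), `TE-3` = c(2.67, 2.44),
      `TS-1` = c(1.65, 2.04), `TS-2` = c(3.36, 2.04), `TS-3` = c(2.34, 4.53),
      `TEM-1` = c(2.34, 3.54, 2.80), `TEM-2` = c(2.34, 2.44, 3.49),
      `TEM-3` = c(1.65, 1.78, 2.15),
      `EPS-1` = c(3.54, 2.20, 3.83), `EPS-2` = c(4.24, 2.20, 4.53),
      `EPS-3` = c(2.82, 2.20, 2.65),
      `TEMS-1` = c(4.24, 2.20, 3.83, 2.15),
      `TEMS-2` = c(2.20, 3.15, 2.20, 2.15),
      `TEMS-3` = c(1.85, 1.77, 2.20, 2.15)),
    measured = c(5.4, 4.0, 3.3, 2.7, 4.5, 6.2, 3.8, 5.0, 3.5, 5.4, 6.8,
                 4.5, 4.8, 4.5, 3.5),
    mvm_printed = c(4.9, 3.9, 3.6, 2.6, 4.0, 5.2, 4.7, 4.5, 3.0, 5.3, 6.2,
                    4.1, 5.5, 4.1, 3.3),
    scm_printed = c(3.8, 3.2, 2.9, 2.2, 3.6, 4.8, 3.8, 3.7, 2.3, 4.1, 4.8,
                    3.0, 4.5, 3.4, 2.4)
  )
}

make_samples <- function(ln_oav_list, measured = NULL) {
  rows <- lapply(seq_along(ln_oav_list), function(i) {
    x <- ln_oav_list[[i]]
    tibble::tibble(
      sample_id = names(ln_oav_list)[i],
      component = paste0("c", seq_along(x)),
      ln_oav = x,
      measured_oi = if (is.null(measured)) NA_real_ else measured[i])
  })
  dplyr::bind_rows(rows)
}
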