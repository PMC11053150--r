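#' Summary-data-based Mendelian randomization (SMR) statistic
#'
#' Tests whether a GWAS association at an instrument variant is mediated by
#' a molecular-trait association at the same variant:
#' \deqn{T_{SMR} = \frac{Z_{zy}^2\,Z_{zx}^2}{Z_{zy}^2 + Z_{zx}^2},}
#' a chi-square statistic with 1 degree of freedom testing the implied
#' effect of the molecular trait on the outcome. The statistic is symmetric
#' in its arguments, bounded by `min(Z_zy^2, Z_zx^2)`, and tends to
#' `Z_zy^2` as `|Z_zx|` grows. Both z equal to zero yields `T = 0`,
#' `p = 1` (not an error).
#'
#' @param z_gwas,z_qtl Signed z statistics for the GWAS and QTL
#'   associations at the instrument (vectorised).
#' @return Tibble with `z_gwas`, `z_qtl`, `t_smr` and `p_smr` (upper
#'   chi-square(1) tail).
#' @examples
#' smr_statistic(2, 2)   # T = 2
#' smr_statistic(5, 10)  # T = 20
#' @export
smr_statistic <- function(z_gwas, z_qtl) {
  if (any(!is.finite(z_gwas)) || any(!is.finite(z_qtl))) {
    abort("z statistics must be finite.")
  }
  zy2 <- z_gwas^2
  zx2 <- z_qtl^2
  t_smr <- if_else(zy2 + zx2 == 0, 0, zy2 * zx2 / (zy2 + zx2))
  tibble(z_gwas = z_gwas, z_qtl = z_qtl, t_smr = t_smr,
         p_smr = pchisq(t_smr, df = 1L, lower.tail = FALSE))
}

#' SMR colocalization scan over signals and molecular traits
#'
#' Uses each independent signal's index variant as the instrument, pairs
#' its GWAS z statistic with the meta-analysed QTL z statistic for every
#' trait covering that variant, computes the SMR statistic, and
#' Bonferroni-adjusts within each signal (the family being that signal's
#' tested trait pairs). Instruments absent from the QTL results are
#' skipped with a message.
#'
#' @param signals Tibble of independent signals: columns `signal_id`,
#'   `snp`, `z` (GWAS z of the index, conditional or marginal).
#' @param qtl_meta Tibble from [stouffer_meta()] (columns `snp`,
#'   `trait_id`, `z_meta`).
#' @param alpha Significance level for the adjusted p (default 0.05).
#' @return A `fm_smr` tibble: `signal_id`, `snp`, `trait_id`, `z_gwas`,
#'   `z_qtl`, `t_smr`, `p_smr`, `n_tests`, `p_adj`, `significant`.
#' @export
smr_scan <- function(signals, qtl_meta, alpha = 0.05) {
  assert_columns(signals, c("signal_id", "snp", "z"), "signals")
  assert_columns(qtl_meta, c("snp", "trait_id", "z_meta"), "qtl_meta")
  missing <- setdiff(signals$snp, qtl_meta$snp)
  if (length(missing) > 0L) {
    inform(sprintf("No QTL coverage for instrument(s): %s (skipped)",
                   paste(missing, collapse = ", ")))
  }
  paired <- signals |>
    select("signal_id", "snp", z_gwas_in = "z") |>
    dplyr::inner_join(qtl_meta, by = "snp", relationship = "many-to-many")
  if (nrow(paired) == 0L) {
    out <- tibble(signal_id = character(), snp = character(),
                  trait_id = character(), z_gwas = numeric(),
                  z_qtl = numeric(), t_smr = numeric(), p_smr = numeric(),
                  n_tests = integer(), p_adj = numeric(),
                  significant = logical())
    return(structure(out, class = c("fm_smr", class(out))))
  }
  stat <- smr_statistic(paired$z_gwas_in, paired$z_meta)
  out <- paired |>
    mutate(z_gwas = stat$z_gwas, z_qtl = stat$z_qtl,
           t_smr = stat$t_smr, p_smr = stat$p_smr) |>
    group_by(.data$signal_id) |>
    mutate(n_tests = dplyr::n(),
           p_adj = pmin(1, .data$p_smr * .data$n_tests),
           significant = .data$p_adj < alpha) |>
    ungroup() |>
    select("signal_id", "snp", "trait_id", "z_gwas", "z_qtl", "t_smr",
           "p_smr", "n_tests", "p_adj", "significant")
  structure(out, class = c("fm_smr", class(out)))
}
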