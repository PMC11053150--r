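#' Filter and normalise an expression matrix
#'
#' Keeps genes expressed at >= `min_tpm` TPM in >= `min_fraction` of
#' samples *and* >= `min_count` unnormalised reads in >= `min_fraction` of
#' samples (boundaries inclusive), quantile-normalises expression across
#' samples (target: the average empirical distribution, via
#' `limma::normalizeQuantiles`) and then applies a per-gene rank-based
#' inverse normal transform `qnorm((rank - 0.5) / n)` with average ranks
#' for ties.
#'
#' @param counts,tpm Genes-by-samples matrices with matching dimensions and
#'   gene ids as row names.
#' @param min_tpm,min_count,min_fraction Filter thresholds (defaults 0.1
#'   TPM, 6 reads, 20% of samples).
#' @return A genes-by-samples matrix of transformed expression for the
#'   retained genes (each row has mean 0 by construction).
#' @export
filter_and_normalize_expression <- function(counts, tpm, min_tpm = 0.1,
                                            min_count = 6,
                                            min_fraction = 0.2) {
  if (!all(dim(counts) == dim(tpm))) {
    abort("`counts` and `tpm` must share dimensions.")
  }
  keep <- rowMeans(tpm >= min_tpm) >= min_fraction &
    rowMeans(counts >= min_count) >= min_fraction
  if (!any(keep)) abort("All genes removed by the expression filter.")
  qn <- limma::normalizeQuantiles(tpm[keep, , drop = FALSE])
  t(apply(qn, 1L, inverse_normal_transform))
}

#' Rank-based inverse normal transform
#'
#' `qnorm((rank - 0.5) / n)` with average ranks for ties.
#'
#' @param x Numeric vector.
#' @return Transformed vector with mean ~0.
#' @export
inverse_normal_transform <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Cis-QTL scan of CCVs against nearby molecular traits
#'
#' For every (variant, trait) pair whose trait anchor (TSS for expression,
#' CpG position for methylation) lies within `window` bases of the variant
#' (boundary inclusive, same chromosome), fits the ordinary least squares
#' regression of the normalised trait on the variant dosage adjusting for
#' the supplied covariates, and reports the dosage slope with a t-based
#' two-sided p-value. The conventional covariate sets are age, sex and
#' five genotype principal components for expression, and age, sex and
#' colon side for methylation; any covariate data frame is accepted.
#'
#' @param dosages Samples-by-variants dosage matrix (variant ids as column
#'   names).
#' @param variant_meta Tibble with `snp`, `chr`, `pos` for the dosage
#'   columns.
#' @param traits Traits-by-samples matrix of normalised trait values.
#' @param trait_meta Tibble with `trait_id`, `chr`, `anchor` (TSS or CpG
#'   position) for the trait rows.
#' @param covariates Samples-by-covariates data frame or matrix.
#' @param ccvs Variant ids to test (defaults to all dosage columns).
#' @param dataset Dataset label recorded in the output.
#' @param window Cis window in bases (default 1e6, inclusive).
#' @return Tibble of QTL associations: `snp`, `trait_id`, `dataset`,
#'   `beta`, `se`, `p`, `n`, `distance`.
#' @export
cis_qtl_scan <- function(dosages, variant_meta, traits, trait_meta,
                         covariates, ccvs = colnames(dosages),
                         dataset = "dataset1", window = 1e6) {
  assert_columns(variant_meta, c("snp", "chr", "pos"), "variant_meta")
  assert_columns(trait_meta, c("trait_id", "chr", "anchor"), "trait_meta")
  n <- nrow(dosages)
  if (ncol(traits) != n) {
    abort("`traits` must have one column per dosage row (sample).")
  }
  if (is.null(rownames(traits)) ||
      !all(trait_meta$trait_id %in% rownames(traits))) {
    abort("`traits` row names must cover `trait_meta$trait_id`.")
  }
  X <- cbind(intercept = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    abort(sprintf("Covariate matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }

  pairs <- variant_meta |>
    filter(.data$snp %in% ccvs) |>
    dplyr::inner_join(trait_meta, by = "chr", relationship = "many-to-many") |>
    mutate(distance = abs(.data$anchor - .data$pos)) |>
    filter(.data$distance <= window)
  if (nrow(pairs) == 0L) {
    return(tibble(snp = character(), trait_id = character(),
                  dataset = character(), beta = numeric(), se = numeric(),
                  p = numeric(), n = integer(), distance = numeric()))
  }

  g_res <- qr.resid(qx, dosages[, unique(pairs$snp), drop = FALSE])
  t_res <- qr.resid(qx, t(traits[unique(pairs$trait_id), , drop = FALSE]))
  df <- n - ncol(X) - 1L

  gg <- colSums(g_res^2)
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    g <- g_res[, pairs$snp[i]]
    y <- t_res[, pairs$trait_id[i]]
    ggi <- unname(gg[pairs$snp[i]])
    beta <- sum(g * y) / ggi
    rss <- sum(y^2) - beta^2 * ggi
    se <- sqrt(rss / df / ggi)
    tibble(beta = beta, se = se)
  }) |> bind_rows()

  pairs |>
    mutate(dataset = dataset, beta = res$beta, se = res$se,
           p = 2 * pt(abs(.data$beta / .data$se), df, lower.tail = FALSE),
           n = n) |>
    select("snp", "trait_id", "dataset", "beta", "se", "p", "n", "distance")
}

#' Sample-size-weighted z-score meta-analysis of QTL associations
#'
#' Converts each dataset's association to a z score with
#' `qnorm(p/2) * sign(beta)` and combines them as
#' `z = sum(z_i * sqrt(N_i)) / sqrt(sum(N_i))`; the meta p-value is the
#' two-sided normal tail of the combined z. Betas must be harmonised to a
#' common effect allele before combination.
#'
#' @param assocs Tibble of per-dataset associations for (variant, trait)
#'   pairs: columns `snp`, `trait_id`, `dataset`, `beta`, `p`, `n`.
#' @return Tibble with one row per (variant, trait): `snp`, `trait_id`,
#'   `z_meta`, `p_meta`, `n_total`, `n_datasets`. The combined z keeps the
#'   `qnorm(p/2)` sign convention (opposite to the effect direction).
#' @export
stouffer_meta <- function(assocs) {
  assert_columns(assocs, c("snp", "trait_id", "dataset", "beta", "p", "n"),
                 "assocs")
  dup <- assocs |>
    count(.data$snp, .data$trait_id, .data$dataset) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("Duplicated dataset label(s) within a pair: %s",
                  paste(unique(dup$dataset), collapse = ", ")))
  }
  assocs |>
    mutate(z = p_to_z(.data$p, .data$beta)) |>
    group_by(.data$snp, .data$trait_id) |>
    summarise(z_meta = sum(.data$z * sqrt(.data$n)) / sqrt(sum(.data$n)),
              n_total = sum(.data$n), n_datasets = dplyr::n(),
              .groups = "drop") |>
    mutate(p_meta = z_to_p(.data$z_meta)) |>
    select("snp", "trait_id", "z_meta", "p_meta", "n_total", "n_datasets")
}

#' Bonferroni adjustment within per-signal families
#'
#' Adjusts meta-analysis p-values by the number of tests within each
#' family (all trait pairs tested for one independent signal's index
#' variant, per trait kind): `p_adj = min(1, p * m)`, flagged significant
#' at `p_adj < 0.05`.
#'
#' @param meta Tibble from [stouffer_meta()] (or any tibble with a `p_meta`
#'   column).
#' @param family Column name giving the family id (default `"signal_id"`).
#' @param alpha Significance level (default 0.05).
#' @return `meta` with `n_tests`, `p_adj` and `significant` added.
#' @export
bonferroni_per_family <- function(meta, family = "signal_id", alpha = 0.05) {
  assert_columns(meta, c("p_meta", family), "meta")
  meta |>
    group_by(across(all_of(family))) |>
    mutate(n_tests = dplyr::n(),
           p_adj = pmin(1, .data$p_meta * .data$n_tests),
           significant = .data$p_adj < alpha) |>
    ungroup()
}
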