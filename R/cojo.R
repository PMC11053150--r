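#' Approximate conditional analysis from summary statistics
#'
#' Reconstructs, for every target variant, the joint linear model of
#' \{conditioning set, target\} from marginal summary statistics and an LD
#' reference panel, and reports the target's conditional effect, standard
#' error and two-sided p-value. The reconstruction uses the standard
#' summary-statistics algebra: with centred genotypes, `X'X` is approximated
#' by panel correlations scaled by `sqrt(D_j D_k)` where
#' `D_j = (N_j - 1) * v_j` (`v_j` the panel allele variance), `X'y_j = D_j
#' b_j`, and the phenotypic sum of squares is taken as the median across
#' region variants of the per-variant marginal reconstruction
#' `se_j^2 D_j (N_j - 2) + b_j^2 D_j`, rescaled to the effective sample
#' size. Effects from logistic models are treated on the linear
#' approximation scale, as is standard for case-control use.
#'
#' Targets correlated at `r^2` above `collinearity` with any conditioning
#' variant (or whose conditional variance is numerically degenerate) are
#' masked: returned with `estimable = FALSE` and `NA` statistics.
#'
#' @param stats Marginal summary statistics tibble (columns `snp`, `pos`,
#'   `beta`, `se`, `n`; other columns carried through) for the region,
#'   restricted to variants present in the panel.
#' @param panel An [ld_panel()] covering the variants.
#' @param conditioning Character vector of conditioning variant ids (may be
#'   empty, in which case the marginal statistics are returned unchanged).
#' @param collinearity Panel `r^2` above which a target is masked (default
#'   0.9).
#' @param ridge Relative ridge added to the diagonal of the reconstructed
#'   `X'X` (default 1e-8).
#' @return A tibble with one row per non-conditioning variant: input columns
#'   plus `beta_c`, `se_c`, `z_c`, `p_c`, `neglog10p_c`, `estimable`.
#' @export
conditional_analysis <- function(stats, panel, conditioning = character(),
                                 collinearity = 0.9, ridge = 1e-8) {
  assert_columns(stats, c("snp", "beta", "se", "n"), "stats")
  missing_panel <- setdiff(stats$snp, panel$variant_ids)
  if (length(missing_panel) > 0) {
    abort(sprintf("Variant(s) absent from LD panel: %s",
                  paste(head(missing_panel, 5), collapse = ", ")))
  }
  conditioning <- unique(conditioning)
  if (!all(conditioning %in% stats$snp)) {
    abort("Conditioning variants must be present in `stats`.")
  }
  targets <- stats |> filter(!.data$snp %in% conditioning)
  if (length(conditioning) == 0L) {
    return(targets |>
             mutate(beta_c = .data$beta, se_c = .data$se,
                    z_c = .data$beta / .data$se,
                    p_c = z_to_p(.data$z_c),
                    neglog10p_c = z_to_neglog10p(.data$z_c),
                    estimable = TRUE))
  }

  rec <- cojo_setup(stats, panel)
  cond <- rec[match(conditioning, rec$snp), ]
  targ <- rec[match(targets$snp, rec$snp), ]

  R <- panel$correlation
  B_cc <- R[cond$snp, cond$snp, drop = FALSE] *
    tcrossprod(sqrt(cond$D))
  diag(B_cc) <- diag(B_cc) * (1 + ridge)
  B_cc_inv <- tryCatch(solve(B_cc), error = function(e) {
    abort(sprintf(
      "Reconstructed X'X is singular for conditioning set {%s}: %s",
      paste(conditioning, collapse = ", "), conditionMessage(e)))
  })

  B_tc <- R[targ$snp, cond$snp, drop = FALSE] *
    outer(sqrt(targ$D), sqrt(cond$D))
  w <- B_cc_inv %*% cond$Xy                     # not the joint betas of C
  q0 <- sum(cond$Xy * w)                        # Xy_C' B_CC^-1 Xy_C
  M <- B_tc %*% B_cc_inv
  schur <- unname(targ$D - rowSums(M * B_tc))
  resid <- as.numeric(targ$Xy - B_tc %*% w)
  beta_c <- resid / schur

  n_eff <- min(rec$n)
  yty <- rec$sigma2_y[1] * (n_eff - 1)
  k <- length(conditioning)
  rss <- yty - q0 - resid^2 / schur
  df <- n_eff - k - 2
  sigma2 <- rss / df
  se_c <- sqrt(sigma2 / schur)

  r2max <- unname(apply(R[targ$snp, cond$snp, drop = FALSE]^2, 1L, max))
  masked <- r2max > collinearity | schur <= ridge * targ$D | !is.finite(se_c) |
    sigma2 <= 0
  beta_c[masked] <- NA_real_
  se_c[masked] <- NA_real_

  z_c <- beta_c / se_c
  targets |>
    mutate(beta_c = beta_c, se_c = se_c, z_c = z_c,
           p_c = z_to_p(z_c), neglog10p_c = z_to_neglog10p(z_c),
           estimable = !masked)
}

# Shared reconstruction pieces: D_j, X'y_j and the per-variant phenotypic
# variance estimate (median across the region).
cojo_setup <- function(stats, panel) {
  v <- unname(panel$allele_var[stats$snp])
  D <- (stats$n - 1) * v
  Xy <- D * stats$beta
  sigma2_y_j <- (stats$se^2 * D * (stats$n - 2) + stats$beta^2 * D) /
    (stats$n - 1)
  tibble(snp = stats$snp, n = stats$n, D = D, Xy = Xy,
         sigma2_y = median(sigma2_y_j))
}

#' Joint multi-variant model from summary statistics
#'
#' Fits the joint model of a set of index variants reconstructed from
#' summary statistics (same algebra as [conditional_analysis()]) and
#' returns each variant's joint-model effect.
#'
#' @inheritParams conditional_analysis
#' @param snps Variant ids to fit jointly.
#' @return Tibble with `snp`, `beta_joint`, `se_joint`, `z_joint`,
#'   `p_joint`, `neglog10p_joint`.
#' @export
joint_model <- function(stats, panel, snps, ridge = 1e-8) {
  stopifnot(all(snps %in% stats$snp))
  rec <- cojo_setup(stats, panel)
  sub <- rec[match(snps, rec$snp), ]
  B <- panel$correlation[snps, snps, drop = FALSE] * tcrossprod(sqrt(sub$D))
  diag(B) <- diag(B) * (1 + ridge)
  Binv <- tryCatch(solve(B), error = function(e) {
    abort(sprintf("Reconstructed X'X is singular for joint set {%s}",
                  paste(snps, collapse = ", ")))
  })
  beta <- as.numeric(Binv %*% sub$Xy)
  n_eff <- min(rec$n)
  yty <- rec$sigma2_y[1] * (n_eff - 1)
  rss <- yty - sum(beta * sub$Xy)
  sigma2 <- rss / (n_eff - length(snps) - 1)
  if (sigma2 <= 0) sigma2 <- NA_real_
  se <- sqrt(sigma2 * diag(Binv))
  z <- beta / se
  tibble(snp = snps, beta_joint = beta, se_joint = se, z_joint = z,
         p_joint = z_to_p(z), neglog10p_joint = z_to_neglog10p(z))
}
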