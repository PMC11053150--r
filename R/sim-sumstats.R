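#' Per-variant marginal association summary statistics
#'
#' Computes covariate-adjusted marginal association statistics for every
#' polymorphic variant in a phenotyped cohort: ordinary least squares for
#' quantitative traits (exact, via residualisation on the covariates) and a
#' logistic score test with one-step log-odds effect estimate (`beta = U/V`,
#' `se = 1/sqrt(V)` with `U` the score and `V` the efficient information)
#' for binary traits. Monomorphic variants and, for binary traits, variants
#' that perfectly separate cases from controls are excluded and reported in
#' the `excluded` attribute with a reason.
#'
#' @param cohort A phenotyped `cohort` (see [simulate_phenotype()]).
#' @param adjust_covariates Adjust for the cohort covariates (age, sex)?
#' @return A tibble with columns `snp`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `af`, `beta`, `se`, `z`, `p`, `neglog10p`, `n`, plus an
#'   `excluded` attribute (tibble: snp, reason).
#' @export
compute_summary_stats <- function(cohort, adjust_covariates = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$phenotype)) {
    abort("Cohort has no phenotype; run simulate_phenotype() first.")
  }
  g <- cohort$genotypes
  y <- cohort$phenotype
  n <- length(y)
  X <- if (adjust_covariates) {
    cbind(intercept = 1, as.matrix(cohort$covariates))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  }

  af <- colMeans(g) / 2
  excluded <- tibble(snp = character(), reason = character())
  mono <- af == 0 | af == 1
  if (any(mono)) {
    excluded <- bind_rows(excluded,
      tibble(snp = colnames(g)[mono], reason = "monomorphic"))
  }
  keep <- !mono

  if (cohort$config$trait_kind == "binary") {
    # perfect separation: a dosage threshold splits cases from controls
    sep <- vapply(which(keep), function(j) {
      g1 <- g[y == 1, j]; g0 <- g[y == 0, j]
      min(g1) > max(g0) || max(g1) < min(g0)
    }, logical(1))
    if (any(sep)) {
      excluded <- bind_rows(excluded,
        tibble(snp = colnames(g)[which(keep)[sep]],
               reason = "perfect separation"))
      keep[which(keep)[sep]] <- FALSE
    }
  }
  if (!any(keep)) abort("All variants were excluded (monomorphic/separated).")
  gk <- g[, keep, drop = FALSE]

  if (cohort$config$trait_kind == "quantitative") {
    qx <- qr(X)
    yr <- qr.resid(qx, y)
    gr <- qr.resid(qx, gk)
    gg <- colSums(gr^2)
    beta <- colSums(gr * yr) / gg
    rss <- sum(yr^2) - beta^2 * gg
    df <- n - ncol(X) - 1L
    se <- sqrt(rss / df / gg)
    z <- beta / se
    p <- 2 * pt(abs(z), df, lower.tail = FALSE)
    neglog10p <- -(pt(abs(z), df, lower.tail = FALSE, log.p = TRUE) + log(2)) / LOG10
  } else {
    null_fit <- glm.fit(X, y, family = binomial())
    mu <- null_fit$fitted.values
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    GtWX <- crossprod(gk * w, X)
    U <- colSums(gk * (y - mu))
    V <- colSums(gk^2 * w) - rowSums((GtWX %*% solve(XtWX)) * GtWX)
    beta <- U / V
    se <- 1 / sqrt(V)
    z <- beta / se
    p <- z_to_p(z)
    neglog10p <- z_to_neglog10p(z)
  }

  out <- cohort$variants |>
    filter(.data$snp %in% colnames(gk)) |>
    mutate(af = unname(af[keep]), beta = unname(beta), se = unname(se),
           z = unname(z), p = unname(p), neglog10p = unname(neglog10p),
           n = n) |>
    select("snp", "chr", "pos", "effect_allele", "other_allele",
           "af", "beta", "se", "z", "p", "neglog10p", "n")
  attr(out, "excluded") <- excluded
  out
}

#' @importFrom stats glm.fit
NULL

#' Write / read the summary-statistics TSV dialect
#'
#' Column layout: `SNP, CHR, POS, A1, A2, AF, BETA, SE, P, N` where `A1` is
#' the effect allele.
#'
#' @param stats A summary-statistics tibble as from [compute_summary_stats()].
#' @param path Output file path.
#' @return `path`, invisibly (`write_sumstats`); the tibble (`read_sumstats`).
#' @export
write_sumstats <- function(stats, path) {
  stats |>
    select(SNP = "snp", CHR = "chr", POS = "pos", A1 = "effect_allele",
           A2 = "other_allele", AF = "af", BETA = "beta", SE = "se",
           P = "p", N = "n") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    select(snp = "SNP", chr = "CHR", pos = "POS", effect_allele = "A1",
           other_allele = "A2", af = "AF", beta = "BETA", se = "SE",
           p = "P", n = "N") |>
    mutate(chr = as.character(.data$chr),
           z = .data$beta / .data$se,
           neglog10p = z_to_neglog10p(.data$z))
}
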