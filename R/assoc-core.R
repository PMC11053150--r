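#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-study effect estimates for one variant (or, vectorised, for a
#' column-aligned set of variants) under the fixed-effects model:
#' \deqn{\beta = \frac{\sum_i b_i / se_i^2}{\sum_i 1/se_i^2}, \qquad
#'       se = \Big(\sum_i 1/se_i^2\Big)^{-1/2}.}
#' Alleles must already be harmonised to a common effect allele (see
#' [harmonize_alleles()]).
#'
#' @param records A data frame with one row per contributing study and columns
#'   `beta`, `se` (and optionally `n`). Additional columns are ignored.
#' @return A one-row tibble with `beta`, `se`, `z`, `p`, `neglog10p`,
#'   `n_total` (sum of `n`, `NA` if absent) and `n_studies`.
#' @examples
#' ivw_meta(data.frame(beta = c(0.2, 0), se = c(0.1, 0.1)))
#' @export
ivw_meta <- function(records) {
  assert_columns(records, c("beta", "se"), "records")
  if (nrow(records) < 1L) abort("ivw_meta() needs at least one record.")
  if (any(records$se <= 0)) abort("Standard errors must be positive.")
  w <- 1 / records$se^2
  beta <- sum(w * records$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  tibble(
    beta = beta, se = se, z = z,
    p = z_to_p(z), neglog10p = z_to_neglog10p(z),
    n_total = if ("n" %in% names(records)) sum(records$n) else NA_real_,
    n_studies = nrow(records)
  )
}

# Vectorised IVW across aligned per-population matrices (rows = variants,
# columns = populations). NA entries contribute nothing.
ivw_meta_matrix <- function(beta_mat, se_mat) {
  w <- 1 / se_mat^2
  w[is.na(beta_mat)] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  sw[rowSums(!is.na(w)) == 0L] <- NA
  beta <- rowSums(w * beta_mat, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  tibble(beta = beta, se = se, z = z,
         p = z_to_p(z), neglog10p = z_to_neglog10p(z))
}

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Harmonise two summary-statistic records for the same variant
#'
#' Aligns record `b`'s effect allele to record `a`'s. Swapped alleles flip
#' `b`'s beta sign and frequency; strand flips are resolved through base
#' complements. Strand-ambiguous palindromic pairs (A/T, C/G) are aligned by
#' allele-frequency similarity only when both minor allele frequencies are
#' below 0.4 and the frequencies differ by less than 0.2 under one
#' orientation; otherwise the pair is rejected.
#'
#' @param a,b One-row data frames with columns `snp`, `effect_allele`,
#'   `other_allele`, `af`, `beta` (and any others, carried through).
#' @return A list with elements `a`, `b` (aligned records), `action` (one of
#'   `"unchanged"`, `"flipped"`, `"strand_flipped"`, `"rejected"`) and
#'   `reason` (non-`NA` when rejected).
#' @export
harmonize_alleles <- function(a, b) {
  need <- c("effect_allele", "other_allele", "af", "beta")
  assert_columns(a, need, "a"); assert_columns(b, need, "b")
  pair_a <- paste(a$effect_allele, a$other_allele, sep = "/")
  alleles_a <- c(a$effect_allele, a$other_allele)
  alleles_b <- c(b$effect_allele, b$other_allele)
  flip <- function(b) {
    b$beta <- -b$beta
    b$af <- 1 - b$af
    tmp <- b$effect_allele
    b$effect_allele <- b$other_allele
    b$other_allele <- tmp
    b
  }
  result <- function(b, action, reason = NA_character_) {
    list(a = a, b = b, action = action, reason = reason)
  }

  if (pair_a %in% PALINDROMIC) {
    if (!setequal(alleles_a, alleles_b)) {
      abort(sprintf("Unresolvable allele mismatch for variant %s",
                    a$snp %||% "<unnamed>"))
    }
    maf_a <- pmin(a$af, 1 - a$af); maf_b <- pmin(b$af, 1 - b$af)
    if (maf_a >= 0.4 || maf_b >= 0.4) {
      return(result(b, "rejected", "palindromic with MAF >= 0.4"))
    }
    as_is <- abs(a$af - b$af)
    flipped <- abs(a$af - (1 - b$af))
    if (min(as_is, flipped) >= 0.2) {
      return(result(b, "rejected", "palindromic, frequencies unmatchable"))
    }
    if (flipped < as_is) {
      return(result(flip(b), "flipped"))
    }
    return(result(b, "unchanged"))
  }

  if (b$effect_allele == a$effect_allele && b$other_allele == a$other_allele) {
    return(result(b, "unchanged"))
  }
  if (b$effect_allele == a$other_allele && b$other_allele == a$effect_allele) {
    return(result(flip(b), "flipped"))
  }
  comp <- c(complement_allele(b$effect_allele), complement_allele(b$other_allele))
  if (identical(comp, alleles_a)) {
    b$effect_allele <- comp[1]; b$other_allele <- comp[2]
    return(result(b, "strand_flipped"))
  }
  if (identical(rev(comp), alleles_a)) {
    b$effect_allele <- comp[1]; b$other_allele <- comp[2]
    return(result(flip(b), "strand_flipped"))
  }
  abort(sprintf("Unresolvable allele mismatch for variant %s (%s vs %s/%s)",
                a$snp %||% "<unnamed>", pair_a,
                b$effect_allele, b$other_allele))
}
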