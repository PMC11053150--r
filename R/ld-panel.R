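#' Construct an LD reference panel
#'
#' Either from an individuals-by-variants dosage matrix (the usual case;
#' correlations, empirical dosage variances and allele frequencies are
#' computed from it) or directly from a correlation matrix plus allele
#' frequencies (in which case allele variances fall back to `2f(1-f)`).
#'
#' @param dosages Optional dosage matrix with variant ids as column names.
#' @param correlation Optional variant correlation matrix (ignored when
#'   `dosages` is given).
#' @param af Allele frequencies (required with `correlation`).
#' @param variant_ids Variant ids (defaults to column names).
#' @param population Population label.
#' @param n Panel sample size.
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(dosages = NULL, correlation = NULL, af = NULL,
                     variant_ids = NULL, population = "pop",
                     n = if (!is.null(dosages)) nrow(dosages) else NA_integer_) {
  if (!is.null(dosages)) {
    variant_ids <- variant_ids %||% colnames(dosages)
    if (is.null(variant_ids)) abort("Dosage matrix needs variant ids.")
    v <- apply(dosages, 2L, var)
    correlation <- suppressWarnings(cor(dosages))
    correlation[!is.finite(correlation)] <- 0
    diag(correlation) <- 1
    af <- colMeans(dosages) / 2
    allele_var <- v
  } else {
    if (is.null(correlation) || is.null(af)) {
      abort("Provide either `dosages` or both `correlation` and `af`.")
    }
    variant_ids <- variant_ids %||% colnames(correlation)
    if (is.null(variant_ids)) abort("Correlation matrix needs variant ids.")
    if (!isTRUE(all.equal(unname(correlation), unname(t(correlation)),
                          tolerance = 1e-8))) {
      abort("Panel correlation matrix must be symmetric.")
    }
    allele_var <- 2 * af * (1 - af)
  }
  dimnames(correlation) <- list(variant_ids, variant_ids)
  structure(
    list(variant_ids = variant_ids, correlation = correlation,
         allele_var = setNames(allele_var, variant_ids),
         af = setNames(af, variant_ids), population = population, n = n),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %s: %d variants, n = %s\n", x$population,
              length(x$variant_ids), x$n))
  invisible(x)
}

#' Squared correlation between two variants in a panel
#'
#' Variants absent from the panel contribute `r^2 = 0`, matching the
#' treatment of population-absent variants in sharing/novelty rules.
#'
#' @param panel An `ld_panel`.
#' @param a,b Variant ids.
#' @return `r^2` in \[0, 1\].
#' @export
panel_r2 <- function(panel, a, b) {
  if (!(a %in% panel$variant_ids) || !(b %in% panel$variant_ids)) return(0)
  unname(panel$correlation[a, b]^2)
}

#' Aggregate index variants into fine-mapping regions
#'
#' Expands each variant to a 1 Mb interval centred on it and merges
#' overlapping or bookended intervals on the same chromosome, so every
#' region spans at least 1 Mb and regions are disjoint.
#'
#' @param index_variants Data frame with columns `chr`, `pos` (1-based) and
#'   optionally `snp`.
#' @param flank Half-width of the interval around each variant (default
#'   500 kb).
#' @return A tibble with `region_id`, `chr`, `start`, `end` (1-based,
#'   inclusive), `n_members` and a `members` list-column of member variant
#'   ids (positions when `snp` is absent).
#' @export
build_regions <- function(index_variants, flank = 5e5) {
  if (nrow(index_variants) == 0L) {
    return(tibble(region_id = character(), chr = character(),
                  start = numeric(), end = numeric(),
                  n_members = integer(), members = list()))
  }
  assert_columns(index_variants, c("chr", "pos"), "index_variants")
  iv <- as_tibble(index_variants) |>
    mutate(chr = as.character(.data$chr),
           snp = if ("snp" %in% names(index_variants)) .data$snp
                 else as.character(.data$pos))
  gr <- GenomicRanges::GRanges(
    iv$chr, IRanges::IRanges(pmax(iv$pos - flank, 1), iv$pos + flank)
  )
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and bookended
  hit <- GenomicRanges::findOverlaps(gr, merged)
  members <- split(iv$snp[S4Vectors::queryHits(hit)],
                   factor(S4Vectors::subjectHits(hit),
                          levels = seq_along(merged)))
  tibble(
    chr = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged)
  ) |>
    mutate(region_id = sprintf("region_%d", row_number()),
           n_members = unname(lengths(members)),
           members = unname(members)) |>
    relocate("region_id")
}
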