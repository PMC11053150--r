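#' Simulation configuration for a two-population GWAS fixture
#'
#' Defines the conditions under which synthetic cohorts are generated: two
#' populations (labelled `"eur"` and `"eas"`) genotyped at a shared set of
#' variants laid out on one chromosome, a liability-scale phenotype with
#' shared and/or population-specific causal variants, and cis-acting
#' molecular traits (expression or methylation) for the QTL stages.
#'
#' Linkage disequilibrium is induced through a Gaussian copula: haplotypes
#' are thresholded latent autoregressive normals, so the latent correlation
#' between variants `i` and `j` is `ld_decay^|i-j|` and empirical dosage LD
#' decays with inter-variant distance.
#'
#' @param n_individuals Named integer vector, individuals per population,
#'   e.g. `c(eur = 2000, eas = 2000)`. A single unnamed value is recycled.
#' @param n_variants Number of variants in the simulated region.
#' @param ld_decay Latent adjacent-variant correlation in \[0, 1).
#' @param af_range Either a numeric pair applied to both populations or a
#'   named list `list(eur = c(lo, hi), eas = c(lo, hi))`; per-variant allele
#'   frequencies are drawn independently per population from this range, so
#'   ancestry-specific rare/absent signals arise naturally.
#' @param causal_spec Data frame with columns `variant` (index into
#'   `1:n_variants`), `eur`, `eas` (per-population liability effects per
#'   effect-allele copy, log-odds scale for binary traits). `NULL` for a
#'   fully null phenotype.
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param case_fraction Case proportion for binary traits (liability
#'   thresholded at its empirical `1 - case_fraction` quantile).
#' @param covariate_effects Named numeric vector of effects for the simulated
#'   covariates `age` (standardised) and `sex` (0/1).
#' @param n_genes Number of molecular traits for the QTL stages.
#' @param cis_effect_spec Data frame with columns `variant`, `gene` (indices)
#'   and `effect` (trait units per allele copy); `NULL` for no cis effects.
#' @param noise_sd Residual standard deviation of the liability / trait.
#' @param region_chr,region_start,region_span Chromosome label and coordinate
#'   layout; variant positions are drawn uniformly (then sorted) over
#'   `[region_start, region_start + region_span)`.
#' @param seed Integer seed; every generator derived from this config is a
#'   pure function of the config, including the seed.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_individuals = c(eur = 2000, eas = 2000),
                       n_variants = 50,
                       ld_decay = 0.9,
                       af_range = c(0.05, 0.95),
                       causal_spec = NULL,
                       trait_kind = c("binary", "quantitative"),
                       case_fraction = 0.4,
                       covariate_effects = c(age = 0, sex = 0),
                       n_genes = 5,
                       cis_effect_spec = NULL,
                       noise_sd = 1,
                       region_chr = "1",
                       region_start = 1e6,
                       region_span = 1e6,
                       seed = 42L) {
  trait_kind <- match.arg(trait_kind)
  if (length(n_individuals) == 1L && is.null(names(n_individuals))) {
    n_individuals <- c(eur = n_individuals, eas = n_individuals)
  }
  if (!setequal(names(n_individuals), c("eur", "eas"))) {
    abort("`n_individuals` must be named with populations 'eur' and 'eas'.")
  }
  if (any(n_individuals < 1) || n_variants < 1) {
    abort("Degenerate configuration: need at least one individual and one variant.")
  }
  if (ld_decay < 0 || ld_decay >= 1) abort("`ld_decay` must lie in [0, 1).")
  if (!is.list(af_range)) af_range <- list(eur = af_range, eas = af_range)
  for (pop in c("eur", "eas")) {
    r <- af_range[[pop]]
    if (length(r) != 2L || any(r <= 0) || any(r >= 1) || r[1] > r[2]) {
      abort("`af_range` bounds must be increasing frequencies in (0, 1).")
    }
  }
  if (trait_kind == "binary" &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    abort("`case_fraction` must lie in (0, 1).")
  }
  if (!is.null(causal_spec)) {
    causal_spec <- as_tibble(causal_spec)
    assert_columns(causal_spec, c("variant", "eur", "eas"), "causal_spec")
    if (any(causal_spec$variant < 1 | causal_spec$variant > n_variants)) {
      abort("`causal_spec$variant` indices out of range.")
    }
  }
  if (!is.null(cis_effect_spec)) {
    cis_effect_spec <- as_tibble(cis_effect_spec)
    assert_columns(cis_effect_spec, c("variant", "gene", "effect"),
                   "cis_effect_spec")
    if (any(cis_effect_spec$variant < 1 | cis_effect_spec$variant > n_variants) ||
        any(cis_effect_spec$gene < 1 | cis_effect_spec$gene > n_genes)) {
      abort("`cis_effect_spec` indices out of range.")
    }
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  structure(
    list(
      n_individuals = n_individuals, n_variants = as.integer(n_variants),
      ld_decay = ld_decay, af_range = af_range, causal_spec = causal_spec,
      trait_kind = trait_kind, case_fraction = case_fraction,
      covariate_effects = covariate_effects, n_genes = as.integer(n_genes),
      cis_effect_spec = cis_effect_spec, noise_sd = noise_sd,
      region_chr = as.character(region_chr), region_start = region_start,
      region_span = region_span, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d variants on chr%s:%d-%d, ld_decay = %.2f\n",
              x$n_variants, x$region_chr, x$region_start,
              x$region_start + x$region_span, x$ld_decay))
  cat(sprintf("  individuals: eur = %d, eas = %d; trait: %s\n",
              x$n_individuals[["eur"]], x$n_individuals[["eas"]], x$trait_kind))
  cat(sprintf("  causal variants: %d; genes: %d; cis effects: %d; seed %d\n",
              if (is.null(x$causal_spec)) 0L else nrow(x$causal_spec),
              x$n_genes,
              if (is.null(x$cis_effect_spec)) 0L else nrow(x$cis_effect_spec),
              x$seed))
  invisible(x)
}

# Deterministic sub-seeds for independent random streams, all < 2^31.
sim_seed <- function(config, stream) {
  offset <- c(layout = 1L, geno_eur = 2L, geno_eas = 3L, pheno_eur = 4L,
              pheno_eas = 5L, expr = 6L, annot = 7L, qtl = 8L)[[stream]]
  (config$seed %% 2000000000L) + offset
}

# Shared variant layout (ids, positions) and population AFs -- a pure
# function of the config, used by both populations.
sim_layout <- function(config) {
  withr::with_seed(sim_seed(config, "layout"), {
    pos <- sort(sample.int(config$region_span, config$n_variants)) +
      config$region_start - 1L
    af <- lapply(config$af_range, function(r) {
      runif(config$n_variants, r[1], r[2])
    })
    tibble(
      snp = sprintf("rs%05d", seq_len(config$n_variants)),
      chr = config$region_chr,
      pos = as.integer(pos),
      effect_allele = "A",
      other_allele = "G",
      af_eur = af$eur,
      af_eas = af$eas
    )
  })
}
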