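#' Simulate genotype dosages for one population
#'
#' Haplotypes are drawn from a Gaussian copula: each haplotype is a latent
#' AR(1) normal vector with adjacent correlation `ld_decay`, thresholded at
#' the population-specific allele-frequency quantile, and two haplotypes are
#' summed to a dosage in \{0, 1, 2\}. Adjacent-variant dosage LD therefore
#' decays geometrically with inter-variant index distance.
#'
#' @param config A [sim_config()].
#' @param population `"eur"` or `"eas"`.
#' @return A `cohort` object: list with `genotypes` (individuals x variants
#'   dosage matrix), `variants` (tibble: snp, chr, pos, alleles, target and
#'   empirical AF), `covariates` (tibble: age, sex), `population`, `config`.
#' @export
simulate_genotypes <- function(config, population = c("eur", "eas")) {
  stopifnot(inherits(config, "sim_config"))
  population <- match.arg(population)
  layout <- sim_layout(config)
  n <- config$n_individuals[[population]]
  m <- config$n_variants
  f <- layout[[paste0("af_", population)]]
  thr <- qnorm(f)
  rho <- config$ld_decay

  geno <- withr::with_seed(sim_seed(config, paste0("geno_", population)), {
    draw_haplotypes <- function() {
      z <- matrix(rnorm(2L * n * m), nrow = 2L * n, ncol = m)
      if (rho > 0 && m > 1L) {
        s <- sqrt(1 - rho^2)
        for (j in 2:m) z[, j] <- rho * z[, j - 1L] + s * z[, j]
      }
      # allele carrier indicator per haplotype
      sweep(z, 2L, thr, "<") * 1L
    }
    h <- draw_haplotypes()
    h[seq_len(n), , drop = FALSE] + h[n + seq_len(n), , drop = FALSE]
  })
  colnames(geno) <- layout$snp

  covariates <- withr::with_seed(sim_seed(config, paste0("geno_", population)) + 100L, {
    tibble(age = rnorm(n), sex = rbinom(n, 1L, 0.5))
  })

  variants <- layout |>
    mutate(af_target = f, af = colMeans(geno) / 2) |>
    select("snp", "chr", "pos", "effect_allele", "other_allele",
           "af_target", "af")

  structure(
    list(genotypes = geno, variants = variants, covariates = covariates,
         phenotype = NULL, population = population, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d individuals x %d variants%s\n",
              x$population, nrow(x$genotypes), ncol(x$genotypes),
              if (is.null(x$phenotype)) "" else
                sprintf(", %s phenotype", x$config$trait_kind)))
  invisible(x)
}

#' Simulate a phenotype on a genotyped cohort
#'
#' The liability is the causal-genotype score plus covariate effects plus
#' Gaussian noise. Quantitative traits return the liability itself; binary
#' traits threshold the liability at its empirical `1 - case_fraction`
#' quantile, so the realised case proportion matches the target by
#' construction.
#'
#' @param cohort A `cohort` from [simulate_genotypes()].
#' @param config Optional [sim_config()] override (defaults to the cohort's).
#' @return The cohort with `phenotype` (numeric; 0/1 for binary) and
#'   `liability` filled in.
#' @export
simulate_phenotype <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$genotypes)
  score <- numeric(n)
  if (!is.null(config$causal_spec)) {
    eff <- config$causal_spec[[cohort$population]]
    idx <- config$causal_spec$variant
    score <- as.numeric(cohort$genotypes[, idx, drop = FALSE] %*% eff)
  }
  ce <- config$covariate_effects
  cov_part <- ce[["age"]] * cohort$covariates$age +
    ce[["sex"]] * cohort$covariates$sex
  liability <- withr::with_seed(
    sim_seed(config, paste0("pheno_", cohort$population)),
    score + cov_part + rnorm(n, 0, config$noise_sd)
  )
  cohort$liability <- liability
  cohort$phenotype <- if (config$trait_kind == "binary") {
    if (config$case_fraction <= 0 || config$case_fraction >= 1) {
      abort("`case_fraction` must lie in (0, 1).")
    }
    as.numeric(liability > quantile(liability, 1 - config$case_fraction))
  } else {
    liability
  }
  cohort$config <- config
  cohort
}
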