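# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed inside each helper so tests are deterministic.

two_pop_config <- function(n = 3000, n_variants = 40,
                           causal = data.frame(variant = c(8L, 30L),
                                               eur = c(0.2, 0.18),
                                               eas = c(0.2, 0.18)),
                           seed = 7L, ...) {
  sim_config(n_individuals = c(eur = n, eas = n), n_variants = n_variants,
             causal_spec = causal, seed = seed, ...)
}

# Cohorts, summary statistics and panels for both populations.
two_pop_data <- function(config) {
  cohorts <- lapply(c(eur = "eur", eas = "eas"), function(pop) {
    simulate_phenotype(simulate_genotypes(config, pop))
  })
  list(
    cohorts = cohorts,
    stats = lapply(cohorts, compute_summary_stats),
    panels = lapply(cohorts, function(co) {
      ld_panel(co$genotypes, population = co$population)
    })
  )
}

# Summary statistics with exact chosen p-values (beta = z * se), plus an
# uncorrelated LD panel covering them: used for rule-application tests.
stats_with_p <- function(p, af = 0.3, n = 50000, chr = "1",
                         pos = seq_along(p) * 1000 + 1e6) {
  se <- 0.02
  z <- -qnorm(p / 2)
  tibble::tibble(
    snp = sprintf("v%02d", seq_along(p)), chr = chr, pos = pos,
    effect_allele = "A", other_allele = "G", af = af,
    beta = z * se, se = se, z = z, p = p,
    neglog10p = transmapr::z_to_neglog10p(z), n = n
  )
}

identity_panel <- function(snps, af = 0.3, population = "eur") {
  m <- diag(length(snps))
  dimnames(m) <- list(snps, snps)
  ld_panel(correlation = m, af = rep(af, length(snps)),
           population = population, n = 500)
}

# Minimal feature catalog built around explicit coordinates.
toy_catalog <- function(peaks = NULL, interactions = NULL, tads = NULL,
                        genes = NULL, drivers = character(),
                        expressed = NULL, consequences = NULL) {
  genes <- genes %||% tibble::tibble(
    gene_id = "GENEA", chr = "1", tss = 50000, strand = "+",
    biotype = "protein_coding"
  )
  peaks <- peaks %||% tibble::tibble(
    chr = character(), start = numeric(), end = numeric(),
    feature_class = character()
  )
  interactions <- interactions %||% tibble::tibble(
    chr1 = character(), start1 = numeric(), end1 = numeric(),
    chr2 = character(), start2 = numeric(), end2 = numeric(),
    provenance = character()
  )
  tads <- tads %||% tibble::tibble(chr = character(), start = numeric(),
                                   end = numeric())
  feature_catalog(peaks, interactions, tads, genes, drivers,
                  expressed %||% genes$gene_id, consequences)
}

`%||%` <- rlang::`%||%`

# Full boolean grid over the distal evidence flags.
distal_flag_grid <- function() {
  g <- expand.grid(experimental = c(FALSE, TRUE),
                   computational = c(FALSE, TRUE),
                   feature_overlap = c(FALSE, TRUE),
                   multi_interaction = c(FALSE, TRUE),
                   driver = c(FALSE, TRUE),
                   tad_separated = c(FALSE, TRUE),
                   not_expressed = c(FALSE, TRUE))
  tibble::as_tibble(g)
}

# brute-force sweep-line oracle for 1 Mb interval merging
sweep_merge <- function(chr, pos, flank = 5e5) {
  df <- data.frame(chr = as.character(chr), start = pmax(pos - flank, 1),
                   end = pos + flank)
  out <- list()
  for (cc in unique(df$chr)) {
    d <- df[df$chr == cc, ]
    d <- d[order(d$start), ]
    cur <- d[1, ]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur$end + 1) {
        cur$end <- max(cur$end, d$end[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- d[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# Bivariate-normal orthant probability P(Z1 < a, Z2 < b | rho) by 1-D
# numeric integration -- the independent oracle for the Gaussian-copula
# haplotype correlation.
orthant_prob <- function(a, b, rho) {
  integrand <- function(z) {
    dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(integrand, -Inf, a, rel.tol = 1e-10)$value
}
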