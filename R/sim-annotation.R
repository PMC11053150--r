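#' Deterministic gene table for a simulated region
#'
#' `n_genes` genes with TSS evenly spaced across the region, alternating
#' strands, all protein-coding.
#'
#' @param config A [sim_config()].
#' @return Tibble `gene_id`, `chr`, `tss`, `strand`, `biotype`.
#' @export
sim_gene_table <- function(config) {
  k <- config$n_genes
  tibble(
    gene_id = sprintf("GENE%02d", seq_len(k)),
    chr = config$region_chr,
    tss = as.integer(round(config$region_start +
                             config$region_span * seq_len(k) / (k + 1))),
    strand = rep(c("+", "-"), length.out = k),
    biotype = "protein_coding"
  )
}

#' Generate functional-annotation fixtures consistent with a simulation
#'
#' Builds a [feature_catalog()] aligned with the simulated variant and
#' gene coordinates: an enhancer (H3K27ac) plus open-chromatin peak over
#' every cis-effect variant, an H3K4me3 promoter peak over every gene
#' promoter, TF-binding peaks over driver-targeting variants, background
#' peaks of every class placed away from the causal variants, and one
#' experimental plus (for every second cis effect) one computational
#' chromatin interaction joining each cis-effect enhancer to its target
#' gene promoter. All genes are marked expressed; driver and consequence
#' tables are empty unless supplied.
#'
#' When `dir` is given the catalog is also written as plain-text files
#' (one BED per feature class, a BEDPE, a TAD BED, gene table TSV, gene
#' lists, consequence TSV); outputs are byte-identical for a fixed config.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @param peak_halfwidth Half-width of generated peaks in bases.
#' @param drivers,consequences Optional driver gene ids and consequence
#'   tibble to embed.
#' @return The [feature_catalog()] (invisibly carries `files`, the written
#'   paths, when `dir` is given).
#' @export
simulate_annotation_fixtures <- function(config, dir = NULL,
                                         peak_halfwidth = 500,
                                         drivers = character(),
                                         consequences = NULL) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  genes <- sim_gene_table(config)
  hw <- peak_halfwidth
  chr <- config$region_chr

  peak_at <- function(pos, cls) {
    tibble(chr = chr, start = pmax(pos - 1 - hw, 0), end = pos + hw,
           feature_class = cls)
  }
  cis <- config$cis_effect_spec
  peaks <- list()
  interactions <- tibble(chr1 = character(), start1 = numeric(),
                         end1 = numeric(), chr2 = character(),
                         start2 = numeric(), end2 = numeric(),
                         provenance = character())
  if (!is.null(cis) && nrow(cis) > 0L) {
    vpos <- layout$pos[cis$variant]
    peaks$enh <- peak_at(vpos, "enhancer")
    peaks$oc <- peak_at(vpos, "open_chromatin")
    prom <- promoter_windows(genes)
    g <- prom[cis$gene, ]
    interactions <- tibble(
      chr1 = chr, start1 = pmax(vpos - 1 - hw, 0), end1 = vpos + hw,
      chr2 = chr, start2 = g$start - 1, end2 = g$end,
      provenance = "experimental"
    )
    comp <- interactions[seq_len(nrow(interactions)) %% 2L == 0L, ]
    if (nrow(comp) > 0L) {
      comp$provenance <- "computational"
      interactions <- bind_rows(interactions, comp)
    }
  }
  prom_all <- promoter_windows(genes)
  peaks$k4 <- tibble(chr = chr, start = prom_all$start - 1,
                     end = prom_all$end, feature_class = "promoter")
  # background peaks of every class, placed deterministically
  peaks$bg <- withr::with_seed(sim_seed(config, "annot"), {
    k <- length(FEATURE_CLASSES)
    pos <- config$region_start +
      sort(sample.int(config$region_span, 2L * k))
    tibble(chr = chr, start = pos - 1 - hw, end = pos + hw,
           feature_class = rep(FEATURE_CLASSES, each = 2L))
  })
  peaks <- bind_rows(peaks)

  tads <- tibble(chr = chr,
                 start = config$region_start + config$region_span + 1e4,
                 end = config$region_start + config$region_span + 2e4)

  catalog <- feature_catalog(
    peaks = peaks, interactions = interactions, tads = tads, genes = genes,
    drivers = drivers, expressed = genes$gene_id,
    consequences = consequences
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c()
    for (cls in FEATURE_CLASSES) {
      f <- file.path(dir, paste0(cls, ".bed"))
      write_bed(peaks |> filter(.data$feature_class == cls) |>
                  mutate(name = cls), f)
      files <- c(files, f)
    }
    f <- file.path(dir, "interactions.bedpe")
    write_bedpe(interactions, f); files <- c(files, f)
    f <- file.path(dir, "tad_boundaries.bed")
    write_bed(tads |> mutate(name = "tad_boundary"), f); files <- c(files, f)
    f <- file.path(dir, "genes.tsv")
    readr::write_tsv(genes, f); files <- c(files, f)
    f <- file.path(dir, "driver_genes.txt")
    readr::write_lines(drivers, f); files <- c(files, f)
    f <- file.path(dir, "expressed_genes.txt")
    readr::write_lines(genes$gene_id, f); files <- c(files, f)
    f <- file.path(dir, "consequences.tsv")
    readr::write_tsv(catalog$consequences, f); files <- c(files, f)
    attr(catalog, "files") <- files
  }
  catalog
}

#' Simulate a cis-QTL dataset (genotypes plus molecular traits)
#'
#' Draws a genotyped sample from the configured population, then generates
#' one molecular trait per gene: the configured cis effects times dosage
#' plus standard normal noise. Expression datasets carry age, sex and five
#' genotype principal components as covariates; methylation datasets carry
#' age, sex and colon side. Trait anchors are gene TSSs (expression) or a
#' CpG placed at the TSS (methylation).
#'
#' @param config A [sim_config()].
#' @param population `"eur"` or `"eas"`.
#' @param n_samples Dataset sample size.
#' @param dataset Dataset label.
#' @param kind `"expression"` or `"methylation"`.
#' @return List with `dosages`, `variant_meta`, `traits` (traits x
#'   samples), `trait_meta`, `covariates`, `dataset`, `kind`.
#' @export
simulate_qtl_dataset <- function(config, population = "eur",
                                 n_samples = 400, dataset = "dataset1",
                                 kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  sub <- config
  sub$n_individuals[] <- n_samples
  # dataset-specific stream: offset the seed deterministically
  sub$seed <- config$seed + 1000L * (sum(utf8ToInt(dataset)) %% 1000L)
  sub <- do.call(sim_config, sub[setdiff(names(sub), NULL)])
  cohort <- simulate_genotypes(sub, population)
  genes <- sim_gene_table(config)

  traits <- withr::with_seed(sim_seed(sub, "qtl"), {
    e <- matrix(rnorm(config$n_genes * n_samples),
                nrow = config$n_genes,
                dimnames = list(genes$gene_id, NULL))
    cis <- config$cis_effect_spec
    if (!is.null(cis) && nrow(cis) > 0L) {
      for (i in seq_len(nrow(cis))) {
        e[cis$gene[i], ] <- e[cis$gene[i], ] +
          cis$effect[i] * cohort$genotypes[, cis$variant[i]]
      }
    }
    e
  })

  covariates <- if (kind == "expression") {
    # ancestry-PC stand-ins: genome-wide principal components cannot be
    # derived from a single simulated region, so independent Gaussian
    # covariates play their role in the adjustment model
    pcs <- withr::with_seed(sim_seed(sub, "qtl") + 2L, {
      matrix(rnorm(5L * n_samples), n_samples, 5L,
             dimnames = list(NULL, paste0("PC", 1:5)))
    })
    bind_cols(cohort$covariates, as_tibble(pcs))
  } else {
    withr::with_seed(sim_seed(sub, "qtl") + 1L, {
      cohort$covariates |> mutate(colon_side = rbinom(n_samples, 1L, 0.5))
    })
  }

  trait_id_prefix <- if (kind == "expression") "" else "cg_"
  trait_meta <- tibble(
    trait_id = paste0(trait_id_prefix, genes$gene_id),
    chr = genes$chr, anchor = genes$tss
  )
  rownames(traits) <- trait_meta$trait_id

  list(dosages = cohort$genotypes, variant_meta = cohort$variants,
       traits = traits, trait_meta = trait_meta, covariates = covariates,
       dataset = dataset, kind = kind, n = n_samples)
}

#' Simulate a raw expression counts / TPM pair
#'
#' Log-normal TPM with Poisson counts proportional to TPM, for exercising
#' the expression filter and normalisation.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples.
#' @param mean_log_tpm,sd_log_tpm Per-gene log-TPM distribution parameters.
#' @return List with genes-by-samples `counts` and `tpm` matrices.
#' @export
simulate_expression_counts <- function(config, n_samples = 100,
                                       mean_log_tpm = 2, sd_log_tpm = 1) {
  genes <- sim_gene_table(config)
  withr::with_seed(sim_seed(config, "expr"), {
    base <- rnorm(config$n_genes, mean_log_tpm, sd_log_tpm)
    tpm <- exp(matrix(rnorm(config$n_genes * n_samples, base, 0.5),
                      nrow = config$n_genes,
                      dimnames = list(genes$gene_id, NULL)))
    counts <- matrix(rpois(length(tpm), tpm * 10),
                     nrow = config$n_genes,
                     dimnames = dimnames(tpm))
    list(counts = counts, tpm = tpm)
  })
}
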