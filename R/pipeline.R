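default_pipeline_config <- function() {
  list(
    seed = 42L,
    sim = list(
      n_individuals = c(eur = 6000, eas = 6000),
      n_variants = 50,
      ld_decay = 0.9,
      causal_spec = data.frame(variant = c(10L, 40L),
                               eur = c(0.15, 0.15), eas = c(0.15, 0.15)),
      trait_kind = "binary",
      case_fraction = 0.4,
      n_genes = 5,
      cis_effect_spec = data.frame(variant = c(10L, 40L), gene = c(2L, 4L),
                                   effect = c(0.5, 0.4))
    ),
    thresholds = list(),         # fm_thresholds() overrides
    qtl = list(n_samples = 300, expression_datasets = c("eqtl_eur", "eqtl_eas"),
               methylation_datasets = "mqtl_eur", alpha = 0.05),
    scoring = list(penalty = 0.1, promoter_upstream = 100,
                   promoter_downstream = 1000,
                   distal_gt = 4, proximal_gt = 1, coding_gt = 1),
    smr = list(alpha = 0.05),
    tiers = list(A = character(), B = character(), C = character()),
    drivers = character()
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys by name, and range-checks thresholds. An empty configuration
#' yields the full default set.
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return A validated `pipeline_config` list; overridden keys are
#'   recorded in its `overrides` attribute.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  thr_unknown <- setdiff(names(config$thresholds %||% list()),
                         names(formals(fm_thresholds)))
  if (length(thr_unknown) > 0L) {
    abort(sprintf("Unknown threshold key(s): %s",
                  paste(thr_unknown, collapse = ", ")))
  }
  overrides <- names(config)
  merged <- modifyList(defaults, config)
  # materialise and range-check
  merged$thresholds <- do.call(fm_thresholds, merged$thresholds)
  if (!is.null(merged$sim$causal_spec)) {
    merged$sim$causal_spec <- as.data.frame(merged$sim$causal_spec)
  }
  if (!is.null(merged$sim$cis_effect_spec)) {
    merged$sim$cis_effect_spec <- as.data.frame(merged$sim$cis_effect_spec)
  }
  if (!is.null(merged$sim$n_individuals)) {
    merged$sim$n_individuals <- unlist(merged$sim$n_individuals)
  }
  merged$sim$seed <- merged$sim$seed %||% merged$seed
  sim_cfg <- do.call(sim_config, merged$sim)   # validates ranges
  merged$sim_config <- sim_cfg
  structure(merged, class = "pipeline_config", overrides = overrides)
}

#' Run the full fine-mapping and gene-nomination pipeline
#'
#' Executes the stages end to end on fully synthetic data: simulate (two
#' populations, phenotypes, summary statistics, annotation), finemap
#' (region construction, stepwise signal search, stabilisation), ccv,
#' qtl (per-dataset cis scans, sample-size-weighted meta-analysis,
#' per-signal Bonferroni), smr, score (evidence flags and INQUISIT-style
#' scores) and the credible gene set. Stage outputs are written as TSV
#' under `out_dir` together with `manifest.json` (configuration hash,
#' seed, package version, per-stage row counts). Reruns with an identical
#' configuration are byte-identical.
#'
#' @param config A `pipeline_config` from [validate_config()] (or
#'   anything it accepts).
#' @param out_dir Output directory.
#' @return The manifest list, invisibly; stage results in the
#'   `results` attribute.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("transmapr_run_")) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim_cfg <- config$sim_config
  thr <- config$thresholds
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- simulate ---------------------------------------------------------
  res <- stage("simulate", {
    cohorts <- lapply(c(eur = "eur", eas = "eas"), function(pop) {
      simulate_phenotype(simulate_genotypes(sim_cfg, pop))
    })
    stats <- lapply(cohorts, compute_summary_stats)
    for (pop in names(stats)) {
      write_sumstats(stats[[pop]], file.path(out_dir,
                                             sprintf("sumstats_%s.tsv", pop)))
    }
    panels <- lapply(cohorts, function(co) {
      ld_panel(co$genotypes, population = co$population)
    })
    list(cohorts = cohorts, stats = stats, panels = panels)
  })
  counts$simulate <- sum(vapply(res$stats, nrow, integer(1)))

  # -- finemap ----------------------------------------------------------
  layout <- sim_layout(sim_cfg)
  reported <- if (!is.null(sim_cfg$causal_spec)) {
    layout$snp[sim_cfg$causal_spec$variant]
  } else character()
  region <- stage("finemap", {
    regions <- build_regions(layout |>
                               filter(.data$snp %in% reported) |>
                               select("chr", "pos", "snp"))
    finemap_region(res$stats, res$panels, thr,
                   region_id = regions$region_id[1] %||% "region_1",
                   reported = reported)
  })
  readr::write_tsv(as_tibble(region$signals) |> select(-dplyr::any_of("members")),
                   file.path(out_dir, "signals.tsv"))
  counts$finemap <- nrow(region$signals)

  # -- ccv --------------------------------------------------------------
  ccvs <- stage("ccv", ccv_table(region))
  readr::write_tsv(ccvs, file.path(out_dir, "ccvs.tsv"))
  counts$ccv <- nrow(ccvs)

  # -- qtl --------------------------------------------------------------
  qtl <- stage("qtl", {
    ccv_snps <- unique(ccvs$snp)
    scan_one <- function(ds, pop, kind) {
      d <- simulate_qtl_dataset(sim_cfg, population = pop,
                                n_samples = config$qtl$n_samples,
                                dataset = ds, kind = kind)
      cis_qtl_scan(d$dosages, d$variant_meta, d$traits, d$trait_meta,
                   d$covariates, ccvs = ccv_snps, dataset = ds)
    }
    ex <- config$qtl$expression_datasets
    per_ds <- c(
      purrr::map(seq_along(ex), function(i) {
        scan_one(ex[i], if (grepl("eas", ex[i])) "eas" else "eur",
                 "expression")
      }),
      purrr::map(config$qtl$methylation_datasets, scan_one,
                 pop = "eur", kind = "methylation")
    )
    assocs <- bind_rows(per_ds)
    meta <- stouffer_meta(assocs)
    fam <- ccvs |> distinct(.data$signal_id, snp = .data$lead)
    meta_idx <- meta |>
      dplyr::inner_join(fam, by = "snp", relationship = "many-to-many") |>
      mutate(kind = if_else(grepl("^cg_", .data$trait_id),
                            "methylation", "expression")) |>
      group_by(.data$kind) |>
      dplyr::group_modify(~ bonferroni_per_family(.x, "signal_id",
                                                  config$qtl$alpha)) |>
      ungroup()
    list(assocs = assocs, meta = meta, meta_idx = meta_idx)
  })
  readr::write_tsv(qtl$assocs, file.path(out_dir, "qtl_associations.tsv"))
  readr::write_tsv(qtl$meta_idx, file.path(out_dir, "qtl_meta.tsv"))
  counts$qtl <- nrow(qtl$assocs)

  # -- smr --------------------------------------------------------------
  smr <- stage("smr", {
    smr_scan(as_tibble(region$signals) |>
               select("signal_id", "snp", "z"),
             qtl$meta, alpha = config$smr$alpha)
  })
  readr::write_tsv(smr, file.path(out_dir, "smr.tsv"))
  counts$smr <- nrow(smr)

  # -- score ------------------------------------------------------------
  scored <- stage("score", {
    catalog <- simulate_annotation_fixtures(sim_cfg,
                                            dir = file.path(out_dir, "annotation"),
                                            drivers = config$drivers)
    ccv_pos <- ccvs |>
      left_join(layout |> select("snp", "chr"), by = "snp") |>
      distinct(.data$snp, .data$chr, .data$pos)
    evidence <- bind_rows(
      find_distal_links(ccv_pos, catalog,
                        config$scoring$promoter_upstream,
                        config$scoring$promoter_downstream),
      find_proximal_links(ccv_pos, catalog,
                          config$scoring$promoter_upstream,
                          config$scoring$promoter_downstream),
      find_coding_links(ccv_pos, catalog)
    )
    scores <- score_gene_targets(evidence,
                                 ccvs |> select("snp", "signal_id"),
                                 penalty = config$scoring$penalty)
    conf <- confident_targets(scores, config$scoring$distal_gt,
                              config$scoring$proximal_gt,
                              config$scoring$coding_gt, keep_all = TRUE)
    list(catalog = catalog, evidence = evidence, scores = conf)
  })
  readr::write_tsv(scored$evidence, file.path(out_dir, "evidence.tsv"))
  readr::write_tsv(scored$scores, file.path(out_dir, "gene_scores.tsv"))
  counts$score <- nrow(scored$scores)

  # -- credible ---------------------------------------------------------
  credible <- stage("credible", {
    coloc_genes <- smr |>
      filter(.data$significant, !grepl("^cg_", .data$trait_id)) |>
      select("signal_id", gene_id = "trait_id")
    candidates <- bind_rows(
      scored$scores |> filter(.data$confident) |>
        select("signal_id", "gene_id"),
      coloc_genes
    )
    assemble_credible_set(candidates, config$tiers, scored$catalog$genes)
  })
  readr::write_tsv(credible, file.path(out_dir, "credible_genes.tsv"))
  counts$credible <- nrow(credible)

  manifest <- list(
    package_version = as.character(utils::packageVersion("transmapr")),
    seed = sim_cfg$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "sim_config")]),
    overrides = attr(config, "overrides"),
    stages = names(counts),
    rows = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "results") <- list(region = region, ccvs = ccvs, qtl = qtl,
                                    smr = smr, scores = scored$scores,
                                    credible = credible, out_dir = out_dir)
  invisible(manifest)
}
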