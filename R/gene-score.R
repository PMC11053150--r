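#' Point-based evidence scores for CCV-gene links
#'
#' Implements the modified-INQUISIT scoring ledger.
#'
#' *Distal* (range 0-6): 2 points for an experimental chromatin
#' interaction, 1 for a computational one, 3 when both; +1 when the CCV
#' overlaps genomic features (open chromatin, enhancer, TF binding); +1
#' when the CCV participates in at least two interactions; +1 for
#' driver genes. The score is down-weighted by the factor
#' `penalty` (default 0.1) when the pair is separated by a TAD boundary or
#' the gene is not expressed.
#'
#' *Proximal* (range 0-2): 1 point for TF-binding-site overlap, +1 for
#' driver genes; down-weighted to 10% when the gene is not expressed.
#'
#' *Coding* (range 0-2): 1 point for a deleterious consequence
#' (deleterious missense, nonsense, or predicted splice alteration), +1
#' for driver genes; down-weighted to 10% when the gene is not expressed.
#'
#' @param evidence Evidence tibble (see [find_distal_links()] and
#'   companions); vectorised over rows.
#' @param penalty Down-weighting factor for penalty flags (default 0.1).
#' @return Numeric score vector.
#' @name scoring
NULL

#' @rdname scoring
#' @export
score_distal <- function(evidence, penalty = 0.1) {
  base <- if_else(evidence$experimental & evidence$computational, 3,
                  2 * evidence$experimental + 1 * evidence$computational)
  s <- base + evidence$feature_overlap + evidence$multi_interaction +
    evidence$driver
  s <- s * if_else(evidence$tad_separated | evidence$not_expressed,
                   penalty, 1)
  pmin(pmax(s, 0), 6)
}

#' @rdname scoring
#' @export
score_proximal <- function(evidence, penalty = 0.1) {
  s <- 1 * evidence$tf_binding_overlap + 1 * evidence$driver
  s <- s * if_else(evidence$not_expressed, penalty, 1)
  pmin(pmax(s, 0), 2)
}

#' @rdname scoring
#' @export
score_coding <- function(evidence, penalty = 0.1) {
  s <- 1 * evidence$deleterious_coding + 1 * evidence$driver
  s <- s * if_else(evidence$not_expressed, penalty, 1)
  pmin(pmax(s, 0), 2)
}

#' Score all CCV-gene links and aggregate per signal and gene
#'
#' Applies the class-appropriate score to every evidence row, then takes,
#' for each (signal, gene, link class), the maximum score over that
#' signal's CCVs.
#'
#' @param evidence Combined evidence tibble (rows from the three link
#'   finders).
#' @param ccv_signals Tibble mapping CCVs to signals: `snp`, `signal_id`.
#' @param penalty Down-weighting factor (see [score_distal()]).
#' @return A `fm_scores` tibble: `signal_id`, `gene_id`, `distal`,
#'   `proximal`, `coding` (0 when a class has no link).
#' @export
score_gene_targets <- function(evidence, ccv_signals, penalty = 0.1) {
  assert_columns(ccv_signals, c("snp", "signal_id"), "ccv_signals")
  if (nrow(evidence) == 0L) {
    out <- tibble(signal_id = character(), gene_id = character(),
                  distal = numeric(), proximal = numeric(),
                  coding = numeric())
    return(structure(out, class = c("fm_scores", class(out))))
  }
  scored <- evidence |>
    mutate(score = dplyr::case_when(
      .data$link_class == "distal" ~ score_distal(evidence, penalty),
      .data$link_class == "proximal" ~ score_proximal(evidence, penalty),
      .data$link_class == "coding" ~ score_coding(evidence, penalty)
    )) |>
    dplyr::inner_join(ccv_signals, by = "snp",
                      relationship = "many-to-many") |>
    group_by(.data$signal_id, .data$gene_id, .data$link_class) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "link_class", values_from = "score",
                       values_fill = 0)
  for (cls in c("distal", "proximal", "coding")) {
    if (!cls %in% names(scored)) scored[[cls]] <- 0
  }
  out <- scored |> select("signal_id", "gene_id", "distal", "proximal",
                          "coding")
  structure(out, class = c("fm_scores", class(out)))
}

#' Confident target genes
#'
#' A (signal, gene) pair is a confident target when its distal score
#' exceeds 4, its proximal score exceeds 1, or its coding score exceeds 1
#' (strict inequalities).
#'
#' @param scores A `fm_scores` tibble from [score_gene_targets()].
#' @param distal_gt,proximal_gt,coding_gt Strict thresholds.
#' @return `scores` with a `confident` column, filtered to confident rows
#'   when `keep_all = FALSE` (default).
#' @param keep_all Keep non-confident rows (flagged) instead of dropping.
#' @export
confident_targets <- function(scores, distal_gt = 4, proximal_gt = 1,
                              coding_gt = 1, keep_all = FALSE) {
  out <- scores |>
    mutate(confident = .data$distal > distal_gt |
             .data$proximal > proximal_gt | .data$coding > coding_gt)
  if (!keep_all) out <- out |> filter(.data$confident)
  out
}

#' Assemble the tiered credible gene set
#'
#' Filters candidate target genes to protein-coding genes outside the MHC
#' region, assigns each the highest tier it reaches in the supplied
#' prior-evidence gene lists (prioritisation A > B > C), and resolves
#' signals with multiple candidates: keep the highest-tier members, or all
#' members when none is tiered. Signals with a single candidate keep it
#' regardless of tier. The operation is idempotent.
#'
#' @param candidates Tibble of candidate (signal, gene) pairs:
#'   `signal_id`, `gene_id` (typically confident targets and/or
#'   significant colocalizations).
#' @param tiers Named list of character vectors `list(A = ..., B = ...,
#'   C = ...)` of previously supported genes.
#' @param genes Gene table with `gene_id`, `chr`, `tss` and `biotype`.
#' @param mhc MHC interval as `list(chr, start, end)` (GRCh37 default
#'   chr6:28,477,797-33,448,354); genes whose TSS falls inside are
#'   excluded.
#' @return A `fm_credible` tibble: `signal_id`, `gene_id`, `tier`
#'   (`"A"`, `"B"`, `"C"` or `"none"`), `retained`.
#' @export
assemble_credible_set <- function(candidates, tiers, genes,
                                  mhc = list(chr = "6", start = 28477797,
                                             end = 33448354)) {
  assert_columns(candidates, c("signal_id", "gene_id"), "candidates")
  tiers <- modifyList(list(A = character(), B = character(),
                           C = character()), as.list(tiers))
  gene_info <- genes |>
    mutate(biotype = if ("biotype" %in% names(genes)) .data$biotype
           else "protein_coding")
  out <- candidates |>
    distinct(.data$signal_id, .data$gene_id) |>
    left_join(gene_info |> select("gene_id", "chr", "tss", "biotype"),
              by = "gene_id") |>
    filter(.data$biotype == "protein_coding",
           !(as.character(.data$chr) == as.character(mhc$chr) &
               .data$tss >= mhc$start & .data$tss <= mhc$end)) |>
    mutate(tier = dplyr::case_when(
      .data$gene_id %in% tiers$A ~ "A",
      .data$gene_id %in% tiers$B ~ "B",
      .data$gene_id %in% tiers$C ~ "C",
      TRUE ~ "none"
    )) |>
    group_by(.data$signal_id) |>
    mutate(best = min(match(.data$tier, c("A", "B", "C", "none"))),
           retained = dplyr::n() == 1L | .data$best == 4L |
             match(.data$tier, c("A", "B", "C", "none")) == .data$best) |>
    ungroup() |>
    filter(.data$retained) |>
    select("signal_id", "gene_id", "tier", "retained")
  structure(out, class = c("fm_credible", class(out)))
}
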