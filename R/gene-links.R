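#' Strand-aware gene promoter windows
#'
#' The promoter is the interval from `upstream` bases upstream to
#' `downstream` bases downstream of the transcription start site (defaults
#' 100 bp upstream, 1 kb downstream; the two distances can be flipped via
#' the arguments).
#'
#' @param genes Gene table (`gene_id`, `chr`, `tss`, `strand`).
#' @param upstream,downstream Window extents in bases.
#' @return Tibble `gene_id`, `chr`, `start`, `end` (1-based inclusive).
#' @export
promoter_windows <- function(genes, upstream = 100, downstream = 1000) {
  genes |>
    mutate(
      start = if_else(.data$strand == "+",
                      .data$tss - upstream, .data$tss - downstream),
      end = if_else(.data$strand == "+",
                    .data$tss + downstream, .data$tss + upstream),
      start = pmax(.data$start, 1)
    ) |>
    select("gene_id", "chr", "start", "end")
}

empty_evidence <- function() {
  tibble(snp = character(), gene_id = character(), link_class = character(),
         experimental = logical(), computational = logical(),
         feature_overlap = logical(), multi_interaction = logical(),
         driver = logical(), tad_separated = logical(),
         not_expressed = logical(), tf_binding_overlap = logical(),
         deleterious_coding = logical())
}

#' Distal CCV-to-gene links through enhancer-promoter interactions
#'
#' A (CCV, gene) distal link exists when the CCV falls inside an
#' interaction anchor that overlaps an H3K27ac (enhancer) peak while the
#' partner anchor overlaps the gene's promoter window. Evidence flags per
#' link: interaction provenance (`experimental` / `computational`),
#' `multi_interaction` (the CCV participates in at least two qualifying
#' interactions), `feature_overlap` (CCV in an open-chromatin, enhancer or
#' TF-binding peak), `driver` (gene in the driver set), `tad_separated` (a
#' TAD-boundary midpoint lies strictly between CCV and TSS) and
#' `not_expressed` (gene absent from the expressed set). Genes absent from
#' the gene table are skipped with a message.
#'
#' @inheritParams annotate_ccvs
#' @param upstream,downstream Promoter window extents (see
#'   [promoter_windows()]).
#' @return Evidence tibble, one row per (CCV, gene) with
#'   `link_class = "distal"`.
#' @export
find_distal_links <- function(ccvs, catalog, upstream = 100,
                              downstream = 1000) {
  assert_columns(ccvs, c("snp", "chr", "pos"), "ccvs")
  ccvs <- as_tibble(ccvs) |> mutate(chr = as.character(.data$chr))
  ia <- catalog$interactions
  if (nrow(ia) == 0L) return(empty_evidence())

  v_gr <- granges_from_pos(ccvs$chr, ccvs$pos)
  k27 <- catalog$peaks |> filter(.data$feature_class == "enhancer")
  k27_gr <- granges_from_bed(k27)
  prom <- promoter_windows(catalog$genes, upstream, downstream)
  prom_gr <- GenomicRanges::GRanges(prom$chr,
                                    IRanges::IRanges(prom$start, prom$end))

  anchor <- function(side) {
    granges_from_bed(tibble(chr = ia[[paste0("chr", side)]],
                            start = ia[[paste0("start", side)]],
                            end = ia[[paste0("end", side)]]))
  }
  links <- purrr::map(1:2, function(side) {
    a <- anchor(side); b <- anchor(3L - side)
    a_enh <- IRanges::overlapsAny(a, k27_gr)
    cv_hit <- GenomicRanges::findOverlaps(v_gr, a)
    pr_hit <- GenomicRanges::findOverlaps(b, prom_gr)
    tibble(ccv_i = S4Vectors::queryHits(cv_hit),
           ia_i = S4Vectors::subjectHits(cv_hit)) |>
      filter(a_enh[.data$ia_i]) |>
      dplyr::inner_join(
        tibble(ia_i = S4Vectors::queryHits(pr_hit),
               gene_i = S4Vectors::subjectHits(pr_hit)),
        by = "ia_i", relationship = "many-to-many")
  }) |> bind_rows()
  if (nrow(links) == 0L) return(empty_evidence())

  links <- links |>
    mutate(snp = ccvs$snp[.data$ccv_i],
           gene_id = prom$gene_id[.data$gene_i],
           provenance = ia$provenance[.data$ia_i]) |>
    distinct(.data$snp, .data$gene_id, .data$ia_i, .data$provenance)

  # at least two qualifying interactions per CCV (any gene)
  multi <- links |>
    distinct(.data$snp, .data$ia_i) |>
    count(.data$snp) |>
    mutate(multi_interaction = .data$n >= 2L) |>
    select("snp", "multi_interaction")

  ann <- annotate_ccvs(ccvs, catalog)
  feat <- ann |>
    mutate(feature_overlap = .data$open_chromatin | .data$enhancer |
             .data$tf_binding) |>
    select("snp", "feature_overlap")

  out <- links |>
    group_by(.data$snp, .data$gene_id) |>
    summarise(experimental = any(.data$provenance == "experimental"),
              computational = any(.data$provenance == "computational"),
              .groups = "drop") |>
    left_join(multi, by = "snp") |>
    left_join(feat, by = "snp") |>
    left_join(ccvs |> select("snp", "pos"), by = "snp") |>
    left_join(catalog$genes |> select("gene_id", "tss"), by = "gene_id")

  dropped <- out |> filter(is.na(.data$tss))
  if (nrow(dropped) > 0L) {
    inform(sprintf("Gene(s) absent from gene table, skipped: %s",
                   paste(unique(dropped$gene_id), collapse = ", ")))
    out <- out |> filter(!is.na(.data$tss))
  }
  out |>
    mutate(link_class = "distal",
           driver = .data$gene_id %in% catalog$drivers,
           not_expressed = !.data$gene_id %in% catalog$expressed,
           tad_separated = purrr::map2_lgl(.data$pos, .data$tss,
                                           tad_between, tads = catalog$tads),
           tf_binding_overlap = FALSE, deleterious_coding = FALSE) |>
    select(all_of(names(empty_evidence())))
}

# TRUE when a TAD-boundary midpoint lies strictly between two positions
tad_between <- function(pos, tss, tads) {
  if (nrow(tads) == 0L) return(FALSE)
  mid <- (tads$start + tads$end) / 2
  lo <- min(pos, tss); hi <- max(pos, tss)
  any(mid > lo & mid < hi)
}

#' Proximal CCV-to-gene links through active promoters
#'
#' A (CCV, gene) proximal link exists when the CCV lies inside the gene's
#' promoter window *and* inside an H3K4me3 (active promoter) peak.
#' Evidence flags: `tf_binding_overlap` (CCV in a TF-binding peak),
#' `driver`, `not_expressed`.
#'
#' @inheritParams find_distal_links
#' @return Evidence tibble with `link_class = "proximal"`.
#' @export
find_proximal_links <- function(ccvs, catalog, upstream = 100,
                                downstream = 1000) {
  assert_columns(ccvs, c("snp", "chr", "pos"), "ccvs")
  ccvs <- as_tibble(ccvs) |> mutate(chr = as.character(.data$chr))
  ann <- annotate_ccvs(ccvs, catalog)
  in_k4 <- ann$promoter
  prom <- promoter_windows(catalog$genes, upstream, downstream)
  v_gr <- granges_from_pos(ccvs$chr, ccvs$pos)
  prom_gr <- GenomicRanges::GRanges(prom$chr,
                                    IRanges::IRanges(prom$start, prom$end))
  hit <- GenomicRanges::findOverlaps(v_gr, prom_gr)
  links <- tibble(ccv_i = S4Vectors::queryHits(hit),
                  gene_i = S4Vectors::subjectHits(hit)) |>
    filter(in_k4[.data$ccv_i])
  if (nrow(links) == 0L) return(empty_evidence())
  links |>
    mutate(snp = ccvs$snp[.data$ccv_i],
           gene_id = prom$gene_id[.data$gene_i],
           link_class = "proximal",
           experimental = FALSE, computational = FALSE,
           feature_overlap = FALSE, multi_interaction = FALSE,
           driver = .data$gene_id %in% catalog$drivers,
           tad_separated = FALSE,
           not_expressed = !.data$gene_id %in% catalog$expressed,
           tf_binding_overlap = ann$tf_binding[.data$ccv_i],
           deleterious_coding = FALSE) |>
    distinct() |>
    select(all_of(names(empty_evidence())))
}

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "splice", "synonymous")

#' Coding CCV-to-gene links from the consequence table
#'
#' One link per consequence-table row matching a CCV.
#' `deleterious_coding` is true for deleterious missense variants and for
#' all nonsense and predicted splice-altering variants. Unknown
#' consequence classes raise an error.
#'
#' @inheritParams find_distal_links
#' @return Evidence tibble with `link_class = "coding"`.
#' @export
find_coding_links <- function(ccvs, catalog) {
  assert_columns(ccvs, c("snp"), "ccvs")
  cons <- catalog$consequences |> filter(.data$snp %in% ccvs$snp)
  if (nrow(cons) == 0L) return(empty_evidence())
  bad <- setdiff(unique(cons$consequence), CONSEQUENCE_CLASSES)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown consequence class(es): %s",
                  paste(bad, collapse = ", ")))
  }
  cons |>
    mutate(link_class = "coding",
           experimental = FALSE, computational = FALSE,
           feature_overlap = FALSE, multi_interaction = FALSE,
           driver = .data$gene_id %in% catalog$drivers,
           tad_separated = FALSE,
           not_expressed = !.data$gene_id %in% catalog$expressed,
           tf_binding_overlap = FALSE,
           deleterious_coding =
             (.data$consequence == "missense" & .data$deleterious) |
             .data$consequence %in% c("nonsense", "splice")) |>
    select(all_of(names(empty_evidence())))
}
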