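#' Read a BED (BED3+name) interval file
#'
#' Coordinates are 0-based half-open on disk and kept that way in the
#' returned tibble (`start`, `end`); conversion to 1-based happens at
#' overlap time. Malformed lines raise an error naming the line.
#'
#' @param path File path (tab-separated, no header: chrom, start, end,
#'   optional name).
#' @return Tibble with `chr`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chr = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) == 0L) {
    starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(starts) | is.na(ends) | starts < 0 | starts >= ends)
  }
  if (length(bad) > 0L) {
    abort(sprintf("Malformed BED line %d in %s: '%s'",
                  bad[1], path, lines[bad[1]]))
  }
  tibble(
    chr = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    name = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  )
}

#' @rdname read_bed
#' @param intervals Tibble with `chr`, `start`, `end` and optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals |>
    mutate(name = if ("name" %in% names(intervals)) .data$name else ".") |>
    select("chr", "start", "end", "name")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a BEDPE paired-interval file
#'
#' Ten-column BEDPE dialect: chrom1, start1, end1, chrom2, start2, end2,
#' name, score, strand1, strand2; only the first seven are used (the name
#' field carries the interaction provenance, `"experimental"` or
#' `"computational"`).
#'
#' @param path File path.
#' @return Tibble with `chr1`, `start1`, `end1`, `chr2`, `start2`, `end2`,
#'   `provenance`.
#' @export
read_bedpe <- function(path) {
  cols <- c("chr1", "start1", "end1", "chr2", "start2", "end2", "provenance")
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L) {
    return(as_tibble(setNames(
      list(character(), numeric(), numeric(), character(), numeric(),
           numeric(), character()), cols)))
  }
  if (ncol(df) < 7L) abort(sprintf("BEDPE file %s needs >= 7 columns.", path))
  df <- df[, 1:7]
  names(df) <- cols
  df |> mutate(chr1 = as.character(.data$chr1), chr2 = as.character(.data$chr2))
}

#' @rdname read_bedpe
#' @param pairs Tibble with `chr1`, `start1`, `end1`, `chr2`, `start2`,
#'   `end2`, `provenance`.
#' @export
write_bedpe <- function(pairs, path) {
  pairs |>
    select("chr1", "start1", "end1", "chr2", "start2", "end2", "provenance") |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

FEATURE_CLASSES <- c("open_chromatin", "active_transcription", "promoter",
                     "enhancer", "repressed", "tf_binding")

#' Assemble a functional-feature catalog
#'
#' Bundles the annotation inputs of the gene-nomination stage: regulatory
#' peaks for the six feature classes (open chromatin, transcribed regions
#' of active genes, promoter H3K4me3, enhancer H3K27ac, repressed
#' elements, TF binding sites), chromatin interactions (experimental and
#' computational), TAD boundaries, the gene table, driver and expressed
#' gene sets, and the precomputed coding-consequence table.
#'
#' @param peaks Tibble `chr`, `start`, `end` (0-based half-open),
#'   `feature_class` (one of the six classes).
#' @param interactions Tibble `chr1`, `start1`, `end1`, `chr2`, `start2`,
#'   `end2`, `provenance` (`"experimental"`/`"computational"`).
#' @param tads Tibble of TAD-boundary intervals `chr`, `start`, `end`.
#' @param genes Tibble `gene_id`, `chr`, `tss`, `strand` (`"+"`/`"-"`),
#'   `biotype`.
#' @param drivers,expressed Character vectors of gene ids.
#' @param consequences Tibble `snp`, `gene_id`, `consequence` (one of
#'   `missense`, `nonsense`, `splice`, `synonymous`), `deleterious`
#'   (logical; meaningful for missense).
#' @return A `feature_catalog` object.
#' @export
feature_catalog <- function(peaks, interactions, tads, genes,
                            drivers = character(), expressed = character(),
                            consequences = NULL) {
  assert_columns(peaks, c("chr", "start", "end", "feature_class"), "peaks")
  bad <- setdiff(unique(peaks$feature_class), FEATURE_CLASSES)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown feature class(es): %s", paste(bad, collapse = ", ")))
  }
  if (any(peaks$start >= peaks$end)) abort("Peak intervals must have start < end.")
  assert_columns(interactions,
                 c("chr1", "start1", "end1", "chr2", "start2", "end2",
                   "provenance"), "interactions")
  assert_columns(genes, c("gene_id", "chr", "tss", "strand"), "genes")
  if (is.null(consequences)) {
    consequences <- tibble(snp = character(), gene_id = character(),
                           consequence = character(), deleterious = logical())
  }
  structure(
    list(peaks = as_tibble(peaks), interactions = as_tibble(interactions),
         tads = as_tibble(tads), genes = as_tibble(genes),
         drivers = drivers, expressed = expressed,
         consequences = as_tibble(consequences)),
    class = "feature_catalog"
  )
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf(paste0("<feature_catalog> %d peaks, %d interactions, %d TAD",
                     " boundaries, %d genes (%d drivers, %d expressed),",
                     " %d coding consequences\n"),
              nrow(x$peaks), nrow(x$interactions), nrow(x$tads),
              nrow(x$genes), length(x$drivers), length(x$expressed),
              nrow(x$consequences)))
  invisible(x)
}

# GRanges from 0-based half-open intervals
granges_from_bed <- function(df) {
  GenomicRanges::GRanges(df$chr, IRanges::IRanges(df$start + 1, df$end))
}

# GRanges of width-1 loci from 1-based positions
granges_from_pos <- function(chr, pos) {
  GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
}

#' Annotate CCVs against the catalog's peak classes
#'
#' A variant at 1-based position `p` overlaps a 0-based half-open interval
#' `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param ccvs Tibble with `snp`, `chr`, `pos` (1-based).
#' @param catalog A [feature_catalog()].
#' @return Tibble with `snp`, `chr`, `pos` and one logical column per
#'   feature class.
#' @export
annotate_ccvs <- function(ccvs, catalog) {
  assert_columns(ccvs, c("snp", "chr", "pos"), "ccvs")
  ccvs <- as_tibble(ccvs) |> mutate(chr = as.character(.data$chr))
  v <- granges_from_pos(ccvs$chr, ccvs$pos)
  flags <- lapply(FEATURE_CLASSES, function(cls) {
    pk <- catalog$peaks |> filter(.data$feature_class == cls)
    if (nrow(pk) == 0L) return(rep(FALSE, nrow(ccvs)))
    IRanges::overlapsAny(v, granges_from_bed(pk))
  })
  names(flags) <- FEATURE_CLASSES
  bind_cols(ccvs |> select("snp", "chr", "pos"), as_tibble(flags))
}
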