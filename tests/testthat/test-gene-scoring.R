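test_that("peak overlap follows 0-based half-open vs 1-based position rules", {
  cat1 <- toy_catalog(peaks = tibble::tibble(
    chr = "1", start = 100, end = 101, feature_class = "enhancer"))
  ccvs <- tibble::tibble(snp = c("a", "b", "c"), chr = "1",
                         pos = c(101, 100, 102))
  ann <- annotate_ccvs(ccvs, cat1)
  expect_true(ann$enhancer[ann$snp == "a"])    # pos 101 hits [100, 101)
  expect_false(ann$enhancer[ann$snp == "b"])   # pos 100 does not
  expect_false(ann$enhancer[ann$snp == "c"])
})

test_that("annotation matches a brute-force all-pairs oracle on a random fixture", {
  set.seed(7)
  ccvs <- tibble::tibble(snp = sprintf("v%04d", 1:1000), chr = "1",
                         pos = sample.int(1e6, 1000))
  starts <- sample.int(1e6, 200)
  peaks <- tibble::tibble(chr = "1", start = starts,
                          end = starts + sample(50:500, 200, replace = TRUE),
                          feature_class = sample(
                            c("enhancer", "open_chromatin", "tf_binding"),
                            200, replace = TRUE))
  ann <- annotate_ccvs(ccvs, toy_catalog(peaks = peaks))
  for (cls in c("enhancer", "open_chromatin", "tf_binding")) {
    pk <- peaks[peaks$feature_class == cls, ]
    oracle <- vapply(ccvs$pos, function(p) {
      any(pk$start <= p - 1 & p - 1 < pk$end)
    }, logical(1))
    expect_identical(ann[[cls]], oracle)
  }
})

test_that("malformed BED lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20\tok", "1\t30\t25\tbad"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("1\t10\t20\tok"), path)
  expect_identical(nrow(read_bed(path)), 1L)
})

test_that("promoter windows are strand aware and flippable", {
  genes <- tibble::tibble(gene_id = c("plus", "minus"), chr = "1",
                          tss = c(10000, 20000), strand = c("+", "-"),
                          biotype = "protein_coding")
  w <- promoter_windows(genes)
  expect_equal(w$start[w$gene_id == "plus"], 10000 - 100)
  expect_equal(w$end[w$gene_id == "plus"], 10000 + 1000)
  expect_equal(w$start[w$gene_id == "minus"], 20000 - 1000)
  expect_equal(w$end[w$gene_id == "minus"], 20000 + 100)
  flipped <- promoter_windows(genes, upstream = 1000, downstream = 100)
  expect_equal(flipped$start[flipped$gene_id == "plus"], 9000)
})

distal_fixture <- function(provenance = "experimental", with_tad = FALSE,
                           extra_loop = FALSE) {
  genes <- tibble::tibble(gene_id = "GENEA", chr = "1", tss = 50000,
                          strand = "+", biotype = "protein_coding")
  # CCV at 10,500 inside an enhancer anchor [10000, 11000)
  loops <- tibble::tibble(chr1 = "1", start1 = 10000, end1 = 11000,
                          chr2 = "1", start2 = 49800, end2 = 50500,
                          provenance = provenance[1])
  if (length(provenance) > 1) {
    for (pv in provenance[-1]) {
      loops <- dplyr::bind_rows(loops, dplyr::mutate(loops[1, ],
                                                     provenance = pv))
    }
  }
  if (extra_loop) {
    loops <- dplyr::bind_rows(loops, tibble::tibble(
      chr1 = "1", start1 = 10200, end1 = 10800, chr2 = "1",
      start2 = 49900, end2 = 50200, provenance = "experimental"))
  }
  peaks <- tibble::tibble(chr = "1", start = 10400, end = 10600,
                          feature_class = "enhancer")
  tads <- if (with_tad) {
    tibble::tibble(chr = "1", start = 30000, end = 30400)
  } else {
    tibble::tibble(chr = character(), start = numeric(), end = numeric())
  }
  toy_catalog(peaks = peaks, interactions = loops, tads = tads,
              genes = genes)
}

test_that("distal links require an enhancer anchor looping to a promoter", {
  ccvs <- tibble::tibble(snp = "ccv1", chr = "1", pos = 10500)
  ev <- find_distal_links(ccvs, distal_fixture("experimental"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$gene_id, "GENEA")
  expect_true(ev$experimental)
  expect_false(ev$computational)
  expect_false(ev$multi_interaction)
  expect_true(ev$feature_overlap)   # the CCV sits in the H3K27ac peak
  expect_false(ev$tad_separated)

  # same loop present in both provenance sets: one link, both flags
  both <- find_distal_links(ccvs, distal_fixture(c("experimental",
                                                   "computational")))
  expect_identical(nrow(both), 1L)
  expect_true(both$experimental && both$computational)

  # two distinct qualifying interactions: multi_interaction set
  multi <- find_distal_links(ccvs, distal_fixture("experimental",
                                                  extra_loop = TRUE))
  expect_true(multi$multi_interaction)

  # TAD boundary between CCV and TSS flips the penalty flag
  tad <- find_distal_links(ccvs, distal_fixture("experimental",
                                                with_tad = TRUE))
  expect_true(tad$tad_separated)

  # a CCV outside any anchor yields nothing
  none <- find_distal_links(tibble::tibble(snp = "x", chr = "1",
                                           pos = 200000),
                            distal_fixture("experimental"))
  expect_identical(nrow(none), 0L)
})

test_that("proximal links need promoter residence plus an H3K4me3 peak", {
  genes <- tibble::tibble(gene_id = "GENEA", chr = "1", tss = 50000,
                          strand = "+", biotype = "protein_coding")
  peaks <- tibble::tibble(
    chr = "1", start = c(49900, 50050), end = c(50100, 50060),
    feature_class = c("promoter", "tf_binding"))
  cat1 <- toy_catalog(peaks = peaks, genes = genes)
  # inside promoter window and K4me3 peak, and in the TF peak
  hit <- find_proximal_links(tibble::tibble(snp = "a", chr = "1",
                                            pos = 50055), cat1)
  expect_identical(nrow(hit), 1L)
  expect_true(hit$tf_binding_overlap)
  # inside the promoter window but outside any K4me3 peak
  miss <- find_proximal_links(tibble::tibble(snp = "b", chr = "1",
                                             pos = 50500), cat1)
  expect_identical(nrow(miss), 0L)
})

test_that("coding links classify consequences and reject unknown classes", {
  genes <- tibble::tibble(gene_id = c("G1", "G2"), chr = "1",
                          tss = c(1000, 2000), strand = "+",
                          biotype = "protein_coding")
  cons <- tibble::tibble(
    snp = c("a", "b", "c", "d"),
    gene_id = c("G1", "G1", "G2", "G2"),
    consequence = c("missense", "missense", "nonsense", "synonymous"),
    deleterious = c(TRUE, FALSE, FALSE, FALSE))
  cat1 <- toy_catalog(genes = genes, consequences = cons)
  ccvs <- tibble::tibble(snp = c("a", "b", "c", "d"), chr = "1", pos = 1:4)
  ev <- find_coding_links(ccvs, cat1)
  expect_identical(nrow(ev), 4L)
  expect_true(ev$deleterious_coding[ev$snp == "a"])    # deleterious missense
  expect_false(ev$deleterious_coding[ev$snp == "b"])   # benign missense
  expect_true(ev$deleterious_coding[ev$snp == "c"])    # nonsense
  expect_false(ev$deleterious_coding[ev$snp == "d"])   # synonymous

  bad <- cat1
  bad$consequences$consequence[1] <- "frameshift_exotic"
  expect_error(find_coding_links(ccvs, bad), "frameshift_exotic")
})

test_that("scoring reproduces the worked point values", {
  ev <- function(...) {
    row <- utils::modifyList(as.list(empty_flags()), list(...))
    tibble::as_tibble(row)
  }
  empty_flags <- function() {
    list(experimental = FALSE, computational = FALSE,
         feature_overlap = FALSE, multi_interaction = FALSE,
         driver = FALSE, tad_separated = FALSE, not_expressed = FALSE,
         tf_binding_overlap = FALSE, deleterious_coding = FALSE)
  }
  # distal: experimental alone = 2; all bonuses, no penalty = 6
  expect_equal(score_distal(ev(experimental = TRUE)), 2)
  expect_equal(score_distal(ev(computational = TRUE)), 1)
  expect_equal(score_distal(ev(experimental = TRUE, computational = TRUE)), 3)
  all_on <- ev(experimental = TRUE, computational = TRUE,
               feature_overlap = TRUE, multi_interaction = TRUE,
               driver = TRUE)
  expect_equal(score_distal(all_on), 6)
  # a TAD separation cuts the full score to 10%
  all_tad <- dplyr::mutate(all_on, tad_separated = TRUE)
  expect_equal(score_distal(all_tad), 0.6)
  # proximal: TF + driver = 2; TF only, not expressed = 0.1
  expect_equal(score_proximal(ev(tf_binding_overlap = TRUE, driver = TRUE)), 2)
  expect_equal(score_proximal(ev()), 0)
  expect_equal(score_proximal(ev(tf_binding_overlap = TRUE,
                                 not_expressed = TRUE)), 0.1)
  # coding: deleterious + driver = 2; benign non-driver = 0;
  # deleterious not expressed = 0.1
  expect_equal(score_coding(ev(deleterious_coding = TRUE, driver = TRUE)), 2)
  expect_equal(score_coding(ev()), 0)
  expect_equal(score_coding(ev(deleterious_coding = TRUE,
                               not_expressed = TRUE)), 0.1)
})

test_that("score ranges hold over the exhaustive flag grid and scores are monotone", {
  grid <- distal_flag_grid()
  grid$tf_binding_overlap <- FALSE
  grid$deleterious_coding <- FALSE
  d <- score_distal(grid)
  expect_true(all(d >= 0 & d <= 6))
  expect_equal(max(d), 6)
  expect_equal(min(d), 0)

  # monotonicity: raising any bonus flag never lowers the score; raising a
  # penalty flag never raises it
  bonus <- c("experimental", "computational", "feature_overlap",
             "multi_interaction", "driver")
  for (fl in bonus) {
    off <- grid[!grid[[fl]], ]
    on <- off; on[[fl]] <- TRUE
    expect_true(all(score_distal(on) >= score_distal(off) - 1e-12),
                info = fl)
  }
  for (fl in c("tad_separated", "not_expressed")) {
    off <- grid[!grid[[fl]], ]
    on <- off; on[[fl]] <- TRUE
    expect_true(all(score_distal(on) <= score_distal(off) + 1e-12),
                info = fl)
  }

  pgrid <- tidyr::expand_grid(tf_binding_overlap = c(FALSE, TRUE),
                              driver = c(FALSE, TRUE),
                              not_expressed = c(FALSE, TRUE))
  p <- score_proximal(pgrid)
  expect_true(all(p >= 0 & p <= 2))
  expect_equal(max(p), 2)
  cgrid <- tidyr::expand_grid(deleterious_coding = c(FALSE, TRUE),
                              driver = c(FALSE, TRUE),
                              not_expressed = c(FALSE, TRUE))
  cs <- score_coding(cgrid)
  expect_true(all(cs >= 0 & cs <= 2))
  expect_equal(max(cs), 2)
})

test_that("per-signal gene scores take the maximum over CCVs and confident thresholds are strict", {
  ev <- tibble::tibble(
    snp = c("c1", "c2", "c3"), gene_id = "G1", link_class = "distal",
    experimental = c(TRUE, TRUE, TRUE),
    computational = c(FALSE, TRUE, TRUE),
    feature_overlap = c(FALSE, TRUE, TRUE),
    multi_interaction = c(FALSE, FALSE, TRUE),
    driver = FALSE, tad_separated = FALSE, not_expressed = FALSE,
    tf_binding_overlap = FALSE, deleterious_coding = FALSE)
  map <- tibble::tibble(snp = c("c1", "c2", "c3"),
                        signal_id = c("s1", "s1", "s2"))
  sc <- score_gene_targets(ev, map)
  expect_equal(sc$distal[sc$signal_id == "s1"], 4)  # max(2, 4)
  expect_equal(sc$distal[sc$signal_id == "s2"], 5)

  conf <- confident_targets(sc, keep_all = TRUE)
  expect_false(conf$confident[conf$signal_id == "s1"])  # 4 is not > 4
  expect_true(conf$confident[conf$signal_id == "s2"])   # 5 > 4
  expect_true(confident_targets(
    tibble::tibble(signal_id = "x", gene_id = "g", distal = 0,
                   proximal = 2, coding = 0), keep_all = TRUE)$confident)
  expect_false(confident_targets(
    tibble::tibble(signal_id = "x", gene_id = "g", distal = 0,
                   proximal = 1, coding = 1), keep_all = TRUE)$confident)
})

test_that("credible gene assembly applies tiering, biotype and MHC rules idempotently", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gC", "gN1", "gN2", "gLnc", "gMhc"),
    chr = c("1", "1", "1", "1", "1", "6"),
    tss = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6, 3e7),
    strand = "+",
    biotype = c(rep("protein_coding", 4), "lincRNA", "protein_coding"))
  tiers <- list(A = "gA", B = character(), C = "gC")

  # multiple candidates: highest tier wins
  multi <- tibble::tibble(signal_id = "s1", gene_id = c("gA", "gC", "gN1"))
  out <- assemble_credible_set(multi, tiers, genes)
  expect_identical(out$gene_id, "gA")
  expect_identical(out$tier, "A")

  # no tiered member: all retained
  none <- tibble::tibble(signal_id = "s2", gene_id = c("gN1", "gN2"))
  out2 <- assemble_credible_set(none, tiers, genes)
  expect_setequal(out2$gene_id, c("gN1", "gN2"))

  # single candidate kept regardless of tier
  single <- tibble::tibble(signal_id = "s3", gene_id = "gN1")
  out3 <- assemble_credible_set(single, tiers, genes)
  expect_identical(out3$gene_id, "gN1")
  expect_identical(out3$tier, "none")

  # non-coding and MHC genes are excluded
  excl <- tibble::tibble(signal_id = "s4", gene_id = c("gLnc", "gMhc", "gC"))
  out4 <- assemble_credible_set(excl, tiers, genes)
  expect_identical(out4$gene_id, "gC")

  # idempotence
  again <- assemble_credible_set(out |> dplyr::select("signal_id", "gene_id"),
                                 tiers, genes)
  expect_equal(as.data.frame(again), as.data.frame(out))
})
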