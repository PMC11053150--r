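test_that("region construction merges overlapping and bookended 1 Mb intervals", {
  r <- build_regions(data.frame(chr = "1", pos = c(1e6, 1.6e6)))
  expect_identical(nrow(r), 1L)
  expect_equal(r$start, 5e5)
  expect_equal(r$end, 2.1e6)
  expect_identical(r$n_members, 2L)

  r2 <- build_regions(data.frame(chr = "1", pos = c(1e6, 3e6)))
  expect_identical(nrow(r2), 2L)
  expect_true(all(r2$end - r2$start + 1 >= 1e6))

  expect_identical(nrow(build_regions(data.frame(chr = character(),
                                                 pos = numeric()))), 0L)
})

test_that("region construction matches the sweep-line oracle on 205 variants", {
  set.seed(99)
  iv <- data.frame(chr = as.character(sample(1:5, 205, replace = TRUE)),
                   pos = sample.int(5e7, 205))
  got <- build_regions(iv)
  want <- sweep_merge(iv$chr, iv$pos)
  expect_identical(nrow(got), nrow(want))
  got_o <- got[order(got$chr, got$start), ]
  want_o <- want[order(want$chr, want$start), ]
  expect_equal(got_o$start, want_o$start)
  expect_equal(got_o$end, want_o$end)
  expect_identical(sum(got$n_members), 205L)
})

test_that("conditional analysis is the identity with no conditioning and orthogonal panels", {
  p <- c(1e-8, 1e-3, 0.2)
  st <- stats_with_p(p)
  panel <- identity_panel(st$snp)
  none <- conditional_analysis(st, panel)
  expect_equal(none$beta_c, st$beta)
  expect_equal(none$se_c, st$se)

  cond <- conditional_analysis(st, panel, conditioning = "v01")
  expect_equal(cond$beta_c, st$beta[-1], tolerance = 1e-6)
})

test_that("summary-based conditional analysis reproduces exact joint OLS with the cohort as panel", {
  cfg <- sim_config(n_individuals = c(eur = 800, eas = 50), n_variants = 12,
                    trait_kind = "quantitative", ld_decay = 0.8,
                    causal_spec = data.frame(variant = c(3L, 9L),
                                             eur = c(0.3, 0.2),
                                             eas = c(0, 0)),
                    seed = 61L)
  co <- simulate_phenotype(simulate_genotypes(cfg, "eur"))
  ss <- compute_summary_stats(co, adjust_covariates = FALSE)
  panel <- ld_panel(co$genotypes, population = "eur")
  cond_set <- c("rs00003", "rs00009")
  got <- conditional_analysis(ss, panel, conditioning = cond_set)
  for (i in seq_len(nrow(got))) {
    t_snp <- got$snp[i]
    fit <- lm(co$phenotype ~ co$genotypes[, cond_set] +
                co$genotypes[, t_snp])
    est <- summary(fit)$coefficients[4, ]
    expect_equal(got$beta_c[i], unname(est["Estimate"]), tolerance = 0.01)
    expect_equal(got$se_c[i], unname(est["Std. Error"]), tolerance = 0.01)
  }
})

test_that("collinear targets are masked rather than estimated", {
  snps <- c("v01", "v02", "v03")
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.99
  dimnames(R) <- list(snps, snps)
  panel <- ld_panel(correlation = R, af = rep(0.3, 3), population = "eur",
                    n = 500)
  st <- stats_with_p(c(1e-8, 1e-7, 1e-3))
  out <- conditional_analysis(st, panel, conditioning = "v01")
  expect_false(out$estimable[out$snp == "v02"])
  expect_true(out$estimable[out$snp == "v03"])
  expect_true(is.na(out$beta_c[out$snp == "v02"]))
})

test_that("stepwise search returns no signals when nothing clears the threshold", {
  cfg <- two_pop_config(n = 500, n_variants = 15, causal = NULL, seed = 71L)
  d <- two_pop_data(cfg)
  for (mode in c("trans", "eur", "eas")) {
    sg <- stepwise_search(d$stats, d$panels, mode)
    expect_identical(nrow(sg), 0L)
  }
})

test_that("stepwise search finds a strong shared signal and tags the causal variant", {
  cfg <- two_pop_config(n = 6000, n_variants = 30,
                        causal = data.frame(variant = 12L, eur = 0.25,
                                            eas = 0.25),
                        seed = 73L)
  d <- two_pop_data(cfg)
  sg <- stepwise_search(d$stats, d$panels, "trans")
  expect_identical(nrow(sg), 1L)
  expect_gt(panel_r2(d$panels$eur, sg$snp[1], "rs00012"), 0.8)
  expect_lt(sg$p[1], 1e-6)
  # output invariant to input row order
  shuf <- lapply(d$stats, function(s) s[rev(seq_len(nrow(s))), ])
  sg2 <- stepwise_search(shuf, d$panels, "trans")
  expect_identical(sg$snp, sg2$snp)
})

test_that("two weakly-linked causal variants produce two stabilised signals", {
  cfg <- two_pop_config(n = 8000, n_variants = 40,
                        causal = data.frame(variant = c(8L, 32L),
                                            eur = c(0.2, 0.2),
                                            eas = c(0.2, 0.2)),
                        seed = 79L)
  d <- two_pop_data(cfg)
  expect_lt(panel_r2(d$panels$eur, "rs00008", "rs00032"), 0.1)
  sg <- stepwise_search(d$stats, d$panels, "trans")
  st <- stabilize_indices(sg, d$stats, d$panels)
  expect_identical(nrow(st), 2L)
  r2_truth <- vapply(c("rs00008", "rs00032"), function(cv) {
    max(vapply(st$snp, function(s) panel_r2(d$panels$eur, s, cv), numeric(1)))
  }, numeric(1))
  expect_true(all(r2_truth > 0.8))
  # every retained signal keeps conditional p below the entry threshold
  expect_true(all(st$p < 1e-6))
  expect_true(attr(st, "converged"))
})

test_that("index stabilisation is a fixed point for already-optimal indices and undoes proxy perturbations", {
  cfg <- two_pop_config(n = 8000, n_variants = 40,
                        causal = data.frame(variant = c(8L, 32L),
                                            eur = c(0.2, 0.2),
                                            eas = c(0.2, 0.2)),
                        seed = 83L)
  d <- two_pop_data(cfg)
  sg <- stepwise_search(d$stats, d$panels, "trans")
  st <- stabilize_indices(sg, d$stats, d$panels)
  again <- stabilize_indices(st, d$stats, d$panels)
  expect_identical(st$snp, again$snp)

  # replace each index by its most correlated neighbour and re-stabilise
  perturbed <- st
  for (i in seq_len(nrow(perturbed))) {
    r2 <- d$panels$eur$correlation[perturbed$snp[i], ]^2
    r2[perturbed$snp] <- -1
    proxy <- names(which.max(r2))
    perturbed$snp[i] <- proxy
  }
  back <- stabilize_indices(perturbed, d$stats, d$panels)
  expect_setequal(back$snp, st$snp)
})

test_that("single-signal sets pass through stabilisation unchanged", {
  cfg <- two_pop_config(n = 6000, n_variants = 20,
                        causal = data.frame(variant = 10L, eur = 0.25,
                                            eas = 0.25),
                        seed = 89L)
  d <- two_pop_data(cfg)
  sg <- stepwise_search(d$stats, d$panels, "trans")
  expect_identical(nrow(sg), 1L)
  st <- stabilize_indices(sg, d$stats, d$panels)
  expect_identical(st$snp, sg$snp)
})

test_that("sharing classification applies the r2 > 0.1 rule and the novelty rule", {
  snps <- c("lead_eur", "lead_trans", "far", "reported1")
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- sqrt(0.15)   # r2 = 0.15 with the trans lead
  R[3, 4] <- R[4, 3] <- sqrt(0.5)    # 'far' correlated with a reported variant
  dimnames(R) <- list(snps, snps)
  panels <- list(eur = ld_panel(correlation = R, af = rep(0.3, 4),
                                population = "eur", n = 500),
                 eas = identity_panel(snps, population = "eas"))
  thr <- fm_thresholds()
  mk <- function(snp, mode) {
    transmapr:::new_fm_signals(
      tibble::tibble(rank = 1L, snp = snp, chr = "1", pos = 1e6,
                     beta = 0.1, se = 0.01, z = 10, p = 1e-23,
                     neglog10p = 23, mode = mode),
      mode, thr)
  }
  trans <- mk("lead_trans", "trans")

  same <- classify_signals(mk("lead_trans", "eur"), trans, panels)
  expect_true(same$shared_with_trans)

  corr <- classify_signals(mk("lead_eur", "eur"), trans, panels)
  expect_true(corr$shared_with_trans)     # r2 = 0.15 > 0.1
  expect_identical(corr$scope, "trans")

  spec <- classify_signals(mk("far", "eur"), trans, panels)
  expect_false(spec$shared_with_trans)
  expect_identical(spec$scope, "eur_specific")

  # novelty: correlated with a previously reported variant in either panel
  nv <- classify_signals(mk("far", "eur"), trans, panels,
                         reported = "reported1")
  expect_false(nv$novel)
  nv2 <- classify_signals(mk("lead_eur", "eur"), trans, panels,
                          reported = "reported1")
  expect_true(nv2$novel)
})

test_that("a lead absent from the other population's panel counts as unshared", {
  snps_eur <- c("only_eur", "other")
  panels <- list(eur = identity_panel(snps_eur, population = "eur"),
                 eas = identity_panel("other", population = "eas"))
  thr <- fm_thresholds()
  trans <- transmapr:::new_fm_signals(
    tibble::tibble(rank = 1L, snp = "other", chr = "1", pos = 1e6,
                   beta = 0.1, se = 0.01, z = 10, p = 1e-23, neglog10p = 23,
                   mode = "trans"), "trans", thr)
  eur_sig <- transmapr:::new_fm_signals(
    tibble::tibble(rank = 1L, snp = "only_eur", chr = "1", pos = 1.2e6,
                   beta = 0.1, se = 0.01, z = 10, p = 1e-23, neglog10p = 23,
                   mode = "eur"), "eur", thr)
  out <- classify_signals(eur_sig, trans, panels)
  expect_identical(out$scope, "eur_specific")
})

test_that("CCV sets apply the two-orders-of-magnitude rule on a single-signal region", {
  st <- stats_with_p(c(1e-9, 5e-8, 2e-7))
  panel <- identity_panel(st$snp)
  stats <- list(eur = st, eas = st)
  panels <- list(eur = panel, eas = identity_panel(st$snp,
                                                   population = "eas"))
  thr <- fm_thresholds(p_enter = 1e-8)   # only the 1e-9 lead qualifies
  sg <- stepwise_search(stats, panels, "eur", thr)
  expect_identical(nrow(sg), 1L)
  expect_identical(sg$snp, "v01")
  cc <- ccv_set(sg, 1L, stats, panels, thr)
  # threshold = 100 x 1e-9: the 5e-8 variant is in, the 2e-7 one is out
  expect_setequal(cc$snp, c("v01", "v02"))
  expect_true(cc$is_lead[cc$snp == "v01"])
  # every member respects the inclusion invariant
  expect_true(all(cc$neglog10p >= attr(cc, "neglog10p_threshold")))
})

test_that("trans-ancestry CCV conditioning meta-analyses per-population conditionals", {
  cfg <- two_pop_config(n = 6000, n_variants = 25,
                        causal = data.frame(variant = 12L, eur = 0.25,
                                            eas = 0.25),
                        seed = 97L)
  d <- two_pop_data(cfg)
  reg <- finemap_region(d$stats, d$panels, region_id = "r1")
  expect_gte(nrow(reg$signals), 1L)
  cc <- reg$ccvs[[1]]
  expect_s3_class(cc, "fm_ccv")
  expect_true(attr(cc, "lead") %in% cc$snp)
  # single-signal region: conditioning set empty, so the lead's CCV stats
  # equal the trans meta-analysis of the marginal statistics
  lead <- attr(cc, "lead")
  marg <- ivw_meta(data.frame(
    beta = c(d$stats$eur$beta[d$stats$eur$snp == lead],
             d$stats$eas$beta[d$stats$eas$snp == lead]),
    se = c(d$stats$eur$se[d$stats$eur$snp == lead],
           d$stats$eas$se[d$stats$eas$snp == lead])))
  expect_equal(cc$beta[cc$snp == lead], marg$beta, tolerance = 1e-10)
})
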