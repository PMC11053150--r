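#' Threshold set for fine-mapping
#'
#' All thresholds default to the values used throughout the analysis:
#' conditional p to accept an independent signal `1e-6`; marginal inclusion
#' p `0.05` in both populations for the trans-ancestry search and `1e-4`
#' for ancestry-specific searches; MAF `0.01`; LD `r^2 > 0.1` for
#' shared-signal and previously-reported classification; CCV inclusion
#' within a factor `100` (two orders of magnitude) of the lead conditional
#' p; collinearity mask at panel `r^2 > 0.9`.
#'
#' @param p_enter Conditional p-value to accept a signal.
#' @param trans_inclusion_p Marginal inclusion p (both populations, trans).
#' @param ancestry_inclusion_p Marginal inclusion p (single-population).
#' @param maf Minor-allele-frequency floor.
#' @param sharing_r2 LD r^2 above which leads are considered the same signal.
#' @param ccv_factor Conditional-p ratio defining CCV membership.
#' @param collinearity,ridge Passed to [conditional_analysis()].
#' @param max_signals Cap on signals per region per mode.
#' @param stabilize_max_iter Cap on index-stabilisation sweeps.
#' @return A named list of thresholds.
#' @export
fm_thresholds <- function(p_enter = 1e-6,
                          trans_inclusion_p = 0.05,
                          ancestry_inclusion_p = 1e-4,
                          maf = 0.01,
                          sharing_r2 = 0.1,
                          ccv_factor = 100,
                          collinearity = 0.9,
                          ridge = 1e-8,
                          max_signals = 10L,
                          stabilize_max_iter = 20L) {
  if (p_enter <= 0 || p_enter >= 1) abort("`p_enter` must lie in (0, 1).")
  if (maf <= 0 || maf >= 0.5) abort("`maf` must lie in (0, 0.5).")
  if (ccv_factor < 1) abort("`ccv_factor` must be >= 1.")
  list(p_enter = p_enter, trans_inclusion_p = trans_inclusion_p,
       ancestry_inclusion_p = ancestry_inclusion_p, maf = maf,
       sharing_r2 = sharing_r2, ccv_factor = ccv_factor,
       collinearity = collinearity, ridge = ridge,
       max_signals = as.integer(max_signals),
       stabilize_max_iter = as.integer(stabilize_max_iter))
}

mode_pops <- function(mode) {
  switch(mode, trans = c("eur", "eas"), eur = "eur", eas = "eas",
         abort(sprintf("Unknown mode '%s'", mode)))
}

# Variant ids eligible for discovery (and for CCV membership) under a mode.
eligible_variants <- function(stats, panels, mode, thresholds) {
  pops <- mode_pops(mode)
  p_incl <- if (mode == "trans") thresholds$trans_inclusion_p
            else thresholds$ancestry_inclusion_p
  per_pop <- lapply(pops, function(pop) {
    s <- stats[[pop]]
    maf <- pmin(s$af, 1 - s$af)
    s$snp[maf > thresholds$maf &
            s$neglog10p >= -log10(p_incl) &
            s$snp %in% panels[[pop]]$variant_ids]
  })
  Reduce(intersect, per_pop)
}

# Conditional statistics for `targets` given conditioning indices, under a
# mode: single-population conditioning, or per-population conditioning
# followed by fixed-effects IVW meta-analysis for the trans mode.
conditional_by_mode <- function(stats, panels, mode, conditioning,
                                universe, thresholds) {
  pops <- mode_pops(mode)
  per_pop <- lapply(pops, function(pop) {
    s <- stats[[pop]] |> filter(.data$snp %in% c(universe, conditioning))
    conditional_analysis(s, panels[[pop]], conditioning,
                         collinearity = thresholds$collinearity,
                         ridge = thresholds$ridge) |>
      select("snp", "pos", "beta_c", "se_c", "estimable")
  })
  names(per_pop) <- pops
  if (length(pops) == 1L) {
    out <- per_pop[[1]] |>
      rename(beta = "beta_c", se = "se_c") |>
      mutate(z = .data$beta / .data$se,
             p = z_to_p(.data$z),
             neglog10p = z_to_neglog10p(.data$z))
    return(out |> filter(.data$snp %in% universe))
  }
  shared <- Reduce(intersect, lapply(per_pop, function(x) x$snp))
  aligned <- lapply(per_pop, function(x) x[match(shared, x$snp), ])
  beta_mat <- matrix(unlist(lapply(aligned, function(x) x$beta_c)),
                     nrow = length(shared))
  se_mat <- matrix(unlist(lapply(aligned, function(x) x$se_c)),
                   nrow = length(shared))
  ok <- Reduce(`&`, lapply(aligned, function(x) x$estimable))
  meta <- ivw_meta_matrix(beta_mat, se_mat)
  tibble(snp = shared, pos = aligned[[1]]$pos,
         beta = meta$beta, se = meta$se, z = meta$z,
         p = meta$p, neglog10p = meta$neglog10p,
         estimable = ok & is.finite(meta$z)) |>
    mutate(across(c("beta", "se", "z", "p", "neglog10p"),
                  ~ if_else(.data$estimable, .x, NA_real_))) |>
    filter(.data$snp %in% universe)
}

#' Forward stepwise search for independent association signals
#'
#' Starting from the most significant eligible association (the
#' trans-ancestry meta-analysis for `mode = "trans"`, the ancestry-specific
#' statistics otherwise), repeatedly conditions every remaining eligible
#' variant on the current index set and accepts the variant with the
#' smallest conditional p-value while it stays below `p_enter`. Ties are
#' broken by larger |z|, then smaller position. Eligibility: MAF > 0.01 and
#' marginal p < 0.05 in *both* populations (trans) or marginal p < 1e-4 in
#' the analysed population (ancestry-specific).
#'
#' @param stats Named list of per-population summary-statistic tibbles
#'   (`eur`, `eas`), as from [compute_summary_stats()] / [read_sumstats()].
#' @param panels Named list of per-population [ld_panel()]s.
#' @param mode `"trans"`, `"eur"` or `"eas"`.
#' @param thresholds A [fm_thresholds()] list.
#' @return A `fm_signals` tibble: one row per accepted signal with `rank`,
#'   `snp`, `chr`, `pos`, conditional acceptance statistics (`beta`, `se`,
#'   `z`, `p`, `neglog10p`) and `mode`. Zero rows when no variant
#'   qualifies.
#' @export
stepwise_search <- function(stats, panels, mode = c("trans", "eur", "eas"),
                            thresholds = fm_thresholds()) {
  mode <- match.arg(mode)
  universe <- eligible_variants(stats, panels, mode, thresholds)
  empty <- tibble(rank = integer(), snp = character(), chr = character(),
                  pos = numeric(), beta = numeric(), se = numeric(),
                  z = numeric(), p = numeric(), neglog10p = numeric(),
                  mode = character())
  meta_pos <- stats[[mode_pops(mode)[1]]] |> select("snp", "chr", "pos")
  if (length(universe) == 0L) return(new_fm_signals(empty, mode, thresholds))

  indices <- character()
  rows <- list()
  enter <- -log10(thresholds$p_enter)
  repeat {
    cond <- conditional_by_mode(stats, panels, mode, indices,
                                setdiff(universe, indices), thresholds) |>
      filter(is.finite(.data$neglog10p))
    if (nrow(cond) == 0L) break
    top <- pick_top(cond)
    if (top$neglog10p < enter) break
    indices <- c(indices, top$snp)
    rows[[length(rows) + 1L]] <- top |>
      select("snp", "beta", "se", "z", "p", "neglog10p")
    if (length(indices) >= thresholds$max_signals) break
  }
  if (length(rows) == 0L) return(new_fm_signals(empty, mode, thresholds))
  out <- bind_rows(rows) |>
    mutate(rank = row_number(), mode = mode) |>
    left_join(meta_pos, by = "snp") |>
    select("rank", "snp", "chr", "pos", "beta", "se", "z", "p",
           "neglog10p", "mode")
  new_fm_signals(out, mode, thresholds)
}

new_fm_signals <- function(df, mode, thresholds, converged = TRUE) {
  structure(df, class = c("fm_signals", class(df)),
            mode = mode, thresholds = thresholds, converged = converged)
}

#' Stabilise signal indices by round-robin conditional reselection
#'
#' For each signal in turn, conditions all eligible variants on the other
#' signals' indices and reselects the variant with the strongest residual
#' association as that signal's index. Sweeps repeat until no index changes
#' or `stabilize_max_iter` sweeps have run (in which case the result is
#' returned flagged non-converged). Single-signal sets pass through
#' unchanged.
#'
#' @param signals A `fm_signals` tibble from [stepwise_search()].
#' @inheritParams stepwise_search
#' @return The stabilised `fm_signals` (attribute `converged` records
#'   convergence; each signal's statistics are its final conditional
#'   statistics given all other indices).
#' @export
stabilize_indices <- function(signals, stats, panels,
                              thresholds = attr(signals, "thresholds")) {
  mode <- attr(signals, "mode")
  if (nrow(signals) <= 1L) return(signals)
  universe <- eligible_variants(stats, panels, mode, thresholds)
  indices <- signals$snp
  converged <- FALSE
  for (iter in seq_len(thresholds$stabilize_max_iter)) {
    changed <- FALSE
    for (i in seq_along(indices)) {
      others <- indices[-i]
      cond <- conditional_by_mode(stats, panels, mode, others,
                                  setdiff(universe, others), thresholds) |>
        filter(is.finite(.data$neglog10p))
      if (nrow(cond) == 0L) next
      top <- pick_top(cond)
      if (top$snp != indices[i]) {
        indices[i] <- top$snp
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("Index stabilisation did not converge in %d sweeps.",
                 thresholds$stabilize_max_iter))
  }
  # final conditional statistics for each index given the others
  meta_pos <- stats[[mode_pops(mode)[1]]] |> select("snp", "chr", "pos")
  rows <- purrr::map(seq_along(indices), function(i) {
    cond <- conditional_by_mode(stats, panels, mode, indices[-i],
                                indices[i], thresholds)
    cond |> select("snp", "beta", "se", "z", "p", "neglog10p")
  })
  out <- bind_rows(rows) |>
    mutate(rank = row_number(), mode = mode) |>
    left_join(meta_pos, by = "snp") |>
    select("rank", "snp", "chr", "pos", "beta", "se", "z", "p",
           "neglog10p", "mode")
  new_fm_signals(out, mode, thresholds, converged = converged)
}

#' Classify ancestry-specific signals against trans-ancestry signals
#'
#' A signal found in an ancestry-specific analysis is *shared* with the
#' trans-ancestry analysis when its lead is the same variant as, or
#' correlated at LD `r^2 > 0.1` (in the corresponding population's panel)
#' with, a trans-ancestry lead; otherwise it is ancestry-specific. Each
#' signal is also flagged novel when its lead has `r^2 <= 0.1` with every
#' previously reported variant in *either* population's panel (maximum
#' over panels; variants absent from a panel contribute `r^2 = 0`).
#'
#' @param signals A `fm_signals` tibble (any mode).
#' @param trans_signals The region's trans-ancestry `fm_signals`.
#' @param panels Named list of per-population [ld_panel()]s.
#' @param reported Character vector of previously reported variant ids
#'   (optional).
#' @param thresholds A [fm_thresholds()] list.
#' @return `signals` with added columns `shared_with_trans` (logical;
#'   `TRUE` for trans-mode input itself), `scope` (`"trans"`,
#'   `"eur_specific"`, `"eas_specific"`) and `novel`.
#' @export
classify_signals <- function(signals, trans_signals, panels,
                             reported = character(),
                             thresholds = attr(signals, "thresholds") %||%
                               fm_thresholds()) {
  mode <- attr(signals, "mode")
  r2_to_any <- function(snp, others, pops) {
    if (length(others) == 0L) return(0)
    max(vapply(others, function(o) {
      max(vapply(pops, function(pop) panel_r2(panels[[pop]], snp, o),
                 numeric(1)))
    }, numeric(1)))
  }
  if (mode == "trans") {
    shared <- rep(TRUE, nrow(signals))
    scope <- rep("trans", nrow(signals))
  } else {
    shared <- vapply(signals$snp, function(s) {
      s %in% trans_signals$snp ||
        r2_to_any(s, trans_signals$snp, mode) > thresholds$sharing_r2
    }, logical(1))
    scope <- if_else(shared, "trans", paste0(mode, "_specific"))
  }
  novel <- vapply(signals$snp, function(s) {
    r2_to_any(s, reported, c("eur", "eas")) <= thresholds$sharing_r2
  }, logical(1))
  signals$shared_with_trans <- unname(shared)
  signals$scope <- unname(scope)
  signals$novel <- unname(novel)
  signals
}

#' Credible causal variant (CCV) set for one signal
#'
#' Conditions every eligible region variant on the indices of all *other*
#' independent signals (per population then IVW-meta-analysed for
#' trans-ancestry signals; marginal/meta statistics when the signal is the
#' region's only one) and keeps the variants whose conditional p-value lies
#' within two orders of magnitude (`ccv_factor`) of the lead's.
#'
#' @param signals The region's stabilised `fm_signals`.
#' @param which_signal Row index or snp id of the signal whose CCVs to build.
#' @inheritParams stepwise_search
#' @return A `fm_ccv` tibble: `snp`, `pos`, conditional `beta`, `se`, `z`,
#'   `p`, `neglog10p`, `is_lead`; attributes `lead`, `mode` and
#'   `neglog10p_threshold`.
#' @export
ccv_set <- function(signals, which_signal, stats, panels,
                    thresholds = attr(signals, "thresholds")) {
  mode <- attr(signals, "mode")
  i <- if (is.character(which_signal)) match(which_signal, signals$snp)
       else which_signal
  if (is.na(i) || i < 1L || i > nrow(signals)) {
    abort("`which_signal` does not identify a signal.")
  }
  lead <- signals$snp[i]
  others <- signals$snp[-i]
  universe <- eligible_variants(stats, panels, mode, thresholds)
  cond <- conditional_by_mode(stats, panels, mode, others,
                              setdiff(universe, others), thresholds)
  lead_row <- cond |> filter(.data$snp == lead)
  if (nrow(lead_row) == 0L || !is.finite(lead_row$neglog10p)) {
    abort(sprintf("Conditional statistics unavailable for lead %s", lead))
  }
  thr <- lead_row$neglog10p - log10(thresholds$ccv_factor)
  members <- cond |>
    filter(is.finite(.data$neglog10p), .data$neglog10p >= thr) |>
    mutate(is_lead = .data$snp == lead) |>
    arrange(dplyr::desc(.data$neglog10p)) |>
    select("snp", "pos", "beta", "se", "z", "p", "neglog10p", "is_lead")
  structure(members, class = c("fm_ccv", class(members)),
            lead = lead, mode = mode, neglog10p_threshold = thr)
}
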