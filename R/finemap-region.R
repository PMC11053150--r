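#' Fine-map one region across trans-ancestry and ancestry-specific modes
#'
#' Runs the forward stepwise search in trans-ancestry, European-only and
#' East-Asian-only modes, stabilises indices within each mode, classifies
#' ancestry-specific signals against the trans-ancestry ones (LD `r^2 >
#' 0.1` sharing rule), and assembles the union of independent signals:
#' every trans-ancestry signal plus the ancestry-specific signals not
#' shared with a trans lead. A CCV set is built for each retained signal
#' within its discovery mode.
#'
#' @inheritParams stepwise_search
#' @param region_id Label attached to the output.
#' @param reported Previously reported variant ids for novelty flagging.
#' @param modes Modes to run (default all three).
#' @return A list of class `fm_region`: `signals` (tibble with `signal_id`,
#'   lead info, conditional statistics, `scope`, `novel`, `n_ccv`), `ccvs`
#'   (named list of `fm_ccv` keyed by `signal_id`) and `per_mode` (the raw
#'   per-mode `fm_signals`).
#' @export
finemap_region <- function(stats, panels, thresholds = fm_thresholds(),
                           region_id = "region_1", reported = character(),
                           modes = c("trans", "eur", "eas")) {
  per_mode <- lapply(modes, function(mode) {
    found <- stepwise_search(stats, panels, mode, thresholds)
    stabilize_indices(found, stats, panels, thresholds)
  })
  names(per_mode) <- modes
  trans <- per_mode[["trans"]] %||%
    new_fm_signals(tibble(snp = character()), "trans", thresholds)

  classified <- lapply(per_mode, classify_signals, trans_signals = trans,
                       panels = panels, reported = reported,
                       thresholds = thresholds)

  keep <- bind_rows(lapply(classified, function(s) {
    if (nrow(s) == 0L) return(NULL)
    s |> filter(attr(s, "mode") == "trans" | !.data$shared_with_trans)
  }))
  if (nrow(keep) == 0L) {
    out <- list(signals = keep, ccvs = list(), per_mode = classified,
                region_id = region_id)
    class(out) <- "fm_region"
    return(out)
  }
  keep <- keep |>
    mutate(region_id = region_id,
           signal_id = sprintf("%s_s%d", region_id, row_number()))

  ccvs <- purrr::map(seq_len(nrow(keep)), function(i) {
    mode <- keep$mode[i]
    ccv_set(classified[[mode]], keep$snp[i], stats, panels, thresholds)
  })
  names(ccvs) <- keep$signal_id
  keep$n_ccv <- vapply(ccvs, nrow, integer(1))

  out <- list(signals = keep |> relocate("region_id", "signal_id"),
              ccvs = ccvs, per_mode = classified, region_id = region_id)
  class(out) <- "fm_region"
  out
}

#' @export
print.fm_region <- function(x, ...) {
  cat(sprintf("<fm_region> %s: %d independent signal(s)\n",
              x$region_id, nrow(x$signals)))
  if (nrow(x$signals) > 0) {
    print(as_tibble(x$signals |>
                      select("signal_id", "snp", "scope", "neglog10p",
                             "novel", "n_ccv")))
  }
  invisible(x)
}

#' Flatten the CCV sets of a fine-mapped region to one tibble
#'
#' @param region A `fm_region` from [finemap_region()].
#' @return Tibble with one row per (signal, CCV): `signal_id`, `lead`,
#'   `snp`, `pos`, conditional statistics, `is_lead`.
#' @export
ccv_table <- function(region) {
  stopifnot(inherits(region, "fm_region"))
  purrr::imap(region$ccvs, function(cc, id) {
    as_tibble(cc) |> mutate(signal_id = id, lead = attr(cc, "lead"))
  }) |>
    bind_rows() |>
    relocate("signal_id", "lead")
}
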