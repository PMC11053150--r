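#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a set of independent association signals
#'
#' @param x A `fm_signals` object.
#' @param ... Unused.
#' @return A plain tibble, one row per signal.
#' @export
tidy.fm_signals <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.fm_signals
#' @export
glance.fm_signals <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_signals = nrow(x),
    converged = isTRUE(attr(x, "converged")),
    min_p = if (nrow(x)) min(x$p) else NA_real_,
    p_enter = attr(x, "thresholds")$p_enter
  )
}

#' Tidy a fine-mapped region
#'
#' @param x A `fm_region` object.
#' @param ... Unused.
#' @return Signals tibble (`tidy`); one-row region summary (`glance`).
#' @export
tidy.fm_region <- function(x, ...) {
  as_tibble(x$signals)
}

#' @rdname tidy.fm_region
#' @export
glance.fm_region <- function(x, ...) {
  tibble(
    region_id = x$region_id,
    n_signals = nrow(x$signals),
    n_ccv_total = sum(vapply(x$ccvs, nrow, integer(1))),
    n_novel = if (nrow(x$signals)) sum(x$signals$novel) else 0L
  )
}

#' Tidy a CCV set
#'
#' @param x A `fm_ccv` object.
#' @param ... Unused.
#' @return Member tibble (`tidy`); one-row set summary (`glance`).
#' @export
tidy.fm_ccv <- function(x, ...) {
  as_tibble(x) |> mutate(lead = attr(x, "lead"))
}

#' @rdname tidy.fm_ccv
#' @export
glance.fm_ccv <- function(x, ...) {
  tibble(
    lead = attr(x, "lead"),
    mode = attr(x, "mode"),
    n_ccv = nrow(x),
    neglog10p_threshold = attr(x, "neglog10p_threshold")
  )
}

#' Tidy SMR colocalization results
#'
#' @param x A `fm_smr` object.
#' @param ... Unused.
#' @return Result tibble (`tidy`); per-scan summary (`glance`).
#' @export
tidy.fm_smr <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.fm_smr
#' @export
glance.fm_smr <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_signals = dplyr::n_distinct(x$signal_id),
    n_significant = sum(x$significant)
  )
}
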