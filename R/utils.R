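#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join row_number n across all_of distinct rename
#'   relocate if_else pull slice count
#' @importFrom stats pnorm qnorm pchisq pt cor lm rnorm runif rbinom quantile
#'   median rpois coef prcomp glm binomial setNames complete.cases var sd
#' @importFrom utils head modifyList
NULL

LOG10 <- log(10)

#' Two-sided -log10 p-value from a z statistic
#'
#' Computed in log space so that extreme statistics (|z| > 40, where the
#' two-sided p underflows double precision) remain finite and comparable.
#'
#' @param z Numeric vector of z statistics.
#' @return Numeric vector of -log10 two-sided normal p-values.
#' @export
z_to_neglog10p <- function(z) {
  -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / LOG10
}

#' Two-sided p-value from a z statistic
#'
#' @param z Numeric vector of z statistics.
#' @return Two-sided normal p-values (underflows to 0 below ~1e-320; use
#'   [z_to_neglog10p()] when ranking extreme signals).
#' @export
z_to_p <- function(z) {
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Signed z score from a two-sided p-value
#'
#' Uses the convention `qnorm(p/2) * sign(beta)`: the magnitude is the
#' two-sided normal quantile, and the sign is *opposite* to the effect
#' direction (`qnorm(p/2)` is negative). This is the convention used by the
#' sample-size-weighted QTL meta-analysis; it cancels in any two-sided test.
#' Set `convention = "standard"` to obtain a z whose sign matches the beta.
#'
#' @param p Two-sided p-values in (0, 1]. Zeros are clamped to the smallest
#'   representable positive double with a warning.
#' @param direction Sign carrier (typically the beta); only its sign is used.
#' @param convention `"qnorm"` (default, `qnorm(p/2)*sign(direction)`) or
#'   `"standard"` (sign agrees with `direction`).
#' @return Signed z scores.
#' @export
p_to_z <- function(p, direction, convention = c("qnorm", "standard")) {
  convention <- match.arg(convention)
  stopifnot(length(p) == length(direction) || length(direction) == 1L)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  if (any(p == 0, na.rm = TRUE)) {
    warn("p-values of 0 clamped to .Machine$double.xmin before conversion.")
    p[p == 0] <- .Machine$double.xmin
  }
  z <- qnorm(p / 2) * sign(direction)
  if (convention == "standard") z <- -z
  z
}

# deterministic ordering used whenever a "most significant variant" is picked:
# largest -log10 p, then largest |z|, then smallest position.
pick_top <- function(df) {
  df |>
    arrange(dplyr::desc(.data$neglog10p), dplyr::desc(abs(.data$z)), .data$pos) |>
    slice(1L)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
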