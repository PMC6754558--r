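#' @importFrom stats median quantile rbinom rnbinom rnorm rpois runif
#'   binom.test chisq.test p.adjust wilcox.test setNames ave
#' @importFrom utils head tail
NULL

#' @importFrom data.table .N
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Keeps derived seeds strictly below 2^31 so they remain valid R
#' integer seeds on all platforms.
#' @noRd
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offset) %% 2147483647L
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

assertColumns <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("'%s' is missing column(s): %s", name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Percentage from a count and a total
#'
#' Convenience used in reports: `100 * count / total`.
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @return Numeric percentage (not rounded).
#' @examples
#' asPercent(96, 363)
#' @export
asPercent <- function(count, total) {
  assertScalarNumber(count, "count", lower = 0)
  assertScalarNumber(total, "total", lower = 1e-12)
  100 * count / total
}
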