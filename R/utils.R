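#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median quantile sd cor rnorm runif rpois rlnorm predict setNames
#' @importFrom utils head modifyList
NULL

# Mean Earth radius in km used by every great-circle computation.
EARTH_RADIUS_KM <- 6371

`%theninform%` <- function(cond, msg) {
  if (cond) inform(msg)
  invisible(cond)
}

stop_shipflow <- function(msg, class = "shipflow_error") {
  abort(msg, class = class)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_shipflow(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic child seeds: one global seed fans out to per-stage streams by
# fixed offsets so stages can be rerun in isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}
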