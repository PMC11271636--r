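#' Allocate a source's outflow across destination regions
#'
#' Turns model scores into flows: \eqn{\hat y_j = O_i \,
#' \mathrm{softmax}(f)_j}, so the predicted flows always sum exactly to the
#' observed total departures \eqn{O_i} (flow conservation).
#'
#' @param scores Numeric vector of model scores, one per destination region.
#' @param O_i Positive total number of departures from the source.
#' @return Non-negative vector summing to `O_i`.
#' @export
allocate_flows <- function(scores, O_i) {
  if (!is.finite(O_i) || O_i <= 0) stop_shipflow("O_i must be positive")
  O_i * softmax(scores)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

log_softmax <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

#' Multinomial cross-entropy flow loss
#'
#' \eqn{L = -\sum_j y_j \log \mathrm{softmax}(f)_j}, computed through the
#' numerically stable log-softmax. Observed flows act as soft counts.
#'
#' @param scores Model scores (length N).
#' @param y Observed non-negative flows (length N, positive total).
#' @return Non-negative scalar loss.
#' @export
flow_loss <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  if (any(y < 0) || sum(y) <= 0) {
    stop_shipflow("y must be non-negative with positive total")
  }
  -sum(y * log_softmax(scores))
}

#' Common Part of Commuters
#'
#' Overlap between predicted and observed flow vectors for one source:
#' \eqn{CPC = 2\sum_j \min(\hat y_j, y_j) / (\sum_j \hat y_j + \sum_j y_j)},
#' in \[0, 1\] with 1 meaning identical flows. The aggregate over many
#' sources is the mean of the per-source values.
#'
#' @param y_hat,y Equal-length non-negative flow vectors.
#' @return Scalar in \[0, 1\].
#' @export
cpc <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y))
  if (any(y_hat < 0) || any(y < 0)) stop_shipflow("flows must be non-negative")
  tot <- sum(y_hat) + sum(y)
  if (tot == 0) {
    warn("both flow vectors are all-zero; CPC defined as 1")
    return(1)
  }
  2 * sum(pmin(y_hat, y)) / tot
}

#' Normalised root mean square error of flows
#'
#' Pooled over all (source, region) pairs by default:
#' \eqn{\sqrt{\mathrm{mean}((y - \hat y)^2)} / (\max y - \min y)}. The
#' per-source variant computes the ratio within each source and averages.
#'
#' @param y_hat,y Flow vectors (pooled across sources) or, for
#'   `per_source = TRUE`, accompanied by `source` ids.
#' @param per_source Average per-source NRMSE instead of pooling.
#' @param source Source id per entry (required for `per_source = TRUE`).
#' @return Non-negative scalar; `NA` when the observed range is zero.
#' @export
nrmse <- function(y_hat, y, per_source = FALSE, source = NULL) {
  stopifnot(length(y_hat) == length(y))
  one <- function(yh, yy) {
    rng <- diff(range(yy))
    if (rng == 0) return(NA_real_)
    sqrt(mean((yy - yh)^2)) / rng
  }
  if (!per_source) return(one(y_hat, y))
  stopifnot(!is.null(source))
  vals <- purrr::map2_dbl(split(y_hat, source), split(y, source), one)
  mean(vals, na.rm = TRUE)
}

#' Pearson correlation of predicted and observed flows
#'
#' @inheritParams nrmse
#' @return Scalar in \[-1, 1\]; `NA` when either vector has zero variance.
#' @export
flow_corr <- function(y_hat, y, per_source = FALSE, source = NULL) {
  stopifnot(length(y_hat) == length(y))
  one <- function(yh, yy) {
    if (sd(yh) == 0 || sd(yy) == 0) return(NA_real_)
    cor(yh, yy)
  }
  if (!per_source) return(one(y_hat, y))
  stopifnot(!is.null(source))
  vals <- purrr::map2_dbl(split(y_hat, source), split(y, source), one)
  mean(vals, na.rm = TRUE)
}

#' CPC of the uniform allocation baseline
#'
#' Allocates each source's outflow uniformly over its destination regions
#' (\eqn{\hat y_j = O_i / N}) and returns the mean CPC across sources; the
#' reference any learned flow model must beat.
#'
#' @param samples A samples tibble (see [assemble_samples()]).
#' @return Mean CPC over sources.
#' @export
uniform_baseline_cpc <- function(samples) {
  assert_columns(samples, c("source", "O_i", "y"), "samples")
  by_src <- split(samples, samples$source)
  mean(vapply(by_src, function(d) {
    cpc(rep(d$O_i[1] / nrow(d), nrow(d)), d$y)
  }, numeric(1)))
}
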