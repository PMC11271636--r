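#' Environmental distance between two ports
#'
#' Euclidean distance over the 4-component environmental vectors
#' (annual minimum, maximum and mean temperature, annual salinity). Smaller
#' distances mean more similar habitats at the two ends of a voyage and
#' therefore higher ballast-water invasion risk. A z-scored variant
#' (standardising each component across a reference table) is available
#' because temperature and salinity are on different scales.
#'
#' @param env A data frame `port_id`, `t_min`, `t_max`, `t_annual`,
#'   `s_annual` (one row per port), or for the two-vector form, a length-4
#'   numeric vector.
#' @param a,b Port ids (when `env` is a table) or length-4 numeric vectors.
#' @param standardize Z-score the four components across `env` first.
#'   Default FALSE (raw units).
#' @return Non-negative scalar distance.
#' @export
env_distance <- function(a, b, env = NULL, standardize = FALSE) {
  if (is.numeric(a) && is.numeric(b)) {
    stopifnot(length(a) == length(b))
    return(sqrt(sum((a - b)^2)))
  }
  env <- validate_env_table(env)
  if (standardize) env <- standardize_env(env)
  va <- env_vector(env, a)
  vb <- env_vector(env, b)
  sqrt(sum((va - vb)^2))
}

env_cols <- function() c("t_min", "t_max", "t_annual", "s_annual")

validate_env_table <- function(env) {
  assert_columns(env, c("port_id", env_cols()), "env")
  env <- tibble::as_tibble(env)
  bad <- !vapply(env[env_cols()], function(x) all(is.finite(x)), logical(1))
  if (any(bad)) stop_shipflow("environmental values must be finite")
  if (any(env$t_min > env$t_annual | env$t_annual > env$t_max)) {
    stop_shipflow("need t_min <= t_annual <= t_max for every port")
  }
  env
}

standardize_env <- function(env) {
  for (col in env_cols()) {
    s <- sd(env[[col]])
    if (s > 0) env[[col]] <- (env[[col]] - mean(env[[col]])) / s
  }
  env
}

env_vector <- function(env, id) {
  r <- match(id, env$port_id)
  if (is.na(r)) stop_shipflow(sprintf("no environmental vector for port %s", id))
  as.numeric(env[r, env_cols()])
}

#' Trip-weighted environmental-distance distribution
#'
#' For every origin-destination link, computes the environmental distance
#' between its end ports and weights it by the number of trips (observed or
#' predicted) on the link, giving the empirical distribution of shipping
#' activity across invasion-risk levels. The distribution is kept both as
#' raw (distance, weight) pairs and as a fixed-bin histogram.
#'
#' @param flows A data frame `source`, `dest`, `weight` (trips on the link;
#'   a `y_hat` or `count` column is accepted and used as the weight).
#' @param env Environmental table `port_id`, `t_min`, `t_max`, `t_annual`,
#'   `s_annual` covering every port in `flows`.
#' @param bins Number of equal-width histogram bins. Default 50.
#' @param breaks Optional explicit break points (shared grids for
#'   comparisons); overrides `bins`.
#' @param standardize Z-score environmental components first. Default FALSE.
#' @return A `risk_distribution`: list with `pairs` (tibble `source`,
#'   `dest`, `d_env`, `weight`), `histogram` (tibble `bin_low`, `bin_high`,
#'   `bin_mid`, `weight`), `breaks` and `total_weight`.
#' @export
weight_distribution <- function(flows, env, bins = 50, breaks = NULL,
                                standardize = FALSE) {
  flows <- tibble::as_tibble(flows)
  if (!"weight" %in% names(flows)) {
    alt <- intersect(c("y_hat", "count"), names(flows))
    if (length(alt) == 0) {
      stop_shipflow("flows must carry a weight, y_hat or count column")
    }
    flows$weight <- flows[[alt[1]]]
  }
  assert_columns(flows, c("source", "dest", "weight"), "flows")
  env <- validate_env_table(env)
  if (standardize) env <- standardize_env(env)

  used <- unique(c(flows$source, flows$dest))
  missing <- setdiff(used, env$port_id)
  if (length(missing) > 0) {
    stop_shipflow(sprintf("ports missing from the environmental table: %s",
                          paste(head(missing, 10), collapse = ", ")))
  }
  M <- as.matrix(env[match(used, env$port_id), env_cols()])
  rownames(M) <- used
  diff2 <- (M[flows$source, , drop = FALSE] -
              M[flows$dest, , drop = FALSE])^2
  d_env <- unname(sqrt(rowSums(diff2)))

  if (is.null(breaks)) {
    breaks <- seq(0, max(d_env) * (1 + 1e-9), length.out = bins + 1)
    if (max(d_env) == 0) breaks <- seq(0, 1, length.out = bins + 1)
  }
  bin <- cut(d_env, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  if (anyNA(bin)) stop_shipflow("some distances fall outside the bin grid")
  w <- vapply(seq_len(length(breaks) - 1), function(b) {
    sum(flows$weight[bin == b])
  }, numeric(1))

  structure(
    list(
      pairs = tibble::tibble(source = flows$source, dest = flows$dest,
                             d_env = d_env, weight = flows$weight),
      histogram = tibble::tibble(
        bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
        bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2, weight = w
      ),
      breaks = breaks, total_weight = sum(flows$weight)
    ),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf(
    "<risk_distribution> %d links, total weight %.1f, %d bins over [%.2f, %.2f]\n",
    nrow(x$pairs), x$total_weight, nrow(x$histogram), min(x$breaks),
    max(x$breaks)
  ))
  invisible(x)
}

#' Compare predicted and observed risk distributions
#'
#' Pearson correlation of the binned trip weights on a shared bin grid
#' (default), or of per-link distance-weight profiles (`method = "pairs"`:
#' the two distributions' weights matched on identical links). Also reports
#' the total-variation distance between the normalised histograms.
#'
#' @param pred,truth `risk_distribution` objects on identical bin grids.
#' @param method `"binned"` (default) or `"pairs"`.
#' @return A list `correlation`, `total_variation`, `method`.
#' @export
compare_distributions <- function(pred, truth, method = c("binned", "pairs")) {
  method <- match.arg(method)
  stopifnot(inherits(pred, "risk_distribution"),
            inherits(truth, "risk_distribution"))
  if (method == "binned") {
    if (!isTRUE(all.equal(pred$breaks, truth$breaks))) {
      stop_shipflow("distributions must share a bin grid")
    }
    a <- pred$histogram$weight
    b <- truth$histogram$weight
  } else {
    key_a <- paste(pred$pairs$source, pred$pairs$dest)
    key_b <- paste(truth$pairs$source, truth$pairs$dest)
    common <- intersect(key_a, key_b)
    a <- pred$pairs$weight[match(common, key_a)]
    b <- truth$pairs$weight[match(common, key_b)]
  }
  correlation <- if (sd(a) == 0 || sd(b) == 0) {
    warn("zero variance in a weights vector; correlation undefined")
    NA_real_
  } else {
    cor(a, b)
  }
  tv <- if (sum(a) > 0 && sum(b) > 0) {
    sum(abs(a / sum(a) - b / sum(b))) / 2
  } else {
    NA_real_
  }
  list(correlation = correlation, total_variation = tv, method = method)
}
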