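#' Port centrality metrics for the shipping network
#'
#' Computes the node-level graph metrics used as gravity features:
#' \describe{
#'   \item{betweenness}{\eqn{C_B(i) = \sum_{u \ne v} \sigma(u,v|i)/\sigma(u,v)}
#'     over ordered pairs with \eqn{i \notin \{u,v\}}; pairs with no
#'     connecting path contribute 0.}
#'   \item{closeness}{Outgoing-distance closeness restricted to the reachable
#'     set and scaled by the reachable fraction:
#'     \eqn{C_C(i) = (r_i/(|V|-1)) \cdot r_i / \sum_{j} d^N_{ij}} where
#'     \eqn{r_i} counts reachable \eqn{j \ne i}. On a strongly connected graph
#'     this reduces to the classical \eqn{(|V|-1)/\sum_j d^N_{ij}}.}
#'   \item{pagerank}{Stationary vector of the damped, weight-proportional
#'     random walk (power iteration; dangling nodes redistribute uniformly).}
#'   \item{straightness}{\eqn{C_S(i) = \frac{1}{|V|-1}\sum_j d^E_{ij}/d^N_{ij}}
#'     where \eqn{d^E} is the great-circle distance and \eqn{d^N} the shortest
#'     network path length with haversine-km edge costs; unreachable
#'     destinations contribute 0.}
#' }
#'
#' @param net A `shipping_network`.
#' @param weight_mode How edge weights enter shortest paths and the walk:
#'   `"trips"` (default; trip counts are used directly), `"reciprocal"`
#'   (cost = 1/weight, reading counts as proximity) or `"unweighted"`.
#' @return `node_metrics()` returns a tibble with columns `port_id`,
#'   `betweenness`, `closeness`, `pagerank`, `straightness`; the single-metric
#'   functions return two-column tibbles.
#' @export
node_metrics <- function(net, weight_mode = "trips") {
  out <- port_betweenness(net, weight_mode) |>
    dplyr::left_join(port_closeness(net, weight_mode), by = "port_id") |>
    dplyr::left_join(port_pagerank(net, weight_mode = weight_mode),
                     by = "port_id") |>
    dplyr::left_join(port_straightness(net), by = "port_id")
  out
}

#' @rdname node_metrics
#' @export
port_betweenness <- function(net, weight_mode = "trips") {
  stopifnot(inherits(net, "shipping_network"), nrow(net$ports) > 0)
  g <- as_port_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE,
                           weights = edge_costs(net, weight_mode))
  tibble::tibble(port_id = net$ports$port_id,
                 betweenness = unname(b[net$ports$port_id]))
}

#' @rdname node_metrics
#' @export
port_closeness <- function(net, weight_mode = "trips") {
  stopifnot(inherits(net, "shipping_network"), nrow(net$ports) > 0)
  n <- nrow(net$ports)
  if (n == 1) {
    return(tibble::tibble(port_id = net$ports$port_id, closeness = 0))
  }
  D <- distance_matrix(net, weight_mode)
  diag(D) <- Inf # exclude self
  cl <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[reach]))
  }, numeric(1))
  tibble::tibble(port_id = net$ports$port_id, closeness = cl)
}

#' @rdname node_metrics
#' @param damping PageRank damping factor, default 0.85.
#' @param tol Convergence tolerance on the L1 change of the stationary
#'   vector, default 1e-9.
#' @param max_iter Maximum power-iteration sweeps, default 200.
#' @export
port_pagerank <- function(net, damping = 0.85, tol = 1e-9, max_iter = 200,
                          weight_mode = "trips") {
  stopifnot(inherits(net, "shipping_network"), nrow(net$ports) > 0)
  ids <- net$ports$port_id
  n <- length(ids)
  if (n == 1) return(tibble::tibble(port_id = ids, pagerank = 1))

  w <- switch(match.arg(weight_mode, c("trips", "reciprocal", "unweighted")),
    trips = net$edges$weight,
    reciprocal = 1 / net$edges$weight,
    unweighted = rep(1, nrow(net$edges))
  )
  i <- match(net$edges$source, ids)
  j <- match(net$edges$dest, ids)
  out_strength <- as.numeric(tapply(w, factor(i, levels = seq_len(n)), sum))
  out_strength[is.na(out_strength)] <- 0

  pi_v <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    # weight-proportional transition; dangling mass spread uniformly
    contrib <- ifelse(out_strength[i] > 0, pi_v[i] * w / out_strength[i], 0)
    new_pi <- as.numeric(tapply(contrib, factor(j, levels = seq_len(n)), sum))
    new_pi[is.na(new_pi)] <- 0
    dangling <- sum(pi_v[out_strength == 0])
    new_pi <- new_pi + dangling / n
    new_pi <- (1 - damping) / n + damping * new_pi
    delta <- sum(abs(new_pi - pi_v))
    pi_v <- new_pi
    if (delta < tol) {
      pi_v <- pi_v / sum(pi_v)
      return(tibble::tibble(port_id = ids, pagerank = pi_v))
    }
  }
  stop_shipflow(sprintf(
    "PageRank did not converge to %.1e within %d iterations", tol, max_iter
  ))
}

#' @rdname node_metrics
#' @export
port_straightness <- function(net) {
  stopifnot(inherits(net, "shipping_network"), nrow(net$ports) > 0)
  n <- nrow(net$ports)
  if (n == 1) {
    return(tibble::tibble(port_id = net$ports$port_id, straightness = 0))
  }
  g <- as_port_igraph(net)
  DN <- igraph::distances(g, mode = "out", weights = edge_lengths_km(net))
  DN <- DN[net$ports$port_id, net$ports$port_id, drop = FALSE]
  DE <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(net$ports$lat[i], net$ports$lon[i],
                 net$ports$lat[j], net$ports$lon[j])
  })
  ratio <- DE / DN
  # zero-distance co-located pairs count as perfectly straight when connected
  ratio[DE == 0 & is.finite(DN)] <- 1
  ratio[!is.finite(DN) | DN == 0 & DE > 0] <- 0
  diag(ratio) <- 0
  tibble::tibble(
    port_id = net$ports$port_id,
    straightness = unname(rowSums(ratio)) / (n - 1)
  )
}

# All-pairs shortest-path distance matrix in registry order.
distance_matrix <- function(net, weight_mode = "trips") {
  g <- as_port_igraph(net)
  D <- igraph::distances(g, mode = "out",
                         weights = edge_costs(net, weight_mode))
  D[net$ports$port_id, net$ports$port_id, drop = FALSE]
}
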