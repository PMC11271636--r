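# Independent brute-force oracles for the graph metrics: Floyd-Warshall
# distances plus exhaustive (pruned) DFS path enumeration. Deliberately
# written without igraph so they can referee the package's computations.

# random seeded digraph as a shipping_network, integer weights 1..10
rand_net <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    reg <- tibble::tibble(
      port_id = sprintf("n%d", seq_len(n)),
      lat = runif(n, -60, 60), lon = runif(n, -179, 180),
      country = "XX"
    )
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i != pairs$j & runif(nrow(pairs)) < p, ]
    if (nrow(pairs) == 0) pairs <- data.frame(i = 1, j = 2)
    trips <- tibble::tibble(
      source = reg$port_id[pairs$i], dest = reg$port_id[pairs$j],
      count = sample(1:10, nrow(pairs), replace = TRUE)
    )
  })
  build_network(trips, reg)
}

# n x n cost matrix under a weight mode (Inf where no edge)
cost_matrix <- function(net, weight_mode = "trips") {
  ids <- net$ports$port_id
  n <- length(ids)
  C <- matrix(Inf, n, n, dimnames = list(ids, ids))
  w <- switch(weight_mode,
    trips = net$edges$weight,
    reciprocal = 1 / net$edges$weight,
    unweighted = rep(1, nrow(net$edges)),
    km = shipflow:::edge_lengths_km(net)
  )
  C[cbind(match(net$edges$source, ids), match(net$edges$dest, ids))] <- w
  C
}

fw_dist <- function(C) {
  n <- nrow(C)
  D <- C
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      alt <- D[i, k] + D[k, ]
      better <- alt < D[i, ]
      D[i, better] <- alt[better]
    }
  }
  D
}

# counts of shortest u->v paths and of those passing through each vertex,
# by DFS with branch-and-bound pruning on the FW distances
count_paths <- function(C, D, u, v, tol = 1e-9) {
  n <- nrow(C)
  sigma <- 0
  through <- numeric(n)
  target <- D[u, v]
  if (!is.finite(target)) return(list(sigma = 0, through = through))
  dfs <- function(cur, cost, visited) {
    if (cur == v) {
      sigma <<- sigma + 1
      mid <- setdiff(visited, c(u, v))
      through[mid] <<- through[mid] + 1
      return(invisible())
    }
    for (nxt in which(is.finite(C[cur, ]))) {
      if (nxt %in% visited) next
      nc <- cost + C[cur, nxt]
      if (nc + D[nxt, v] > target + tol) next
      dfs(nxt, nc, c(visited, nxt))
    }
  }
  dfs(u, 0, u)
  list(sigma = sigma, through = through)
}

oracle_betweenness <- function(net, weight_mode = "trips") {
  C <- cost_matrix(net, weight_mode)
  D <- fw_dist(C)
  n <- nrow(C)
  bet <- numeric(n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v || !is.finite(D[u, v])) next
      cp <- count_paths(C, D, u, v)
      if (cp$sigma > 0) bet <- bet + cp$through / cp$sigma
    }
  }
  setNames(bet, net$ports$port_id)
}

oracle_closeness <- function(net, weight_mode = "trips") {
  D <- fw_dist(cost_matrix(net, weight_mode))
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }, numeric(1)) |> setNames(net$ports$port_id)
}

oracle_straightness <- function(net) {
  D <- fw_dist(cost_matrix(net, "km"))
  n <- nrow(D)
  E <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(net$ports$lat[i], net$ports$lon[i],
                 net$ports$lat[j], net$ports$lon[j])
  })
  vapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) {
      if (i == j || !is.finite(D[i, j])) next
      tot <- tot + if (E[i, j] == 0) 1 else E[i, j] / D[i, j]
    }
    tot / (n - 1)
  }, numeric(1)) |> setNames(net$ports$port_id)
}

oracle_pagerank <- function(net, damping = 0.85, weight_mode = "trips") {
  ids <- net$ports$port_id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  w <- switch(weight_mode,
    trips = net$edges$weight,
    reciprocal = 1 / net$edges$weight,
    unweighted = rep(1, nrow(net$edges))
  )
  W[cbind(match(net$edges$source, ids), match(net$edges$dest, ids))] <- w
  P <- matrix(1 / n, n, n)
  rs <- rowSums(W)
  P[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  M <- (1 - damping) / n + damping * P
  v <- rep(1 / n, n)
  for (it in 1:10000) {
    nv <- as.numeric(v %*% M)
    if (sum(abs(nv - v)) < 1e-13) break
    v <- nv
  }
  setNames(v / sum(v), ids)
}

oracle_components <- function(net) {
  ids <- net$ports$port_id
  n <- length(ids)
  A <- matrix(FALSE, n, n)
  A[cbind(match(net$edges$source, ids), match(net$edges$dest, ids))] <- TRUE
  closure <- function(B) {
    R <- B | diag(TRUE, n)
    repeat {
      R2 <- R | (R %*% R > 0)
      if (identical(R2, R)) return(R)
      R <- R2
    }
  }
  # classes of the mutual-reachability relation = distinct indicator rows
  strong <- closure(A) & t(closure(A))
  weak <- closure(A | t(A))
  list(n_strong = nrow(unique(strong)), n_weak = nrow(unique(weak)))
}

# numeric-vs-analytic gradient comparison over a random subset of parameters
grad_check_max_err <- function(model, X, y, n_per_param = 4, eps = 1e-5) {
  fw <- shipflow:::model_forward(model, X, train = FALSE)
  lg <- shipflow:::loss_and_grad_scores(fw$scores, y)
  grads <- shipflow:::model_backward(model, fw$cache, lg$dscores)
  flatp <- shipflow:::flatten_params(model$params)
  flatg <- shipflow:::flatten_params(grads)
  loss_at <- function(params) {
    m <- model
    m$params <- params
    flow_loss(shipflow:::model_forward(m, X, train = FALSE)$scores, y)
  }
  set_leaf <- function(params, path, i, val) {
    if (length(path) == 1) {
      params[[path]][i] <- val
    } else {
      params[[path[1]]] <- set_leaf(params[[path[1]]], path[-1], i, val)
    }
    params
  }
  max_err <- 0
  for (nm in names(flatp)) {
    p <- flatp[[nm]]
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    idx <- if (length(p) > n_per_param) {
      sample(length(p), n_per_param)
    } else {
      seq_along(p)
    }
    for (i in idx) {
      up <- loss_at(set_leaf(model$params, path, i, p[i] + eps))
      dn <- loss_at(set_leaf(model$params, path, i, p[i] - eps))
      num <- (up - dn) / (2 * eps)
      err <- abs(num - flatg[[nm]][i]) / max(1, abs(num))
      max_err <- max(max_err, err)
    }
  }
  max_err
}
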