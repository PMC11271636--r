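test_that("betweenness counts intermediates on simple chains", {
  reg <- toy_registry(c("a", "b", "c"))
  net <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "c")), reg
  )
  b <- port_betweenness(net, "unweighted")
  expect_equal(setNames(b$betweenness, b$port_id),
               c(a = 0, b = 1, c = 0))
  empty <- build_network(tibble::tibble(source = character(),
                                        dest = character()), reg)
  expect_true(all(port_betweenness(empty)$betweenness == 0))
})

test_that("closeness is 1 on complete graphs and 0 for isolated nodes", {
  reg <- toy_registry(c("a", "b", "c"))
  pairs <- expand.grid(source = reg$port_id, dest = reg$port_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$dest, ]
  net <- build_network(tibble::as_tibble(pairs), reg)
  cl <- port_closeness(net, "unweighted")
  expect_equal(cl$closeness, rep(1, 3))

  reg4 <- toy_registry(c("a", "b", "c", "z"))
  net4 <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "c")), reg4
  )
  expect_equal(port_closeness(net4)$closeness[4], 0) # z is isolated
})

test_that("pagerank is uniform on symmetric cycles and sums to one", {
  reg <- toy_registry(c("a", "b"))
  net <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "a")), reg
  )
  pr <- port_pagerank(net)
  expect_equal(pr$pagerank, c(0.5, 0.5), tolerance = 1e-9)

  reg3 <- toy_registry(c("a", "b", "c"))
  net3 <- build_network(
    tibble::tibble(source = c("a", "b", "c"), dest = c("b", "c", "a")), reg3
  )
  expect_equal(port_pagerank(net3)$pagerank, rep(1 / 3, 3), tolerance = 1e-9)

  net_r <- rand_net(7, 0.4, seed = 5)
  pr_r <- port_pagerank(net_r)
  expect_equal(sum(pr_r$pagerank), 1, tolerance = 1e-9)
  expect_true(all(pr_r$pagerank > 0 & pr_r$pagerank < 1))
})

test_that("pagerank matches dense power iteration and igraph", {
  for (seed in c(2, 13, 31)) {
    net <- rand_net(6, 0.45, seed = seed)
    got <- port_pagerank(net)
    want <- oracle_pagerank(net)
    expect_equal(setNames(got$pagerank, got$port_id), want,
                 tolerance = 1e-8)
    ig <- igraph::page_rank(shipflow:::as_port_igraph(net), damping = 0.85,
                            weights = net$edges$weight)$vector
    expect_equal(setNames(got$pagerank, got$port_id), ig[got$port_id],
                 tolerance = 1e-6)
  }
})

test_that("pagerank is invariant under node relabelling", {
  net <- rand_net(6, 0.5, seed = 8)
  perm <- c(4, 2, 6, 1, 5, 3)
  ports2 <- net$ports[perm, ]
  net2 <- build_network(
    tibble::tibble(source = net$edges$source, dest = net$edges$dest,
                   count = net$edges$weight), ports2
  )
  pr1 <- port_pagerank(net)
  pr2 <- port_pagerank(net2)
  expect_equal(pr1$pagerank[match(pr2$port_id, pr1$port_id)], pr2$pagerank,
               tolerance = 1e-12)
})

test_that("straightness is 1 along geodesic chains and 0 when isolated", {
  # three collinear equatorial ports connected along the chain
  reg <- toy_registry(c("a", "b", "c"), lat = c(0, 0, 0), lon = c(0, 5, 10))
  net <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "c")), reg
  )
  s <- port_straightness(net)
  expect_equal(s$straightness[s$port_id == "a"], 1, tolerance = 1e-12)
  # c reaches nothing
  expect_equal(s$straightness[s$port_id == "c"], 0)

  reg2 <- toy_registry(c("a", "b", "z"))
  net2 <- build_network(tibble::tibble(source = "a", dest = "b"), reg2)
  expect_equal(port_straightness(net2)$straightness[3], 0)
})

test_that("graph metrics equal exhaustive-path oracles on random digraphs", {
  for (seed in 1:12) {
    net <- rand_net(n = 4 + seed %% 5, p = 0.45, seed = 100 + seed)
    mode <- c("trips", "reciprocal", "unweighted")[1 + seed %% 3]
    b <- port_betweenness(net, mode)
    expect_equal(setNames(b$betweenness, b$port_id),
                 oracle_betweenness(net, mode), tolerance = 1e-9)
    cl <- port_closeness(net, mode)
    expect_equal(setNames(cl$closeness, cl$port_id),
                 oracle_closeness(net, mode), tolerance = 1e-9)
    s <- port_straightness(net)
    expect_equal(setNames(s$straightness, s$port_id),
                 oracle_straightness(net), tolerance = 1e-9)
  }
})

test_that("betweenness rankings associate positively across weight modes", {
  # trip-count and reciprocal edge costs give different shortest paths but
  # related centrality orderings on gravity worlds
  cors <- vapply(1:5, function(seed) {
    w <- cached_world(n_ports = 50, n_regions = 6, seed = seed)
    net <- build_network(w$trips, w$ports)
    cor(port_betweenness(net, "trips")$betweenness,
        port_betweenness(net, "reciprocal")$betweenness,
        method = "spearman")
  }, numeric(1))
  expect_true(all(cors > 0.3))
})

test_that("node_metrics assembles all four metrics per port", {
  net <- rand_net(6, 0.5, seed = 21)
  m <- node_metrics(net)
  expect_named(m, c("port_id", "betweenness", "closeness", "pagerank",
                    "straightness"))
  expect_true(all(is.finite(as.matrix(m[, -1]))))
  expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)
  expect_true(all(m$closeness >= 0 & m$closeness <= 1))
  expect_true(all(m$straightness >= 0 & m$straightness <= 1 + 1e-12))
})
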