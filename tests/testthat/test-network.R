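test_that("build_network sums trips into edge weights", {
  reg <- toy_registry(c("a", "b", "c"))
  empty <- build_network(tibble::tibble(source = character(),
                                        dest = character()), reg)
  expect_equal(nrow(empty$edges), 0)
  expect_false(empty$augmented)

  net <- build_network(
    tibble::tibble(source = c("a", "a", "b"), dest = c("b", "b", "c")), reg
  )
  expect_equal(nrow(net$edges), 2)
  w <- setNames(net$edges$weight, paste(net$edges$source, net$edges$dest))
  expect_equal(w[["a b"]], 2)
  expect_equal(w[["b c"]], 1)
})

test_that("edge weights equal brute-force pair tallies on random trips", {
  reg <- toy_registry(sprintf("p%d", 1:5))
  withr::with_seed(3, {
    trips <- tibble::tibble(
      source = sample(reg$port_id, 40, replace = TRUE),
      dest = sample(reg$port_id, 40, replace = TRUE)
    )
  })
  trips <- trips[trips$source != trips$dest, ]
  net <- build_network(trips, reg)
  tally <- table(paste(trips$source, trips$dest))
  got <- setNames(net$edges$weight, paste(net$edges$source, net$edges$dest))
  expect_equal(sort(names(got)), sort(names(tally)))
  expect_equal(as.numeric(got[names(tally)]), as.numeric(tally))
})

test_that("unknown ports are rejected by name and self-loops are dropped", {
  reg <- toy_registry(c("a", "b"))
  expect_error(
    build_network(tibble::tibble(source = "a", dest = "zzz"), reg), "zzz"
  )
  expect_message(
    net <- build_network(
      tibble::tibble(source = c("a", "a"), dest = c("a", "b")), reg
    ),
    "self-loop"
  )
  expect_equal(nrow(net$edges), 1)
})

test_that("fully_connect adds exactly the missing ordered pairs", {
  reg <- toy_registry(c("a", "b", "c"))
  net <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "c"),
                   count = c(5, 2)), reg
  )
  full <- fully_connect(net)
  expect_true(full$augmented)
  expect_equal(nrow(full$edges), 6)
  expect_equal(sum(full$edges$pseudo), 4)
  expect_true(all(full$edges$weight[full$edges$pseudo] == 0.1))
  # original weights preserved
  real <- full$edges[!full$edges$pseudo, ]
  expect_equal(sort(real$weight), c(2, 5))
  # second call violates the precondition
  expect_error(fully_connect(full), "already")
})

test_that("fully_connect on an edgeless network yields n(n-1) pseudo edges", {
  reg <- toy_registry(sprintf("p%d", 1:4))
  net <- build_network(tibble::tibble(source = character(),
                                      dest = character()), reg)
  full <- fully_connect(net)
  expect_equal(nrow(full$edges), 12)
  expect_true(all(full$edges$pseudo))
})

test_that("single-port networks are returned unchanged with a warning", {
  net <- build_network(tibble::tibble(source = character(),
                                      dest = character()),
                       toy_registry("solo"))
  expect_warning(out <- fully_connect(net), "fewer than two")
  expect_false(out$augmented)
})

test_that("inverse-distance pseudo weights decay with distance", {
  reg <- toy_registry(c("a", "b", "c"), lat = c(0, 0, 0), lon = c(0, 10, 120))
  net <- build_network(tibble::tibble(source = "a", dest = "b"), reg)
  full <- fully_connect(net, mode = "inverse_distance")
  ps <- full$edges[full$edges$pseudo, ]
  w_ac <- ps$weight[ps$source == "a" & ps$dest == "c"]
  w_bc <- ps$weight[ps$source == "b" & ps$dest == "c"]
  expect_true(w_ac < w_bc) # a is farther from c than b is
  expect_true(all(ps$weight <= 0.1 + 1e-12))
})

test_that("weak and strong components match a reachability-closure oracle", {
  # two disjoint 2-cycles
  reg <- toy_registry(c("a", "b", "c", "d"))
  net <- build_network(
    tibble::tibble(source = c("a", "b", "c", "d"),
                   dest = c("b", "a", "d", "c")), reg
  )
  comp <- network_components(net)
  expect_equal(comp$n_weak, 2)
  expect_equal(comp$n_strong, 2)

  # single edge: 1 weak, 2 strong
  net2 <- build_network(tibble::tibble(source = "a", dest = "b"),
                        toy_registry(c("a", "b")))
  comp2 <- network_components(net2)
  expect_equal(comp2$n_weak, 1)
  expect_equal(comp2$n_strong, 2)

  for (seed in 1:20) {
    net3 <- rand_net(n = 3 + seed %% 6, p = 0.3, seed = seed)
    got <- network_components(net3)
    want <- oracle_components(net3)
    expect_equal(got$n_weak, want$n_weak)
    expect_equal(got$n_strong, want$n_strong)
  }
})

test_that("GraphML export round-trips weights and metric attributes", {
  net <- rand_net(5, 0.5, seed = 9)
  metrics <- node_metrics(net)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path, metrics)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true(all(c("pagerank", "betweenness") %in%
                    igraph::vertex_attr_names(g)))
  got_w <- sort(igraph::E(g)$w %||% igraph::E(g)$weight)
  expect_equal(got_w, sort(net$edges$weight))
})

test_that("registry and trip CSV readers validate their schemas", {
  reg <- toy_registry(c("a", "b"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg, f1)
  expect_equal(read_port_registry(f1)$port_id, c("a", "b"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(src = "a", dst = "b"), f2)
  expect_error(read_trips(f2), "source")
})
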