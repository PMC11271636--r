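make_full_net <- function(n_ports = 40, seed = 1) {
  w <- cached_world(n_ports = n_ports, n_regions = 6, seed = seed)
  net <- build_network(w$trips, w$ports)
  list(world = w, net = net, full = fully_connect(net))
}

test_that("edge importance equals a hand-computed min-max oracle", {
  # 4-port line on the equator, 3 real edges with weights 2,3,4 + pseudo 0.1
  reg <- toy_registry(c("a", "b", "c", "d"), lat = rep(0, 4),
                      lon = c(0, 10, 30, 60))
  net <- build_network(
    tibble::tibble(source = c("a", "b", "c"), dest = c("b", "c", "d"),
                   count = c(2, 3, 4)), reg
  )
  full <- fully_connect(net)
  imp <- edge_importance(full, eps = 1e-6)
  key <- paste(full$edges$source, full$edges$dest)
  d <- shipflow:::edge_lengths_km(full)
  w_hat <- (full$edges$weight - 0.1) / (4 - 0.1)
  d_hat <- (d - min(d)) / (max(d) - min(d))
  expect_equal(imp$edge_importance, w_hat / (d_hat + 1e-6), tolerance = 1e-12)
  # the pseudo edges carry the minimum weight, hence zero importance
  expect_true(all(imp$edge_importance[full$edges$pseudo] == 0))
  # highest importance: heaviest short link relative to the grid
  expect_error(edge_importance(net), "fully connected")
})

test_that("degenerate normalisation yields zeros with a warning", {
  reg <- toy_registry(c("a", "b"), lat = c(0, 0), lon = c(0, 10))
  net <- build_network(
    tibble::tibble(source = c("a", "b"), dest = c("b", "a"),
                   count = c(3, 3)), reg
  )
  # both edges real and equal: constant weights AND constant distances
  full <- structure(net, class = "shipping_network")
  full$augmented <- TRUE
  expect_warning(expect_warning(imp <- edge_importance(full), "weights"),
                 "distances")
  expect_true(all(imp$edge_importance == 0))
})

test_that("stratified balancing keeps all real rows and matches allocation", {
  x <- make_full_net(seed = 2)
  rows <- edge_feature_rows(x$full)
  bal <- suppressMessages(sample_pseudo_links(rows, seed = 5))
  n_real <- sum(rows$label == "real")
  expect_equal(sum(bal$label == "real"), n_real)
  expect_equal(sum(bal$label == "pseudo"), n_real)
  # no duplicated pseudo rows
  ps <- bal[bal$label == "pseudo", ]
  expect_equal(anyDuplicated(paste(ps$source, ps$dest)), 0)

  # determinism
  bal2 <- suppressMessages(sample_pseudo_links(rows, seed = 5))
  expect_identical(bal, bal2)
  bal3 <- suppressMessages(sample_pseudo_links(rows, seed = 6))
  expect_false(identical(bal, bal3))

  # per-stratum counts within 1 of proportional allocation
  pseudo <- rows[rows$label == "pseudo", ]
  brk <- unique(quantile(pseudo$d_haversine, seq(0, 1, 0.1)))
  strat <- function(d, r) paste(cut(d, brk, include.lowest = TRUE,
                                    labels = FALSE), r)
  pop <- table(strat(pseudo$d_haversine, pseudo$source_region))
  got <- table(factor(strat(ps$d_haversine, ps$source_region),
                      levels = names(pop)))
  expected <- n_real * as.numeric(pop) / nrow(pseudo)
  expect_true(all(abs(as.numeric(got) - expected) <= 1 + 1e-9))
})

test_that("classifiers separate a linearly separable fixture perfectly", {
  withr::with_seed(4, {
    n <- 400
    lab <- rep(c("real", "pseudo"), each = n / 2)
    d <- ifelse(lab == "real", runif(n, 100, 4000), runif(n, 6000, 15000))
    rows <- tibble::tibble(
      d_haversine = d, d_searoute = d * 1.15,
      edge_importance = ifelse(lab == "real", runif(n, 0.5, 1), 0),
      label = factor(lab, levels = c("real", "pseudo"))
    )
  })
  sc <- train_link_classifier(
    rows, screen_config(classifier_menu = c("decision_tree", "random_forest"),
                        seed = 1)
  )
  expect_true(all(sc$report$val_accuracy == 1))
})

test_that("label-shuffled rows score at chance level", {
  withr::with_seed(9, {
    n <- 2000
    rows <- tibble::tibble(
      d_haversine = runif(n, 100, 15000),
      d_searoute = runif(n, 100, 17000),
      edge_importance = runif(n),
      label = factor(sample(rep(c("real", "pseudo"), each = n / 2)),
                     levels = c("real", "pseudo"))
    )
  })
  sc <- train_link_classifier(
    rows, screen_config(classifier_menu = "logistic", seed = 2)
  )
  expect_gte(sc$report$val_accuracy, 0.4)
  expect_lte(sc$report$val_accuracy, 0.6)
})

test_that("single-class input is rejected and reports reproduce under seed", {
  rows <- tibble::tibble(
    d_haversine = runif(50), d_searoute = runif(50),
    edge_importance = runif(50),
    label = factor(rep("real", 50), levels = c("real", "pseudo"))
  )
  expect_error(train_link_classifier(rows), "single class")

  x <- make_full_net(seed = 3)
  bal <- suppressMessages(
    sample_pseudo_links(edge_feature_rows(x$full), seed = 1)
  )
  cfgm <- screen_config(classifier_menu = c("logistic", "xgboost"), seed = 4)
  r1 <- train_link_classifier(bal, cfgm)$report
  r2 <- train_link_classifier(bal, cfgm)$report
  expect_identical(r1, r2)
})

test_that("edge importance never hurts accuracy on gravity worlds", {
  x <- make_full_net(seed = 7)
  bal <- suppressMessages(
    sample_pseudo_links(
      edge_feature_rows(x$full, provider = synthetic_route_provider()),
      seed = 7
    )
  )
  with_imp <- train_link_classifier(bal, screen_config(seed = 7))$report
  without <- train_link_classifier(
    bal, screen_config(use_edge_importance = FALSE, seed = 7)
  )$report
  cmp <- dplyr::left_join(with_imp, without, by = "model",
                          suffix = c("_with", "_without"))
  expect_true(all(cmp$val_accuracy_with >= cmp$val_accuracy_without))
})

test_that("screen_links honours the classifier's decisions", {
  x <- make_full_net(seed = 8)
  rows <- edge_feature_rows(x$full)
  bal <- suppressMessages(sample_pseudo_links(rows, seed = 8))
  sc <- train_link_classifier(bal, screen_config(seed = 8))

  # forced all-real / all-pseudo classifiers via a rigged logistic fit
  rig <- sc$models$logistic
  rig$fit$coefficients[] <- 0
  rig$fit$coefficients[1] <- -50 # P(pseudo) ~ 0 -> everything real
  all_real <- screen_links(x$full, rig)
  n <- nrow(x$full$ports)
  expect_equal(nrow(all_real), n * (n - 1))
  rig$fit$coefficients[1] <- 50 # everything pseudo
  expect_equal(nrow(screen_links(x$full, rig)), 0)

  # trained filter keeps nearly all stable (>= 3 trip) links
  retained <- screen_links(x$full, sc)
  stable <- x$net$edges[x$net$edges$weight >= 3, c("source", "dest")]
  recall <- nrow(dplyr::semi_join(stable, retained,
                                  by = c("source", "dest"))) / nrow(stable)
  expect_gte(recall, 0.9)
})
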