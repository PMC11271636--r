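test_that("the packaged mapping resolves reference countries and regions", {
  reg <- toy_registry(c("suez", "keppel"), lat = c(30, 1.3),
                      lon = c(32.5, 103.8),
                      country = c("Egypt", "Singapore"))
  rt <- encode_regions(reg)
  got <- setNames(rt$ports$region, rt$ports$country)
  expect_equal(got[["Egypt"]], "Northern Africa")
  expect_equal(got[["Singapore"]], "South-eastern Asia")
  expect_lte(length(unique(default_region_mapping()$region)), 17)
})

test_that("unmapped countries are rejected by name", {
  reg <- toy_registry("x1", country = "Atlantis")
  expect_error(encode_regions(reg), "Atlantis")
})

test_that("region centroids sit on the symmetry axis of their ports", {
  reg <- toy_registry(c("n", "s"), lat = c(30, -30), lon = c(10, 10),
                      country = "AA")
  rt <- encode_regions(reg, mapping = tibble::tibble(country = "AA",
                                                     region = "R1"))
  expect_equal(rt$regions$centroid_lat, 0, tolerance = 1e-9)
  expect_equal(rt$regions$centroid_lon, 10, tolerance = 1e-9)
})

# a hand-checkable 5-port fixture: two countries/regions, fixed trips/trade
fixture_world <- function() {
  reg <- tibble::tibble(
    port_id = c("a1", "a2", "b1", "b2", "b3"),
    name = port_id <- c("a1", "a2", "b1", "b2", "b3"),
    lat = c(0, 0, 10, 10, 20), lon = c(0, 10, 50, 60, 55),
    country = c("A", "A", "B", "B", "B"),
    region = c("RA", "RA", "RB", "RB", "RB")
  )
  trips <- tibble::tibble(
    source = c("a1", "a1", "a1", "a2", "b1"),
    dest = c("a2", "b1", "b2", "b1", "a1"),
    count = c(4, 2, 3, 5, 1)
  )
  trade <- tibble::tibble(
    exporter = c("A", "B"), importer = c("B", "A"), usd = c(1000, 700)
  )
  list(reg = reg, trips = trips, trade = trade)
}

test_that("assembled samples match a hand-computed feature matrix", {
  fx <- fixture_world()
  net <- build_network(fx$trips, fx$reg)
  metrics <- node_metrics(net)
  regions <- encode_regions(fx$reg, tibble::tibble(country = c("A", "B"),
                                                   region = c("RA", "RB")))
  samples <- expect_message(
    assemble_samples(net, metrics, regions, fx$trade),
    NA
  )
  # a1 ships to RA (4 trips) and RB (2+3 trips): one sample with N = 2
  a1 <- samples[samples$source == "a1", ]
  expect_equal(nrow(a1), 2)
  expect_equal(a1$O_i, c(9, 9))
  expect_equal(setNames(a1$y, a1$region), c(RA = 4, RB = 5))
  # origin out-flux and region in-flux by direct tally
  expect_equal(a1$flux_origin, c(9, 9))
  expect_equal(setNames(a1$flux_dest_region, a1$region),
               c(RA = 4 + 1, RB = 2 + 3 + 5))
  # same-country trade is zero; cross-country trade is the table value
  expect_equal(setNames(a1$trade_usd, a1$region), c(RA = 0, RB = 1000))
  # metric features copied from the metrics table / region medians
  expect_equal(a1$betw_origin,
               rep(metrics$betweenness[metrics$port_id == "a1"], 2))
  b_reg <- metrics$betweenness[metrics$port_id %in% c("b1", "b2", "b3")]
  expect_equal(a1$betw_region_med[a1$region == "RB"], median(b_reg))
  # distance feature: haversine to the region centroid
  cen <- regions$regions
  expect_equal(
    a1$distance_km[a1$region == "RB"],
    haversine_km(0, 0, cen$centroid_lat[cen$region == "RB"],
                 cen$centroid_lon[cen$region == "RB"])
  )
  # flows sum to O_i when every destination is retained
  sums <- tapply(samples$y, samples$source, sum)
  expect_equal(as.numeric(sums), unique(samples[, c("source", "O_i")])$O_i)
})

test_that("retained links restrict the destination regions", {
  fx <- fixture_world()
  net <- build_network(fx$trips, fx$reg)
  metrics <- node_metrics(net)
  regions <- encode_regions(fx$reg, tibble::tibble(country = c("A", "B"),
                                                   region = c("RA", "RB")))
  retained <- tibble::tibble(source = c("a1", "a1"), dest = c("b1", "b2"))
  samples <- assemble_samples(net, metrics, regions, fx$trade,
                              retained_links = retained)
  expect_equal(unique(samples$source), "a1")
  expect_equal(samples$region, "RB")
  expect_equal(samples$y, 5)
})

test_that("missing trade pairs count as zero with a message", {
  fx <- fixture_world()
  net <- build_network(fx$trips, fx$reg)
  metrics <- node_metrics(net)
  regions <- encode_regions(fx$reg, tibble::tibble(country = c("A", "B"),
                                                   region = c("RA", "RB")))
  expect_message(
    samples <- assemble_samples(net, metrics, regions,
                                fx$trade[0, ]),
    "missing"
  )
  expect_true(all(samples$trade_usd == 0))
})

test_that("feature scaling is invertible and centred on the training split", {
  x <- cached_samples(n_ports = 40, n_regions = 6, seed = 4)
  sc <- scale_features(x$samples)
  feats <- shipflow:::od_feature_cols()
  scaled_feats <- sc$stats$feature[sc$stats$scaled]
  for (f in scaled_feats) {
    expect_equal(mean(sc$samples[[f]]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$samples[[f]]), 1, tolerance = 1e-9)
  }
  back <- unscale_features(sc$samples, sc$stats)
  for (f in feats) {
    expect_equal(back[[f]], x$samples[[f]], tolerance = 1e-12)
  }
})

test_that("constant features pass through unscaled with a warning", {
  x <- cached_samples(n_ports = 40, n_regions = 6, seed = 4)
  s <- x$samples
  s$trade_usd <- 5
  expect_warning(sc <- scale_features(s), "trade_usd")
  expect_true(all(sc$samples$trade_usd == 5))
})

test_that("sample JSONL round-trips the feature matrices", {
  x <- cached_samples(n_ports = 40, n_regions = 6, seed = 4)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_samples_jsonl(x$samples, path)
  back <- read_samples_jsonl(path)
  ord <- function(d) d[order(d$source, d$region), ]
  a <- ord(as.data.frame(x$samples))
  b <- ord(as.data.frame(back))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-12)
})
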