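# Cached small synthetic worlds so multiple test files can share fixtures
# without regenerating them.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(n_ports = 60, n_regions = 8, seed = 1, ...) {
  key <- paste(n_ports, n_regions, seed, ...)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_synthetic_world(
      world_config(n_ports = n_ports, n_regions = n_regions, seed = seed, ...)
    )
  }
  .world_cache[[key]]
}

# network + metrics + samples for a cached world
cached_samples <- function(n_ports = 60, n_regions = 8, seed = 1) {
  key <- paste("S", n_ports, n_regions, seed)
  if (is.null(.world_cache[[key]])) {
    w <- cached_world(n_ports, n_regions, seed)
    net <- build_network(w$trips, w$ports)
    metrics <- node_metrics(net)
    regions <- encode_regions(w$ports, w$country_regions)
    samples <- assemble_samples(net, metrics, regions, w$trade)
    .world_cache[[key]] <- list(world = w, net = net, metrics = metrics,
                                regions = regions, samples = samples)
  }
  .world_cache[[key]]
}

# minimal hand-built registry helper
toy_registry <- function(ids, lat = NULL, lon = NULL, country = "XX",
                         region = NA_character_) {
  n <- length(ids)
  tibble::tibble(
    port_id = ids,
    name = ids,
    lat = lat %||% seq(0, 10, length.out = n),
    lon = lon %||% seq(0, 10, length.out = n),
    country = rep_len(country, n),
    region = rep_len(region, n)
  )
}
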