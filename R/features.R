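# Frozen feature order of the gravity vectors. Any reorder is an API break.
od_feature_cols <- function() {
  c("flux_origin", "flux_dest_region", "distance_km", "trade_usd",
    "betw_origin", "betw_region_med", "close_origin", "close_region_med",
    "pr_origin", "pr_region_med")
}

#' The packaged country-to-region mapping
#'
#' A UN-subregion-style mapping of countries into 17 geographic region
#' tokens, used to encode destination ports into prediction classes. It is a
#' default: pass your own mapping to [encode_regions()] to override it.
#'
#' @return A tibble `country`, `region`.
#' @export
default_region_mapping <- function() {
  path <- system.file("extdata", "country_regions.csv", package = "shipflow")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Encode ports into geographic regions
#'
#' Assigns each port's country to a region (at most 17 region tokens) and
#' computes each region's spherical centroid over its member ports: member
#' locations are averaged as unit vectors on the sphere and the mean is
#' projected back to latitude/longitude.
#'
#' @param registry A port registry (see [build_network()]).
#' @param mapping A data frame `country`, `region`; defaults to
#'   [default_region_mapping()]. Every registry country must be mapped.
#' @return A `region_table`: list with `ports` (registry plus resolved
#'   `region`), `country_regions`, and `regions` (tibble `region`,
#'   `centroid_lat`, `centroid_lon`, `n_ports`).
#' @export
encode_regions <- function(registry, mapping = default_region_mapping()) {
  registry <- validate_registry(registry)
  assert_columns(mapping, c("country", "region"), "mapping")
  mapping <- dplyr::distinct(tibble::as_tibble(mapping),
                             .data$country, .data$region)
  if (anyDuplicated(mapping$country) > 0) {
    stop_shipflow("mapping assigns some country to more than one region")
  }
  unmapped <- setdiff(unique(registry$country), mapping$country)
  if (length(unmapped) > 0) {
    stop_shipflow(sprintf(
      "no region mapping for countr%s: %s",
      if (length(unmapped) == 1) "y" else "ies",
      paste(unmapped, collapse = ", ")
    ))
  }
  if (length(unique(mapping$region)) > 17) {
    stop_shipflow("region mapping defines more than 17 regions")
  }
  registry$region <- mapping$region[match(registry$country, mapping$country)]

  regions <- registry |>
    dplyr::group_by(region = .data$region) |>
    dplyr::summarise(
      centroid_lat = spherical_centroid(.data$lat, .data$lon)[1],
      centroid_lon = spherical_centroid(.data$lat, .data$lon)[2],
      n_ports = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(ports = registry,
         country_regions = mapping[mapping$country %in% registry$country, ],
         regions = regions),
    class = "region_table"
  )
}

# Mean direction on the unit sphere, returned as c(lat, lon) in degrees.
spherical_centroid <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  x <- mean(cos(phi) * cos(lam))
  y <- mean(cos(phi) * sin(lam))
  z <- mean(sin(phi))
  r <- sqrt(x^2 + y^2 + z^2)
  if (r < 1e-12) return(c(0, 0)) # antipodal degenerate: undefined direction
  c(asin(z / r) * 180 / pi, atan2(y, x) * 180 / pi)
}

#' Assemble per-source gravity samples
#'
#' For every source port with at least one retained destination, builds one
#' sample: its destination classes are the distinct regions of its retained
#' destination ports, and each (source, region) row carries the 10 gravity
#' features in frozen order:
#' origin port out-flux; destination-region in-flux; great-circle km from the
#' source port to the region centroid; bilateral trade (USD exported from the
#' source country, summed over the region's member countries, with
#' intra-country pairs contributing zero); origin betweenness and region
#' median betweenness; origin closeness and region median closeness; origin
#' PageRank and region median PageRank. Region medians are taken over member
#' ports present in the network. `O_i` is the total observed departures from
#' the source and `y` the observed trips into each region.
#'
#' @param net The un-augmented `shipping_network` (observed links only).
#' @param metrics Node metrics computed on `net` (see [node_metrics()]).
#' @param regions A `region_table` covering the network's ports.
#' @param trade A data frame `exporter`, `importer`, `usd` (country level).
#'   Missing pairs count as zero (a message reports how many were missing).
#' @param retained_links Tibble `source`, `dest` of screened pairs; defaults
#'   to the network's observed edges.
#' @return A tibble with one row per (source, region): `source`, `region`,
#'   the 10 feature columns, `O_i` and `y`.
#' @export
assemble_samples <- function(net, metrics, regions, trade,
                             retained_links = NULL) {
  stopifnot(inherits(net, "shipping_network"), inherits(regions, "region_table"))
  if (net$augmented) {
    stop_shipflow("assemble_samples expects the un-augmented network")
  }
  assert_columns(metrics, c("port_id", "betweenness", "closeness", "pagerank"),
                 "metrics")
  if (anyNA(match(net$ports$port_id, metrics$port_id))) {
    stop_shipflow("metrics are missing some network ports")
  }
  assert_columns(trade, c("exporter", "importer", "usd"), "trade")
  if (is.null(retained_links)) {
    retained_links <- net$edges[, c("source", "dest")]
  }

  ports <- regions$ports
  if (anyNA(match(net$ports$port_id, ports$port_id))) {
    stop_shipflow("region table does not cover all network ports")
  }
  port_region <- setNames(ports$region, ports$port_id)
  port_country <- setNames(ports$country, ports$port_id)

  real <- dplyr::filter(net$edges, !.data$pseudo)
  out_flux <- tapply(real$weight, real$source, sum)
  in_flux <- tapply(real$weight, real$dest, sum)
  region_influx <- tapply(real$weight, port_region[real$dest], sum)

  # region medians over member ports present in the network
  mtab <- metrics[match(net$ports$port_id, metrics$port_id), ]
  mtab$region <- port_region[net$ports$port_id]
  region_med <- mtab |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      betw_region_med = median(.data$betweenness),
      close_region_med = median(.data$closeness),
      pr_region_med = median(.data$pagerank),
      .groups = "drop"
    )

  # observed trips source -> region (only over retained destinations)
  obs <- real |>
    dplyr::semi_join(retained_links, by = c("source", "dest")) |>
    dplyr::mutate(region = unname(port_region[.data$dest])) |>
    dplyr::group_by(.data$source, .data$region) |>
    dplyr::summarise(y = sum(.data$weight), .groups = "drop")

  pairs <- retained_links |>
    dplyr::mutate(region = unname(port_region[.data$dest])) |>
    dplyr::distinct(.data$source, .data$region) |>
    dplyr::arrange(.data$source, .data$region)

  src_ll <- ports[match(pairs$source, ports$port_id), c("lat", "lon")]
  cen <- regions$regions[match(pairs$region, regions$regions$region), ]

  trade_key <- paste(trade$exporter, trade$importer, sep = "\r")
  trade_usd <- setNames(trade$usd, trade_key)
  region_countries <- split(regions$country_regions$country,
                            regions$country_regions$region)
  missing_trade <- 0L
  pair_trade <- vapply(seq_len(nrow(pairs)), function(r) {
    sc <- port_country[[pairs$source[r]]]
    members <- setdiff(region_countries[[pairs$region[r]]], sc)
    if (length(members) == 0) return(0)
    vals <- trade_usd[paste(sc, members, sep = "\r")]
    missing_trade <<- missing_trade + sum(is.na(vals))
    sum(vals, na.rm = TRUE)
  }, numeric(1))
  if (missing_trade > 0) {
    inform(sprintf("%d country pair(s) missing from the trade table (as 0)",
                   missing_trade))
  }

  samples <- tibble::tibble(
    source = pairs$source,
    region = pairs$region,
    flux_origin = as.numeric(out_flux[pairs$source]),
    flux_dest_region = as.numeric(region_influx[pairs$region]),
    distance_km = haversine_km(src_ll$lat, src_ll$lon,
                               cen$centroid_lat, cen$centroid_lon),
    trade_usd = pair_trade,
    betw_origin = mtab$betweenness[match(pairs$source, mtab$port_id)],
    betw_region_med = region_med$betw_region_med[
      match(pairs$region, region_med$region)],
    close_origin = mtab$closeness[match(pairs$source, mtab$port_id)],
    close_region_med = region_med$close_region_med[
      match(pairs$region, region_med$region)],
    pr_origin = mtab$pagerank[match(pairs$source, mtab$port_id)],
    pr_region_med = region_med$pr_region_med[
      match(pairs$region, region_med$region)]
  )
  samples$flux_origin[is.na(samples$flux_origin)] <- 0
  samples$flux_dest_region[is.na(samples$flux_dest_region)] <- 0
  samples <- samples |>
    dplyr::left_join(obs, by = c("source", "region")) |>
    dplyr::mutate(y = dplyr::coalesce(.data$y, 0)) |>
    dplyr::mutate(O_i = as.numeric(out_flux[.data$source]),
                  .before = "y")
  samples <- dplyr::filter(samples, !is.na(.data$O_i), .data$O_i > 0)
  samples
}

#' Standardise gravity features with training-split statistics
#'
#' Z-scores the 10 feature columns. When `stats` is `NULL` the statistics are
#' fitted from `samples` (the training split); pass the returned `stats` to
#' scale validation/test samples with training statistics only. Constant
#' features are passed through unscaled and flagged.
#'
#' @param samples A samples tibble from [assemble_samples()].
#' @param stats Optional statistics tibble from a previous call.
#' @return A list `samples` (scaled tibble) and `stats` (tibble `feature`,
#'   `mean`, `sd`, `scaled`).
#' @export
scale_features <- function(samples, stats = NULL) {
  feats <- od_feature_cols()
  assert_columns(samples, feats, "samples")
  if (is.null(stats)) {
    stats <- tibble::tibble(
      feature = feats,
      mean = vapply(feats, function(f) mean(samples[[f]]), numeric(1)),
      sd = vapply(feats, function(f) sd(samples[[f]]), numeric(1))
    )
    stats$scaled <- is.finite(stats$sd) & stats$sd > 0
    if (any(!stats$scaled)) {
      warn(sprintf("constant feature(s) passed through unscaled: %s",
                   paste(stats$feature[!stats$scaled], collapse = ", ")))
    }
  }
  for (r in seq_len(nrow(stats))) {
    if (stats$scaled[r]) {
      f <- stats$feature[r]
      samples[[f]] <- (samples[[f]] - stats$mean[r]) / stats$sd[r]
    }
  }
  list(samples = samples, stats = stats)
}

#' @rdname scale_features
#' @export
unscale_features <- function(samples, stats) {
  for (r in seq_len(nrow(stats))) {
    if (stats$scaled[r]) {
      f <- stats$feature[r]
      samples[[f]] <- samples[[f]] * stats$sd[r] + stats$mean[r]
    }
  }
  samples
}

#' Write / read gravity samples as JSON lines
#'
#' One JSON object per source port, carrying the region list, the 10-feature
#' matrix in frozen column order, `O_i` and the observed flows.
#'
#' @param samples A samples tibble.
#' @param path Output / input file path.
#' @return `path` invisibly; `read_samples_jsonl()` returns the tibble.
#' @export
write_samples_jsonl <- function(samples, path) {
  feats <- od_feature_cols()
  by_src <- split(samples, samples$source)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in names(by_src)) {
    d <- by_src[[s]]
    obj <- list(source = s, regions = d$region,
                X = unname(as.matrix(d[, feats])),
                O_i = d$O_i[1], y = d$y)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_samples_jsonl
#' @export
read_samples_jsonl <- function(path) {
  lines <- readLines(path)
  feats <- od_feature_cols()
  purrr::map_dfr(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    X <- matrix(obj$X, ncol = length(feats))
    colnames(X) <- feats
    dplyr::bind_cols(
      tibble::tibble(source = obj$source, region = obj$regions),
      tibble::as_tibble(X),
      tibble::tibble(O_i = obj$O_i, y = obj$y)
    )
  })
}
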