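#' Build a directed weighted shipping network from trip records
#'
#' Ports are nodes; an edge (i, j) carries the total number of individual
#' trips observed from port i to port j. Self-loops are dropped (with a
#' message reporting how many), and every port id appearing in the trips must
#' exist in the registry.
#'
#' @param trips A data frame of trip records with columns `source` and `dest`
#'   (port ids) and optionally `count` (positive integer; absent means one
#'   event per row). Extra columns (e.g. `year`) are ignored.
#' @param registry A data frame of ports with columns `port_id`, `lat`, `lon`,
#'   `country` and optionally `name`, `region`.
#' @return A `shipping_network`: a list with tibbles `ports` and `edges`
#'   (`source`, `dest`, `weight`, `pseudo`) and the flag `augmented = FALSE`.
#' @examples
#' reg <- tibble::tibble(port_id = c("a", "b", "c"),
#'                       lat = c(0, 10, 20), lon = c(0, 10, 20),
#'                       country = "XX")
#' trips <- tibble::tibble(source = c("a", "a", "b"), dest = c("b", "b", "c"))
#' net <- build_network(trips, reg)
#' net$edges
#' @export
build_network <- function(trips, registry) {
  registry <- validate_registry(registry)
  assert_columns(trips, c("source", "dest"), "trips")
  trips <- tibble::as_tibble(trips)
  if (!"count" %in% names(trips)) trips$count <- 1L
  if (any(!is.finite(trips$count)) || any(trips$count < 0)) {
    stop_shipflow("trip counts must be non-negative and finite")
  }

  unknown <- setdiff(unique(c(trips$source, trips$dest)), registry$port_id)
  if (length(unknown) > 0) {
    stop_shipflow(sprintf(
      "trip records reference unknown port id(s): %s",
      paste(head(unknown, 10), collapse = ", ")
    ))
  }

  n_self <- sum(trips$source == trips$dest)
  if (n_self > 0) {
    inform(sprintf("dropped %d self-loop trip row(s)", n_self))
    trips <- dplyr::filter(trips, .data$source != .data$dest)
  }

  edges <- trips |>
    dplyr::group_by(.data$source, .data$dest) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::mutate(pseudo = FALSE) |>
    dplyr::arrange(.data$source, .data$dest)

  new_shipping_network(ports = registry, edges = edges, augmented = FALSE)
}

new_shipping_network <- function(ports, edges, augmented) {
  structure(
    list(ports = ports, edges = edges, augmented = augmented),
    class = "shipping_network"
  )
}

validate_registry <- function(registry) {
  assert_columns(registry, c("port_id", "lat", "lon", "country"), "registry")
  registry <- tibble::as_tibble(registry)
  if (anyDuplicated(registry$port_id) > 0) {
    stop_shipflow("registry port_id values must be unique")
  }
  if (any(is.na(registry$country) | registry$country == "")) {
    stop_shipflow("registry country must be non-empty for every port")
  }
  check_lat_lon(registry$lat, registry$lon)
  if (!"name" %in% names(registry)) registry$name <- registry$port_id
  if (!"region" %in% names(registry)) registry$region <- NA_character_
  registry[, c("port_id", "name", "lat", "lon", "country", "region")]
}

#' @export
print.shipping_network <- function(x, ...) {
  cat(sprintf(
    "<shipping_network> %d ports, %d directed edges (%d pseudo)%s\n",
    nrow(x$ports), nrow(x$edges), sum(x$edges$pseudo),
    if (x$augmented) ", fully connected" else ""
  ))
  invisible(x)
}

#' Fully connect a shipping network with small-weight pseudo-edges
#'
#' Disconnected and weakly connected parts of a real shipping network starve
#' the downstream models of candidate destinations, so every absent ordered
#' pair is added as a "pseudo" edge with a small weight (default 0.1). An
#' inverse-distance mode is also available, where pseudo weights decay with
#' the great-circle distance between the pair (scaled so the closest pseudo
#' pair receives `pseudo_weight`).
#'
#' @param net A non-augmented `shipping_network`.
#' @param pseudo_weight Weight given to added edges (constant mode), default
#'   0.1.
#' @param mode `"constant"` (default) or `"inverse_distance"`.
#' @return The augmented `shipping_network` with `augmented = TRUE`; original
#'   edges and weights are untouched and carry `pseudo = FALSE`.
#' @export
fully_connect <- function(net, pseudo_weight = 0.1,
                          mode = c("constant", "inverse_distance")) {
  stopifnot(inherits(net, "shipping_network"))
  mode <- match.arg(mode)
  if (net$augmented) {
    stop_shipflow("network is already fully connected")
  }
  if (pseudo_weight <= 0) stop_shipflow("pseudo_weight must be positive")
  ids <- net$ports$port_id
  n <- length(ids)
  if (n < 2) {
    warn("network has fewer than two ports; nothing to connect")
    return(net)
  }

  all_pairs <- tidyr::expand_grid(source = ids, dest = ids) |>
    dplyr::filter(.data$source != .data$dest)
  missing <- dplyr::anti_join(all_pairs, net$edges, by = c("source", "dest"))

  if (mode == "constant") {
    missing$weight <- pseudo_weight
  } else {
    loc <- net$ports[match(missing$source, net$ports$port_id), c("lat", "lon")]
    loc2 <- net$ports[match(missing$dest, net$ports$port_id), c("lat", "lon")]
    d <- haversine_km(loc$lat, loc$lon, loc2$lat, loc2$lon)
    d <- pmax(d, 1) # two ports at the same location: cap the weight
    missing$weight <- pseudo_weight * min(d) / d
  }
  missing$pseudo <- TRUE

  edges <- dplyr::bind_rows(net$edges, missing) |>
    dplyr::arrange(.data$source, .data$dest)
  stopifnot(nrow(edges) == n * (n - 1))
  new_shipping_network(net$ports, edges, augmented = TRUE)
}

#' Weak and strong connectivity structure of the network
#'
#' @param net A `shipping_network`.
#' @return A list with `membership` (tibble: `port_id`, `weak`, `strong`
#'   component labels) and counts `n_weak`, `n_strong`.
#' @export
network_components <- function(net) {
  g <- as_port_igraph(net)
  weak <- igraph::components(g, mode = "weak")
  strong <- igraph::components(g, mode = "strong")
  list(
    membership = tibble::tibble(
      port_id = net$ports$port_id,
      weak = unname(weak$membership[net$ports$port_id]),
      strong = unname(strong$membership[net$ports$port_id])
    ),
    n_weak = weak$no,
    n_strong = strong$no
  )
}

# igraph view of the network; vertex order follows the port registry.
as_port_igraph <- function(net) {
  verts <- net$ports[, c("port_id", "name", "lat", "lon", "country",
                         "region")]
  names(verts)[2] <- "port_name" # igraph reserves `name` for vertex ids
  igraph::graph_from_data_frame(
    net$edges[, c("source", "dest", "weight", "pseudo")],
    directed = TRUE,
    vertices = verts
  )
}

# Shortest-path edge costs under the three weighting conventions.
# Trip counts are the paper-facing weights; reciprocal reads them as
# proximities (cost = 1/w); unweighted ignores them.
edge_costs <- function(net, weight_mode = c("trips", "reciprocal",
                                            "unweighted")) {
  weight_mode <- match.arg(weight_mode)
  switch(weight_mode,
    trips = net$edges$weight,
    reciprocal = 1 / net$edges$weight,
    unweighted = NA # igraph: ignore the weight attribute
  )
}

# Haversine length in km of every edge, in edge order.
edge_lengths_km <- function(net) {
  i <- match(net$edges$source, net$ports$port_id)
  j <- match(net$edges$dest, net$ports$port_id)
  haversine_km(net$ports$lat[i], net$ports$lon[i],
               net$ports$lat[j], net$ports$lon[j])
}

#' Export a shipping network (optionally with node metrics) to GraphML
#'
#' @param net A `shipping_network`.
#' @param path Output file path.
#' @param metrics Optional node-metrics tibble (see [node_metrics()]) to be
#'   attached as vertex attributes.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, metrics = NULL) {
  g <- as_port_igraph(net)
  if (!is.null(metrics)) {
    assert_columns(metrics, "port_id", "metrics")
    idx <- match(igraph::V(g)$name, metrics$port_id)
    for (col in setdiff(names(metrics), "port_id")) {
      g <- igraph::set_vertex_attr(g, col, value = metrics[[col]][idx])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read trips / port registries from CSV
#'
#' `read_trips()` expects columns `source,dest[,count][,year]`;
#' `read_port_registry()` expects `port_id,name,lat,lon,country[,region]`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_trips <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("source", "dest"), "trips file")
  df
}

#' @rdname read_trips
#' @export
read_port_registry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_registry(df)
}
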