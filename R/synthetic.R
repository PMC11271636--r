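#' Configuration for a synthetic shipping world
#'
#' The generator emulates the statistical structure of the global shipping
#' system that the flow models assume: heavy-tailed port "masses",
#' origin-destination trip counts following a gravity law (flows proportional
#' to the product of masses and decaying with a power of distance, realised as
#' Poisson counts), country/region structure with at most 17 regions,
#' bilateral trade volumes correlated with inter-country flows and exactly
#' zero within a country, and latitudinally graded temperature/salinity
#' fields.
#'
#' @param n_ports Number of ports (>= 2). Default 150.
#' @param n_countries Number of countries. Default 30.
#' @param n_regions Number of geographic regions (<= 17). Default 12.
#' @param gamma Gravity distance-decay exponent (> 0). Default 2.
#' @param kappa Gravity flux scale; expected flow is
#'   `kappa * m_i * m_j / d_ij^gamma` with distance in km. Default 5e6.
#' @param mass_sdlog Log-sd of the log-normal port masses. Default 1.
#' @param temp_noise_sd Noise sd (deg C) around the latitudinal temperature
#'   gradient. Default 2.
#' @param trade_scale USD per expected inter-country trip. Default 1e6.
#' @param trade_noise_sdlog Log-sd of multiplicative trade noise. Default 0.5.
#' @param trade_symmetric Make trade symmetric across the pair. Default FALSE
#'   (directional).
#' @param detour_factor Sea-route distance = haversine x this factor (plus
#'   noise), matching the routing fallback. Default 1.15.
#' @param detour_noise_sd Sd of the multiplicative detour noise. Default 0.03.
#' @param seed Integer seed controlling every draw. Default 1.
#' @return A `world_config` list.
#' @export
world_config <- function(n_ports = 150, n_countries = 30, n_regions = 12,
                         gamma = 2, kappa = 5e6, mass_sdlog = 1,
                         temp_noise_sd = 2, trade_scale = 1e6,
                         trade_noise_sdlog = 0.5, trade_symmetric = FALSE,
                         detour_factor = 1.15, detour_noise_sd = 0.03,
                         seed = 1) {
  if (n_ports < 2) stop_shipflow("n_ports must be at least 2")
  if (n_regions > 17) stop_shipflow("n_regions must be at most 17")
  if (gamma <= 0) stop_shipflow("gamma must be positive")
  if (kappa < 0) stop_shipflow("kappa must be non-negative")
  structure(
    list(
      n_ports = as.integer(n_ports), n_countries = as.integer(n_countries),
      n_regions = as.integer(n_regions), gamma = gamma, kappa = kappa,
      mass_sdlog = mass_sdlog, temp_noise_sd = temp_noise_sd,
      trade_scale = trade_scale, trade_noise_sdlog = trade_noise_sdlog,
      trade_symmetric = trade_symmetric, detour_factor = detour_factor,
      detour_noise_sd = detour_noise_sd, seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

#' Generate the ports, countries, regions and environmental fields
#'
#' Port locations are sampled area-uniformly on the sphere within latitudes
#' \[-60, 60\] (shipping avoids the poles), clustered around country centres;
#' countries are grouped into regions by clustering their centres on the unit
#' sphere. Port masses are log-normal (heavy-tailed fluxes). Annual mean
#' temperature decreases with absolute latitude plus noise; annual min/max
#' bracket it by construction; salinity varies mildly around oceanic values.
#'
#' @param cfg A [world_config()].
#' @return A `synthetic_world` list with `ports` (a registry tibble:
#'   `port_id`, `name`, `lat`, `lon`, `country`, `region`), `masses`,
#'   `country_regions`, `env` (per-port `t_min`, `t_max`, `t_annual`,
#'   `s_annual`) and `cfg`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  withr::with_seed(derive_seed(cfg$seed, 1), {
    n <- cfg$n_ports
    nc <- cfg$n_countries

    # country centres, area-uniform within the latitude band
    smax <- sin(60 * pi / 180)
    c_lat <- asin(runif(nc, -smax, smax)) * 180 / pi
    c_lon <- runif(nc, -180 + 1e-9, 180)

    # regions partition countries by clustering centres on the unit sphere
    xyz <- cbind(
      cos(c_lat * pi / 180) * cos(c_lon * pi / 180),
      cos(c_lat * pi / 180) * sin(c_lon * pi / 180),
      sin(c_lat * pi / 180)
    )
    k <- min(cfg$n_regions, nc)
    km <- stats::kmeans(xyz, centers = k, nstart = 10, iter.max = 50)
    region_of_country <- sprintf("R%02d", km$cluster)

    country_ids <- sprintf("C%02d", seq_len(nc))
    country_regions <- tibble::tibble(
      country = country_ids, region = region_of_country
    )

    # ports clustered around their country centre
    port_country <- sample(seq_len(nc), n, replace = TRUE)
    lat <- pmin(pmax(c_lat[port_country] + rnorm(n, 0, 3), -60), 60)
    lon <- c_lon[port_country] + rnorm(n, 0, 3)
    lon <- ((lon + 180) %% 360) - 180
    lon[lon == -180] <- 180

    ports <- tibble::tibble(
      port_id = sprintf("P%03d", seq_len(n)),
      name = sprintf("Port %03d", seq_len(n)),
      lat = lat, lon = lon,
      country = country_ids[port_country],
      region = region_of_country[port_country]
    )

    masses <- rlnorm(n, meanlog = 0, sdlog = cfg$mass_sdlog)

    t_annual <- 29 - 0.45 * abs(lat) + rnorm(n, 0, cfg$temp_noise_sd)
    half_range <- 4 + abs(rnorm(n, 0, 1.5))
    env <- tibble::tibble(
      port_id = ports$port_id,
      t_min = t_annual - half_range,
      t_max = t_annual + half_range,
      t_annual = t_annual,
      s_annual = 35 - 0.03 * abs(lat) + rnorm(n, 0, 1.5)
    )

    structure(
      list(ports = ports, masses = masses, country_regions = country_regions,
           env = env, cfg = cfg),
      class = "synthetic_world"
    )
  })
}

#' Draw gravity-law trips for a synthetic world
#'
#' Expected flow between distinct ports is
#' \eqn{\lambda_{ij} = \kappa m_i m_j / d_{ij}^\gamma} (distance in km,
#' floored at 50 km so near-coincident ports do not explode); realised trips
#' are independent Poisson draws, and pairs drawing zero are non-links. This
#' deliberately produces the unstable 1-2-trip links that the screening
#' stage targets.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @return The world with `trips` (tibble `source`, `dest`, `count` for
#'   positive counts) and `lambda` (dense expected-flow matrix, ports in
#'   registry order) attached.
#' @export
generate_flows <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$cfg
  n <- nrow(world$ports)
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(world$ports$lat[i], world$ports$lon[i],
                 world$ports$lat[j], world$ports$lon[j])
  })
  D <- pmax(D, 50)
  lambda <- cfg$kappa * outer(world$masses, world$masses) / D^cfg$gamma
  diag(lambda) <- 0
  withr::with_seed(derive_seed(cfg$seed, 2), {
    counts <- matrix(rpois(n * n, lambda), n, n)
  })
  diag(counts) <- 0L
  idx <- which(counts > 0, arr.ind = TRUE)
  world$trips <- tibble::tibble(
    source = world$ports$port_id[idx[, 1]],
    dest = world$ports$port_id[idx[, 2]],
    count = counts[idx]
  ) |> dplyr::arrange(.data$source, .data$dest)
  world$lambda <- lambda
  world
}

#' Derive a bilateral trade table from the world's expected flows
#'
#' Country-pair USD volume is the aggregated inter-country expected flow
#' scaled to dollars with multiplicative log-normal noise; intra-country
#' entries are exactly zero (domestic shipping carries no bilateral trade).
#'
#' @param world A `synthetic_world` with flows generated.
#' @return The world with `trade` attached (tibble `exporter`, `importer`,
#'   `usd`, all ordered country pairs).
#' @export
generate_trade <- function(world) {
  stopifnot(inherits(world, "synthetic_world"), !is.null(world$lambda))
  cfg <- world$cfg
  cty <- world$ports$country
  countries <- sort(unique(cty))
  agg <- rowsum(t(rowsum(world$lambda, cty)), cty) # country x country flows
  agg <- agg[countries, countries, drop = FALSE]
  pairs <- tidyr::expand_grid(exporter = countries, importer = countries)
  withr::with_seed(derive_seed(cfg$seed, 3), {
    noise <- rlnorm(nrow(pairs), 0, cfg$trade_noise_sdlog)
  })
  flow <- agg[cbind(match(pairs$exporter, countries),
                    match(pairs$importer, countries))]
  usd <- cfg$trade_scale * flow * noise
  if (cfg$trade_symmetric) {
    m <- matrix(usd, length(countries), length(countries), byrow = FALSE)
    m <- (m + t(m)) / 2
    usd <- as.vector(m)
  }
  usd[pairs$exporter == pairs$importer] <- 0
  world$trade <- dplyr::mutate(pairs, usd = usd)
  world
}

#' Generate a complete synthetic shipping world
#'
#' Convenience wrapper: [generate_world()] then [generate_flows()] then
#' [generate_trade()].
#'
#' @param cfg A [world_config()].
#' @return A `synthetic_world` with ports, env, trips, lambda and trade.
#' @export
generate_synthetic_world <- function(cfg = world_config()) {
  generate_trade(generate_flows(generate_world(cfg)))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d ports, %d countries, %d regions%s\n",
    nrow(x$ports), nrow(x$country_regions),
    length(unique(x$country_regions$region)),
    if (!is.null(x$trips)) sprintf(", %d trips on %d links",
                                   sum(x$trips$count), nrow(x$trips)) else ""
  ))
  invisible(x)
}

#' Write the four input tables of a world to CSV
#'
#' Writes `ports.csv`, `trips.csv`, `trade.csv`, `env.csv` and a
#' `ground_truth.json` (link set and expected-flow summaries) to `dir`.
#'
#' @param world A complete `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world_csvs <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"), !is.null(world$trips))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(world$ports, file.path(dir, "ports.csv"))
  readr::write_csv(world$trips, file.path(dir, "trips.csv"))
  readr::write_csv(world$trade, file.path(dir, "trade.csv"))
  readr::write_csv(world$env, file.path(dir, "env.csv"))
  gt <- list(
    n_ports = nrow(world$ports),
    n_links = nrow(world$trips),
    n_trips = sum(world$trips$count),
    links = paste(world$trips$source, world$trips$dest, sep = ">")
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
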