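#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. Input
#' tables come either from a synthetic world (`world` parameters) or from
#' four CSV paths (`inputs`). The single global `seed` fans out to per-stage
#' seeds by fixed offsets so stages are individually reproducible.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param world `NULL` or a list of [world_config()] arguments.
#' @param inputs `NULL` or a list with paths `ports`, `trips`, `trade`,
#'   `env`.
#' @param screen List of [screen_config()] arguments.
#' @param model List with `type` (`"transformer"` or `"deepgravity"`) and
#'   spec arguments (e.g. `encoder_layers`, `layers`).
#' @param train List of [train_config()] arguments.
#' @param bwra List with `bins` (default 50) and `standardize` (default
#'   FALSE).
#' @param seed Global integer seed. Default 1.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, world = NULL, inputs = NULL,
                            screen = list(), model = list(type = "transformer"),
                            train = list(), bwra = list(), seed = 1) {
  if (is.null(world) == is.null(inputs)) {
    stop_shipflow("exactly one of `world` and `inputs` must be given")
  }
  if (!is.null(inputs)) {
    need <- c("ports", "trips", "trade", "env")
    assert_columns(as.list(inputs), need, "inputs")
  }
  known_model <- c("type", "encoder_layers", "layers", "embed_dim", "heads",
                   "ffn_dim", "dropout")
  unknown <- setdiff(names(model), known_model)
  if (length(unknown) > 0) {
    stop_shipflow(paste("unknown model field(s):",
                        paste(unknown, collapse = ", ")))
  }
  model$type <- match.arg(model$type %||% "transformer",
                          c("transformer", "deepgravity"))
  structure(
    list(out_dir = out_dir, world = world, inputs = inputs, screen = screen,
         model = model, train = train,
         bwra = modifyList(list(bins = 50, standardize = FALSE), bwra),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load / save a pipeline configuration
#'
#' YAML or JSON, decided by the file extension. Unknown top-level keys are
#' rejected by name; omitted keys take their defaults. `load(save(cfg))`
#' round-trips.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config` (`load`); `path` invisibly (`save`).
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("out_dir", "world", "inputs", "screen", "model", "train",
             "bwra", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_shipflow(paste("unknown config key(s):",
                        paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$out_dir)) stop_shipflow("config must set out_dir")
  do.call(pipeline_config, raw)
}

#' @rdname load_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
save_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the forecasting pipeline end to end
#'
#' Stages, in order: load (or synthesise) the four input tables; build the
#' network and compute node metrics; fully connect and screen links;
#' assemble the gravity samples; train and evaluate the flow model; compute
#' the ballast-water risk distributions for observed and predicted flows.
#' Every artifact is written under `cfg$out_dir` and recorded in a manifest
#' with an MD5 content hash. A stage failure halts the run with the stage
#' name; the partial manifest is still written.
#'
#' @param cfg A `pipeline_config`.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  record <- function(stage, files, info = list()) {
    hashes <- as.list(tools::md5sum(files))
    manifest$stages[[stage]] <<- list(
      outputs = lapply(seq_along(files), function(i) {
        list(path = files[i], md5 = unname(hashes[[i]]))
      }),
      info = info
    )
  }
  fail <- function(stage, e) {
    manifest$error <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop_shipflow(sprintf("pipeline failed at stage '%s': %s", stage,
                          conditionMessage(e)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # -- stage 1: inputs -------------------------------------------------------
  tables <- run_stage("load_inputs", {
    if (!is.null(cfg$world)) {
      wc <- do.call(world_config,
                    modifyList(cfg$world, list(seed = cfg$seed)))
      world <- generate_synthetic_world(wc)
      list(ports = world$ports, trips = world$trips, trade = world$trade,
           env = world$env, world = world)
    } else {
      list(
        ports = read_port_registry(cfg$inputs$ports),
        trips = read_trips(cfg$inputs$trips),
        trade = readr::read_csv(cfg$inputs$trade, show_col_types = FALSE),
        env = readr::read_csv(cfg$inputs$env, show_col_types = FALSE),
        world = NULL
      )
    }
  })
  f <- file.path(cfg$out_dir, c("ports.csv", "trips.csv", "trade.csv",
                                "env.csv"))
  run_stage("load_inputs", {
    readr::write_csv(tables$ports, f[1])
    readr::write_csv(tables$trips, f[2])
    readr::write_csv(tables$trade, f[3])
    readr::write_csv(tables$env, f[4])
  })
  record("load_inputs", f,
         list(n_ports = nrow(tables$ports), n_trip_rows = nrow(tables$trips)))

  # -- stage 2: network + metrics -------------------------------------------
  st2 <- run_stage("network_metrics", {
    net <- build_network(tables$trips, tables$ports)
    metrics <- node_metrics(net)
    comp <- network_components(net)
    mpath <- file.path(cfg$out_dir, "node_metrics.csv")
    gpath <- file.path(cfg$out_dir, "network.graphml")
    readr::write_csv(metrics, mpath)
    write_network_graphml(net, gpath, metrics)
    list(net = net, metrics = metrics, comp = comp, files = c(mpath, gpath))
  })
  record("network_metrics", st2$files,
         list(n_edges = nrow(st2$net$edges), n_weak = st2$comp$n_weak,
              n_strong = st2$comp$n_strong))

  # -- stage 3: link screening ----------------------------------------------
  st3 <- run_stage("screen_links", {
    scfg <- do.call(screen_config,
                    modifyList(cfg$screen,
                               list(seed = derive_seed(cfg$seed, 3))))
    full <- fully_connect(st2$net)
    rows <- edge_feature_rows(full)
    balanced <- sample_pseudo_links(rows, seed = scfg$seed)
    screen <- train_link_classifier(balanced, scfg)
    retained <- screen_links(full, screen)
    rpath <- file.path(cfg$out_dir, "retained_links.csv")
    apath <- file.path(cfg$out_dir, "screen_report.csv")
    readr::write_csv(retained, rpath)
    readr::write_csv(screen$report, apath)
    list(retained = retained, screen = screen, files = c(rpath, apath))
  })
  record("screen_links", st3$files,
         list(n_retained = nrow(st3$retained),
              selected = st3$screen$selected))

  # -- stage 4: features -----------------------------------------------------
  st4 <- run_stage("featurize", {
    mapping <- if (all(!is.na(tables$ports$region))) {
      dplyr::distinct(tables$ports[, c("country", "region")])
    } else {
      default_region_mapping()
    }
    regions <- encode_regions(tables$ports, mapping)
    samples <- assemble_samples(st2$net, st2$metrics, regions, tables$trade,
                                retained_links = st3$retained)
    spath <- file.path(cfg$out_dir, "samples.jsonl")
    write_samples_jsonl(samples, spath)
    list(regions = regions, samples = samples, files = spath)
  })
  record("featurize", st4$files,
         list(n_samples = length(unique(st4$samples$source)),
              n_rows = nrow(st4$samples)))

  # -- stage 5: train + evaluate --------------------------------------------
  st5 <- run_stage("train_evaluate", {
    tcfg <- do.call(train_config,
                    modifyList(cfg$train,
                               list(seed = derive_seed(cfg$seed, 5))))
    spec <- if (cfg$model$type == "transformer") {
      do.call(transformer_gravity_spec,
              cfg$model[intersect(names(cfg$model),
                                  c("encoder_layers", "embed_dim", "heads",
                                    "ffn_dim", "dropout"))])
    } else {
      do.call(deep_gravity_spec,
              cfg$model[intersect(names(cfg$model), "layers")])
    }
    fit <- train_gravity(spec, st4$samples, tcfg)
    pred <- predict(fit, st4$samples)
    ppath <- file.path(cfg$out_dir, "predictions.csv")
    epath <- file.path(cfg$out_dir, "evaluation.json")
    readr::write_csv(pred[, c("source", "region", "y_hat", "y")], ppath)
    jsonlite::write_json(
      list(model = cfg$model$type, params = count_params(spec),
           best_epoch = fit$best_epoch, val_cpc = fit$val_cpc,
           val_metrics = fit$val_metrics,
           uniform_baseline_cpc = uniform_baseline_cpc(
             st4$samples[st4$samples$source %in% fit$val_sources, ])),
      epath, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    list(fit = fit, pred = pred, files = c(ppath, epath))
  })
  record("train_evaluate", st5$files,
         list(val_cpc = st5$fit$val_cpc, best_epoch = st5$fit$best_epoch))

  # -- stage 6: ballast-water risk ------------------------------------------
  st6 <- run_stage("bwra", {
    obs <- dplyr::transmute(st2$net$edges[!st2$net$edges$pseudo, ],
                            source = .data$source, dest = .data$dest,
                            weight = .data$weight)
    pred_port <- downscale_predictions(st5$pred, st4$regions, obs)
    truth_dist <- weight_distribution(obs, tables$env, bins = cfg$bwra$bins,
                                      standardize = cfg$bwra$standardize)
    pred_dist <- weight_distribution(pred_port, tables$env,
                                     breaks = truth_dist$breaks,
                                     standardize = cfg$bwra$standardize)
    cmp <- compare_distributions(pred_dist, truth_dist)
    bpath <- file.path(cfg$out_dir, "risk_pairs.csv")
    jpath <- file.path(cfg$out_dir, "risk_summary.json")
    readr::write_csv(pred_dist$pairs, bpath)
    jsonlite::write_json(
      list(correlation = cmp$correlation,
           total_variation = cmp$total_variation,
           total_weight_pred = pred_dist$total_weight,
           total_weight_true = truth_dist$total_weight),
      jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    list(cmp = cmp, files = c(bpath, jpath))
  })
  record("bwra", st6$files, st6$cmp[c("correlation", "total_variation")])

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Region-level predicted flows -> port-pair flows: each source's predicted
# flow into a region is split across its observed destination ports in that
# region proportionally to observed shares (uniform across the region's
# ports when the source has no observed destination there).
downscale_predictions <- function(pred, regions, obs) {
  port_region <- setNames(regions$ports$region, regions$ports$port_id)
  obs$region <- port_region[obs$dest]
  out <- list()
  for (r in seq_len(nrow(pred))) {
    src <- pred$source[r]
    reg <- pred$region[r]
    members <- obs[obs$source == src & obs$region == reg, ]
    if (nrow(members) > 0) {
      share <- members$weight / sum(members$weight)
      out[[r]] <- tibble::tibble(source = src, dest = members$dest,
                                 weight = pred$y_hat[r] * share)
    } else {
      ports_in <- regions$ports$port_id[regions$ports$region == reg]
      ports_in <- setdiff(ports_in, src)
      if (length(ports_in) == 0) next
      out[[r]] <- tibble::tibble(source = src, dest = ports_in,
                                 weight = pred$y_hat[r] / length(ports_in))
    }
  }
  dplyr::bind_rows(out)
}
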