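#' Edge importance on the fully connected network
#'
#' Combines the min-max normalised flow size with the min-max normalised
#' great-circle distance: \eqn{I_{ij} = \hat w_{ij} / (\hat d_{ij} +
#' \epsilon)}. High-flow, short links score highest; pseudo edges enter with
#' their pseudo weight. Normalisation statistics are taken over all edges of
#' the augmented graph.
#'
#' @param net An augmented `shipping_network` (see [fully_connect()]).
#' @param eps Small constant preventing division by zero. Default 1e-6.
#' @return A tibble `source`, `dest`, `edge_importance`.
#' @export
edge_importance <- function(net, eps = 1e-6) {
  stopifnot(inherits(net, "shipping_network"))
  if (!net$augmented) {
    stop_shipflow("edge_importance requires a fully connected network")
  }
  w_hat <- minmax_or_zero(net$edges$weight, "edge weights")
  d_hat <- minmax_or_zero(edge_lengths_km(net), "edge distances")
  tibble::tibble(
    source = net$edges$source,
    dest = net$edges$dest,
    edge_importance = w_hat / (d_hat + eps)
  )
}

minmax_or_zero <- function(x, what) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warn(sprintf("%s are all equal; normalised values set to 0", what))
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Per-edge feature rows for link screening
#'
#' One row per ordered pair of the augmented network, carrying the haversine
#' distance, the sea-route distance (via [searoute_km()]), the edge
#' importance, the source port's region, and the class label: `real` for
#' observed links, `pseudo` for the added ones.
#'
#' @inheritParams edge_importance
#' @param provider Optional sea-route provider passed to [searoute_km()].
#' @param detour_factor Fallback detour multiplier. Default 1.15.
#' @return A tibble `source`, `dest`, `d_haversine`, `d_searoute`,
#'   `edge_importance`, `source_region`, `label`.
#' @export
edge_feature_rows <- function(net, provider = NULL, detour_factor = 1.15,
                              eps = 1e-6) {
  imp <- edge_importance(net, eps)
  i <- match(net$edges$source, net$ports$port_id)
  j <- match(net$edges$dest, net$ports$port_id)
  d <- searoute_km(net$ports$lat[i], net$ports$lon[i],
                   net$ports$lat[j], net$ports$lon[j],
                   provider = provider, detour_factor = detour_factor)
  tibble::tibble(
    source = net$edges$source,
    dest = net$edges$dest,
    d_haversine = d$d_haversine,
    d_searoute = d$d_searoute,
    edge_importance = imp$edge_importance,
    source_region = net$ports$region[i],
    label = factor(ifelse(net$edges$pseudo, "pseudo", "real"),
                   levels = c("real", "pseudo"))
  )
}

#' A deterministic synthetic sea-route provider
#'
#' Returns a provider function for [searoute_km()] that inflates the
#' haversine distance by the detour factor times pair-specific multiplicative
#' noise. The noise is a deterministic hash of the coordinates, so the
#' provider is reproducible without touching the RNG stream. This is a
#' synthetic stand-in for a routing database, useful for tests and worlds.
#'
#' @param detour_factor Mean detour multiplier. Default 1.15.
#' @param noise_sd Relative amplitude of the pair noise. Default 0.03.
#' @return A function `f(lat1, lon1, lat2, lon2)` returning km.
#' @export
synthetic_route_provider <- function(detour_factor = 1.15, noise_sd = 0.03) {
  force(detour_factor); force(noise_sd)
  function(lat1, lon1, lat2, lon2) {
    d <- haversine_km(lat1, lon1, lat2, lon2)
    u <- sin(lat1 * 12.9898 + lon1 * 78.233 + lat2 * 37.719 + lon2 * 4.581)
    d * pmax(detour_factor * (1 + noise_sd * u), 1)
  }
}

#' Balance real and pseudo links by stratified sampling
#'
#' Keeps every real row and draws an equal number of pseudo rows without
#' replacement, allocated across strata (haversine-distance decile x source
#' region) proportionally to stratum size, so the sampled negatives preserve
#' the spatial distribution of the pseudo links. Strata short of rows borrow
#' from the nearest distance decile (reported via a message).
#'
#' @param rows Feature rows from [edge_feature_rows()] (both classes
#'   present).
#' @param seed Integer seed; the selection is deterministic given it.
#' @return The balanced tibble of rows (all real + sampled pseudo).
#' @export
sample_pseudo_links <- function(rows, seed = 1) {
  assert_columns(rows, c("d_haversine", "label"), "rows")
  real <- dplyr::filter(rows, .data$label == "real")
  pseudo <- dplyr::filter(rows, .data$label == "pseudo")
  if (nrow(real) == 0 || nrow(pseudo) == 0) {
    stop_shipflow("both real and pseudo links are required")
  }
  n_take <- nrow(real)
  if (nrow(pseudo) <= n_take) {
    warn("fewer pseudo than real links; keeping all pseudo rows")
    return(dplyr::bind_rows(real, pseudo))
  }

  brk <- unique(quantile(pseudo$d_haversine, probs = seq(0, 1, 0.1)))
  decile <- cut(pseudo$d_haversine, breaks = brk, include.lowest = TRUE,
                labels = FALSE)
  region <- if ("source_region" %in% names(rows)) {
    as.character(pseudo$source_region)
  } else {
    rep("all", nrow(pseudo))
  }
  region[is.na(region)] <- "unknown"
  stratum <- paste(decile, region, sep = "|")

  sizes <- table(stratum)
  # largest-remainder proportional allocation summing exactly to n_take
  exact <- n_take * as.numeric(sizes) / nrow(pseudo)
  alloc <- floor(exact)
  shortfall <- n_take - sum(alloc)
  if (shortfall > 0) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(shortfall)]
    alloc[extra] <- alloc[extra] + 1
  }
  names(alloc) <- names(sizes)

  withr::with_seed(as.integer(seed), {
    picked <- integer(0)
    borrowed <- 0L
    for (s in names(alloc)) {
      want <- alloc[[s]]
      if (want == 0) next
      in_s <- which(stratum == s)
      if (length(in_s) >= want) {
        picked <- c(picked, sample(in_s, want))
      } else {
        picked <- c(picked, in_s)
        need <- want - length(in_s)
        borrowed <- borrowed + need
        dec <- as.integer(sub("\\|.*", "", s))
        pool <- setdiff(order(abs(decile - dec)), c(picked, in_s))
        picked <- c(picked, pool[seq_len(need)])
      }
    }
    if (borrowed > 0) {
      inform(sprintf("borrowed %d pseudo row(s) from neighbouring deciles",
                     borrowed))
    }
  })
  dplyr::bind_rows(real, pseudo[sort(unique(picked)), ])
}

#' Screening configuration
#'
#' @param classifier_menu Subset of `c("logistic", "kneighbors",
#'   "decision_tree", "xgboost", "random_forest")`.
#' @param use_edge_importance Include the edge-importance feature (3
#'   features) or distances only (2 features). Default TRUE.
#' @param train_fraction Fraction of balanced rows used for training (the
#'   rest validates). Default 0.75.
#' @param cv_folds Grid-search cross-validation folds. Default 5.
#' @param selected Which menu model becomes the deployed filter. Default
#'   `"logistic"`: it deliberately prunes unstable 1-2-trip links.
#' @param seed Integer seed. Default 1.
#' @return A `screen_config` list.
#' @export
screen_config <- function(classifier_menu = c("logistic", "kneighbors",
                                              "decision_tree", "xgboost",
                                              "random_forest"),
                          use_edge_importance = TRUE,
                          train_fraction = 0.75, cv_folds = 5,
                          selected = "logistic", seed = 1) {
  menu <- match.arg(classifier_menu, several.ok = TRUE,
                    choices = c("logistic", "kneighbors", "decision_tree",
                                "xgboost", "random_forest"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_shipflow("train_fraction must be in (0, 1)")
  }
  if (cv_folds < 2) stop_shipflow("cv_folds must be at least 2")
  if (!selected %in% menu) selected <- menu[1]
  structure(
    list(classifier_menu = menu, use_edge_importance = use_edge_importance,
         train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
         selected = selected, seed = as.integer(seed)),
    class = "screen_config"
  )
}

# Fixed, versioned grid-search spaces. Tie-break: first listed parameter set
# at equal mean CV accuracy.
screen_grids <- function() {
  list(
    logistic = list(list()),
    kneighbors = list(list(k = 3), list(k = 5), list(k = 9)),
    decision_tree = list(list(cp = 0.001), list(cp = 0.01)),
    xgboost = list(list(max_depth = 2, nrounds = 60),
                   list(max_depth = 4, nrounds = 60)),
    random_forest = list(list(mtry = 1, ntree = 200),
                         list(mtry = 2, ntree = 200))
  )
}

fit_screen_model <- function(model, params, x, y, seed) {
  scaler <- list(center = colMeans(x), scale = apply(x, 2, sd))
  scaler$scale[scaler$scale == 0] <- 1
  xs <- scale(x, scaler$center, scaler$scale)
  withr::with_seed(as.integer(seed), {
    fit <- switch(model,
      logistic = {
        df <- as.data.frame(xs); df$.y <- y
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      kneighbors = caret::knn3(xs, y, k = params$k),
      decision_tree = {
        df <- as.data.frame(xs); df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = params$cp))
      },
      xgboost = xgboost::xgboost(
        xs, y, nrounds = params$nrounds, max_depth = params$max_depth,
        learning_rate = 0.3, nthreads = 1, verbosity = 0
      ),
      random_forest = randomForest::randomForest(
        xs, y, ntree = params$ntree, mtry = params$mtry
      ),
      stop_shipflow(paste("unknown model:", model))
    )
  })
  structure(list(model = model, params = params, fit = fit, scaler = scaler,
                 features = colnames(x)),
            class = "screen_model")
}

#' @export
predict.screen_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, object$scaler$center, object$scaler$scale)
  lev <- c("real", "pseudo")
  # distance/vote ties (knn) are broken via the RNG; pin it for determinism
  out <- withr::with_seed(1L, switch(object$model,
    logistic = {
      df <- as.data.frame(xs)
      p <- stats::predict(object$fit, newdata = df, type = "response")
      lev[(p > 0.5) + 1] # glm models P(second level) = P(pseudo)
    },
    kneighbors = as.character(stats::predict(object$fit, xs, type = "class")),
    decision_tree = {
      df <- as.data.frame(xs)
      as.character(stats::predict(object$fit, df, type = "class"))
    },
    xgboost = as.character(stats::predict(object$fit, xs, type = "class")),
    random_forest = as.character(stats::predict(object$fit, xs))
  ))
  factor(out, levels = lev)
}

#' Train the link-prediction classifier menu
#'
#' Treats "does this ordered port pair carry real traffic?" as binary
#' classification. Each menu model is grid-searched with k-fold
#' cross-validation on the training fraction of the balanced rows, refit on
#' the whole training fraction with its best parameters, and scored on the
#' held-out validation fraction (and on `test_rows` when given).
#'
#' @param rows Balanced feature rows (see [sample_pseudo_links()]).
#' @param cfg A [screen_config()].
#' @param test_rows Optional held-out rows for test accuracy.
#' @return A `link_screen` object: fitted models, an accuracy `report`
#'   tibble, the selected filter model name, and the config.
#' @export
train_link_classifier <- function(rows, cfg = screen_config(),
                                  test_rows = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  feats <- c("d_haversine", "d_searoute",
             if (cfg$use_edge_importance) "edge_importance")
  assert_columns(rows, c(feats, "label"), "rows")
  y <- factor(rows$label, levels = c("real", "pseudo"))
  if (length(unique(y)) < 2) {
    stop_shipflow("training rows contain a single class")
  }
  x <- as.matrix(rows[, feats, drop = FALSE])

  # stratified train/validation split
  withr::with_seed(derive_seed(cfg$seed, 11), {
    tr <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(length(idx) * cfg$train_fraction))
    }), use.names = FALSE)
  })
  tr <- sort(tr)
  va <- setdiff(seq_along(y), tr)

  withr::with_seed(derive_seed(cfg$seed, 12), {
    fold <- sample(rep_len(seq_len(cfg$cv_folds), length(tr)))
  })

  grids <- screen_grids()
  models <- list()
  report <- list()
  for (m in cfg$classifier_menu) {
    cv_acc <- vapply(grids[[m]], function(params) {
      accs <- vapply(seq_len(cfg$cv_folds), function(f) {
        in_f <- tr[fold == f]
        out_f <- tr[fold != f]
        fit <- fit_screen_model(m, params, x[out_f, , drop = FALSE], y[out_f],
                                derive_seed(cfg$seed, 100 + f))
        mean(predict(fit, rows[in_f, , drop = FALSE]) == y[in_f])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- which.max(cv_acc) # which.max takes the first at ties
    fit <- fit_screen_model(m, grids[[m]][[best]], x[tr, , drop = FALSE],
                            y[tr], derive_seed(cfg$seed, 200))
    val_acc <- mean(predict(fit, rows[va, , drop = FALSE]) == y[va])
    test_acc <- NA_real_
    if (!is.null(test_rows)) {
      yt <- factor(test_rows$label, levels = c("real", "pseudo"))
      test_acc <- mean(predict(fit, test_rows) == yt)
    }
    models[[m]] <- fit
    report[[m]] <- tibble::tibble(
      model = m,
      best_params = paste(names(grids[[m]][[best]]),
                          unlist(grids[[m]][[best]]) %||% "",
                          sep = "=", collapse = ","),
      cv_accuracy = cv_acc[best],
      val_accuracy = val_acc,
      test_accuracy = test_acc
    )
  }
  structure(
    list(models = models, report = dplyr::bind_rows(report),
         selected = cfg$selected, cfg = cfg, features = feats),
    class = "link_screen"
  )
}

#' @export
print.link_screen <- function(x, ...) {
  cat(sprintf("<link_screen> selected filter: %s\n", x$selected))
  print(x$report)
  invisible(x)
}

#' Screen the fully connected network for probable links
#'
#' Scores every ordered pair of the augmented network with the screen's
#' selected classifier and returns the pairs classified as real. Low-count
#' links (1-2 trips) may be dropped by design: the filter exists to prune
#' them.
#'
#' @param net An augmented `shipping_network`.
#' @param screen A fitted `link_screen` (or a single `screen_model`).
#' @param provider,detour_factor Passed to [edge_feature_rows()].
#' @return A tibble `source`, `dest` of retained pairs.
#' @export
screen_links <- function(net, screen, provider = NULL, detour_factor = 1.15) {
  rows <- edge_feature_rows(net, provider = provider,
                            detour_factor = detour_factor)
  model <- if (inherits(screen, "link_screen")) {
    screen$models[[screen$selected]]
  } else {
    screen
  }
  stopifnot(inherits(model, "screen_model"))
  keep <- predict(model, rows) == "real"
  rows[keep, c("source", "dest")]
}
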