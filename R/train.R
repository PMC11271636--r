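#' Training configuration for gravity models
#'
#' Per-sample (batch size 1) Adam steps on the cross-entropy flow loss with
#' L2 weight penalty; after each epoch the mean CPC on the validation
#' samples is computed, the learning rate is cut by `lr_reduce_factor` after
#' `lr_patience` epochs without improvement, training stops after
#' `early_stop_patience` stagnant epochs, and the best-CPC checkpoint is
#' returned.
#'
#' @param lr Initial Adam learning rate. Default 1e-3.
#' @param weight_decay L2 penalty coefficient. Default 1e-5.
#' @param lr_reduce_factor Multiplier applied on plateau. Default 0.1.
#' @param lr_patience Stagnant epochs before an LR cut. Default 10.
#' @param early_stop_patience Stagnant epochs before stopping. Default 20.
#' @param max_epochs Epoch budget. Default 200.
#' @param val_fraction Fraction of source ports held out for validation when
#'   no explicit split is given. Default 0.25.
#' @param cv_folds Folds for [cross_validate_gravity()]. Default 5.
#' @param seed Integer seed (fold assignment, initialisation, shuffling,
#'   dropout). Default 1.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-5,
                         lr_reduce_factor = 0.1, lr_patience = 10,
                         early_stop_patience = 20, max_epochs = 200,
                         val_fraction = 0.25, cv_folds = 5, seed = 1) {
  stopifnot(lr > 0, lr_patience > 0, early_stop_patience > 0, max_epochs >= 1)
  structure(
    list(lr = lr, weight_decay = weight_decay,
         lr_reduce_factor = lr_reduce_factor, lr_patience = lr_patience,
         early_stop_patience = early_stop_patience,
         max_epochs = as.integer(max_epochs), val_fraction = val_fraction,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "train_config"
  )
}

# samples tibble -> list of per-source sample objects (X, O, y, regions)
samples_to_list <- function(samples) {
  feats <- od_feature_cols()
  assert_columns(samples, c("source", "region", feats, "O_i", "y"), "samples")
  lapply(split(samples, samples$source), function(d) {
    list(source = d$source[1], regions = d$region,
         X = as.matrix(d[, feats]), O = d$O_i[1], y = d$y)
  })
}

#' Train a gravity flow model
#'
#' Splits the source ports into training and validation sets, fits the
#' feature scaler on the training split only, then optimises the model with
#' per-sample Adam steps under the schedule in `cfg` (see [train_config()]).
#' Model selection is by validation mean CPC.
#'
#' @param spec A [transformer_gravity_spec()] or [deep_gravity_spec()].
#' @param samples A samples tibble from [assemble_samples()] (unscaled).
#' @param cfg A [train_config()].
#' @param val_sources Optional character vector of source ports to use as
#'   the validation split (overrides `val_fraction`).
#' @return A `gravity_fit`: best-checkpoint `model`, scaler `stats`,
#'   training `history` tibble (epoch, train_loss, val_cpc, lr), validation
#'   metrics, split membership and configs.
#' @export
train_gravity <- function(spec, samples, cfg = train_config(),
                          val_sources = NULL) {
  stopifnot(inherits(spec, "gravity_spec"), inherits(cfg, "train_config"))
  sources <- unique(samples$source)
  if (length(sources) < 2) stop_shipflow("need at least 2 source samples")
  if (is.null(val_sources)) {
    withr::with_seed(derive_seed(cfg$seed, 21), {
      n_val <- max(1, round(length(sources) * cfg$val_fraction))
      val_sources <- sample(sources, n_val)
    })
  }
  train_sources <- setdiff(sources, val_sources)
  if (length(train_sources) == 0) stop_shipflow("empty training split")

  sc <- scale_features(samples[samples$source %in% train_sources, ])
  train_list <- samples_to_list(sc$samples)
  val_scaled <- scale_features(samples[samples$source %in% val_sources, ],
                               stats = sc$stats)$samples
  val_list <- samples_to_list(val_scaled)

  model <- init_gravity_model(spec, seed = derive_seed(cfg$seed, 22))
  opt <- adam_init(model$params)
  lr <- cfg$lr
  best <- list(params = model$params, cpc = -Inf, epoch = 0)
  stagnant <- 0
  history <- list()

  withr::with_seed(derive_seed(cfg$seed, 23), {
    for (epoch in seq_len(cfg$max_epochs)) {
      order_idx <- sample(length(train_list))
      total_loss <- 0
      for (s in train_list[order_idx]) {
        fw <- model_forward(model, s$X, train = TRUE)
        lg <- loss_and_grad_scores(fw$scores, s$y)
        if (!is.finite(lg$loss)) {
          stop_shipflow(sprintf(
            "training diverged (non-finite loss at epoch %d)", epoch))
        }
        total_loss <- total_loss + lg$loss
        grads <- model_backward(model, fw$cache, lg$dscores)
        st <- adam_step(model$params, grads, opt, lr, cfg$weight_decay)
        model$params <- st$params
        opt <- st$state
      }
      val_cpc <- mean(vapply(val_list, function(s) {
        f <- model_forward(model, s$X, train = FALSE)$scores
        cpc(allocate_flows(f, s$O), s$y)
      }, numeric(1)))
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = total_loss, val_cpc = val_cpc, lr = lr
      )
      if (val_cpc > best$cpc + 1e-12) {
        best <- list(params = model$params, cpc = val_cpc, epoch = epoch)
        stagnant <- 0
      } else {
        stagnant <- stagnant + 1
        if (stagnant >= cfg$early_stop_patience) break
        if (stagnant %% cfg$lr_patience == 0) lr <- lr * cfg$lr_reduce_factor
      }
    }
  })

  model$params <- best$params
  fit <- structure(
    list(model = model, spec = spec, stats = sc$stats,
         history = dplyr::bind_rows(history),
         best_epoch = best$epoch, val_cpc = best$cpc,
         train_sources = train_sources, val_sources = val_sources,
         cfg = cfg),
    class = "gravity_fit"
  )
  fit$val_metrics <- evaluate_gravity(fit, samples[samples$source %in%
                                                     val_sources, ])
  fit
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf(
    "<gravity_fit> %s | %s params | best epoch %d | validation CPC %.3f\n",
    class(x$spec)[1], format(count_params(x$spec), big.mark = ","),
    x$best_epoch, x$val_cpc
  ))
  invisible(x)
}

#' Predict flows for gravity samples
#'
#' @param object A `gravity_fit`.
#' @param newdata A samples tibble (unscaled; the fit's training scaler is
#'   applied).
#' @param ... Unused.
#' @return `newdata` with a `y_hat` column (predicted flows; per source they
#'   sum to `O_i`).
#' @export
predict.gravity_fit <- function(object, newdata, ...) {
  scaled <- scale_features(newdata, stats = object$stats)$samples
  lst <- samples_to_list(scaled)
  preds <- purrr::map_dfr(lst, function(s) {
    f <- model_forward(object$model, s$X, train = FALSE)$scores
    tibble::tibble(source = s$source, region = s$regions,
                   y_hat = allocate_flows(f, s$O))
  })
  dplyr::left_join(newdata, preds, by = c("source", "region"))
}

#' Evaluate a fitted gravity model
#'
#' @param fit A `gravity_fit`.
#' @param samples Samples tibble to score.
#' @param per_source Use per-source NRMSE/correlation averaging instead of
#'   pooling over all (source, region) pairs. Default FALSE (pooled).
#' @return A list with `cpc` (mean over sources), `nrmse`, `corr` and `n`.
#' @export
evaluate_gravity <- function(fit, samples, per_source = FALSE) {
  pred <- predict(fit, samples)
  by_src <- split(pred, pred$source)
  list(
    cpc = mean(vapply(by_src, function(d) cpc(d$y_hat, d$y), numeric(1))),
    nrmse = nrmse(pred$y_hat, pred$y, per_source, pred$source),
    corr = flow_corr(pred$y_hat, pred$y, per_source, pred$source),
    n = length(by_src)
  )
}

#' Cross-validate a gravity model over source ports
#'
#' Assigns source ports to `cfg$cv_folds` folds (seeded), trains on the
#' remaining folds (with an internal validation split for the schedule) and
#' scores each held-out fold; reports per-fold and aggregate CPC
#' (mean/max/min), NRMSE and correlation.
#'
#' @inheritParams train_gravity
#' @return An `evaluation_report`: tibble `folds`, aggregate list `summary`,
#'   and the parameter count.
#' @export
cross_validate_gravity <- function(spec, samples, cfg = train_config()) {
  sources <- unique(samples$source)
  k <- cfg$cv_folds
  if (length(sources) < k) stop_shipflow("fewer sources than folds")
  withr::with_seed(derive_seed(cfg$seed, 31), {
    fold <- sample(rep_len(seq_len(k), length(sources)))
  })
  names(fold) <- sources
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    held <- sources[fold == f]
    fit <- train_gravity(spec, samples[!samples$source %in% held, ], cfg)
    m <- evaluate_gravity(fit, samples[samples$source %in% held, ])
    tibble::tibble(fold = f, cpc = m$cpc, nrmse = m$nrmse, corr = m$corr,
                   n_sources = length(held))
  })
  structure(
    list(
      folds = folds,
      summary = list(
        cpc_mean = mean(folds$cpc), cpc_max = max(folds$cpc),
        cpc_min = min(folds$cpc),
        nrmse = mean(folds$nrmse, na.rm = TRUE),
        corr = mean(folds$corr, na.rm = TRUE)
      ),
      params = count_params(spec), spec = spec, cfg = cfg
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<evaluation_report> CPC %.3f [%.3f, %.3f] | NRMSE %.3f | Corr %.3f | %s params\n",
    s$cpc_mean, s$cpc_min, s$cpc_max, s$nrmse, s$corr,
    format(x$params, big.mark = ",")
  ))
  invisible(x)
}
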