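#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   labs theme_minimal facet_wrap sec_axis scale_y_continuous
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted gravity model's training history
#'
#' @param x A `gravity_fit`.
#' @param ... Unused.
#' @return The history tibble: `epoch`, `train_loss`, `val_cpc`, `lr`.
#' @method tidy gravity_fit
#' @export
tidy.gravity_fit <- function(x, ...) x$history

#' One-row summary of a fitted gravity model
#'
#' @param x A `gravity_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model class, parameter count, best epoch,
#'   validation CPC/NRMSE/correlation, split sizes.
#' @method glance gravity_fit
#' @export
glance.gravity_fit <- function(x, ...) {
  tibble::tibble(
    model = class(x$spec)[1],
    n_params = count_params(x$spec),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    val_cpc = x$val_cpc,
    val_nrmse = x$val_metrics$nrmse,
    val_corr = x$val_metrics$corr,
    n_train = length(x$train_sources),
    n_val = length(x$val_sources)
  )
}

#' Tidy a cross-validation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$folds

#' One-row summary of a cross-validation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble with CPC mean/max/min, NRMSE, correlation and
#'   parameter count.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    cpc_mean = s$cpc_mean, cpc_max = s$cpc_max, cpc_min = s$cpc_min,
    nrmse = s$nrmse, corr = s$corr, n_params = x$params
  )
}

#' Tidy a link-screen accuracy report
#'
#' @param x A `link_screen`.
#' @param ... Unused.
#' @return The per-model accuracy tibble.
#' @method tidy link_screen
#' @export
tidy.link_screen <- function(x, ...) x$report

#' Training-curve plot for a gravity fit
#'
#' Training loss and validation CPC by epoch.
#'
#' @param object A `gravity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gravity_fit
#' @export
autoplot.gravity_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_cpc"),
                           names_to = "series", values_to = "value")
  ggplot(h, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~ .data$series, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL,
         title = "Gravity model training history") +
    theme_minimal()
}

#' Risk-distribution plot
#'
#' Trip weight across environmental-distance bins; small distances mean
#' environmentally similar port pairs, i.e. higher invasion risk.
#'
#' @param object A `risk_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_distribution
#' @export
autoplot.risk_distribution <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$bin_mid, y = .data$weight)) +
    geom_col(width = diff(object$breaks)[1]) +
    labs(x = "environmental distance", y = "trip weight",
         title = "Trip-weighted environmental-distance distribution") +
    theme_minimal()
}

#' Classifier accuracy plot for a link screen
#'
#' @param object A `link_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot link_screen
#' @export
autoplot.link_screen <- function(object, ...) {
  r <- tidyr::pivot_longer(object$report,
                           dplyr::any_of(c("cv_accuracy", "val_accuracy",
                                           "test_accuracy")),
                           names_to = "split", values_to = "accuracy")
  r <- dplyr::filter(r, !is.na(.data$accuracy))
  ggplot(r, aes(x = .data$model, y = .data$accuracy, fill = .data$split)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "accuracy", title = "Link classifier accuracy") +
    theme_minimal()
}
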