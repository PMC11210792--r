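# broom-style tidiers and plot methods.

#' @exportS3Method generics::tidy
tidy.dasnet <- function(x, ...) {
  x$log
}

#' @exportS3Method generics::glance
glance.dasnet <- function(x, ...) {
  tibble(
    n_parameters = tree_n_params(x$params),
    latent_size = x$config$r,
    epochs_run = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' @exportS3Method generics::tidy
tidy.dasnet_cv <- function(x, ...) {
  x$results
}

#' @exportS3Method generics::glance
glance.dasnet_cv <- function(x, ...) {
  best <- x$summary[x$summary$draw == x$best$draw, ]
  tibble(
    n_draws = nrow(x$summary), best_draw = x$best$draw,
    best_mean_val_loss = best$mean_val_loss,
    best_sd_val_loss = best$sd_val_loss
  )
}

#' @exportS3Method generics::tidy
tidy.das_knn <- function(x, ...) {
  x$mse
}

#' @exportS3Method ggplot2::autoplot
autoplot.dasnet <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "Epoch", y = "Multi-task loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.das_attention_summary <- function(object, ...) {
  ggplot2::ggplot(object$global_by_targets,
                  ggplot2::aes(x = .data$n_targets, y = .data$mean_weight,
                               fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~score_kind) +
    ggplot2::labs(x = "Number of predicted targets",
                  y = "Mean global attention weight", fill = "Source") +
    ggplot2::theme_minimal()
}

#' Plot MSE against history length
#'
#' @param predictions A prediction tibble (see [mse_vs_history()]).
#' @param max_bin Pooling bound for long histories.
#' @return A ggplot object.
#' @export
plot_mse_vs_history <- function(predictions, max_bin = 8L) {
  df <- mse_vs_history(predictions, max_bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_prior_cms, y = .data$mse)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~score_kind, scales = "free_y") +
    ggplot2::labs(x = "Number of prior medical visits", y = "MSE") +
    ggplot2::theme_minimal()
}
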