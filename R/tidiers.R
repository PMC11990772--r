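#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

as_maybe_tibble <- function(df) {
  if (requireNamespace("tibble", quietly = TRUE)) tibble::as_tibble(df)
  else df
}

#' Tidy the training history of an integration fit
#'
#' @param x an `st_integration`.
#' @param ... unused.
#' @return one row per epoch with the loss components.
#' @export
tidy.st_integration <- function(x, ...) {
  as_maybe_tibble(x$history)
}

#' One-row summary of an integration fit
#'
#' @param x an `st_integration`.
#' @param ... unused.
#' @return a single-row data frame with dimensions and final losses.
#' @export
glance.st_integration <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  as_maybe_tibble(data.frame(
    n_slices = length(x$embeddings),
    n_spots = sum(vapply(x$embeddings, nrow, integer(1))),
    h = ncol(x$embeddings[[1]]),
    epochs = last$epoch,
    final_total = last$total,
    final_contrastive = last$contrastive,
    final_within = last$within,
    final_across = last$across,
    n_mnn_pairs = sum(vapply(x$mnn_pairs, nrow, integer(1)))))
}

#' Tidy a metric report
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return long table of metric names and values.
#' @export
tidy.metric_report <- function(x, ...) {
  keys <- setdiff(names(x), "params")
  keep <- !vapply(x[keys], is.null, logical(1))
  as_maybe_tibble(data.frame(metric = keys[keep],
                             value = unlist(x[keys][keep], use.names = FALSE)))
}

#' Plot the training loss trajectory
#'
#' @param integration an `st_integration`.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_loss_history <- function(integration) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_loss_history() needs the ggplot2 package")
  hh <- integration$history
  long <- data.frame(
    epoch = rep(hh$epoch, 3),
    component = rep(c("contrastive", "within", "across"), each = nrow(hh)),
    value = c(hh$contrastive, hh$within, hh$across))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = integration$config$stage1_epochs,
                        linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a joint embedding colored by batch or label
#'
#' Projects the stacked embeddings to their first two principal components.
#'
#' @param integration an `st_integration`.
#' @param labels optional per-spot labels (stacked in slice order); when
#'   `NULL`, points are colored by slice.
#' @return a ggplot object (requires ggplot2).
#' @export
plot_embedding <- function(integration, labels = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_embedding() needs the ggplot2 package")
  je <- joint_embedding(integration)
  pc <- stats::prcomp(je$Z, rank. = 2)$x
  df <- data.frame(PC1 = pc[, 1], PC2 = pc[, 2],
                   group = if (is.null(labels)) je$batch
                           else as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(colour = if (is.null(labels)) "slice" else "label") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
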