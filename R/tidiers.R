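# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model's training history
#'
#' @param x A `dgi_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `lr`, `loss`,
#'   `loss_reg`, `loss_cl`, `loss_ce`, `val_acc`.
#' @method tidy dgi_fit
#' @export
tidy.dgi_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `dgi_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the configuration essentials, final training
#'   loss, and the best validation accuracy and its epoch.
#' @method glance dgi_fit
#' @export
glance.dgi_fit <- function(x, ...) {
  tibble::tibble(
    embedding_dim = x$config$embedding_dim,
    num_layers = x$config$num_layers,
    aggregation = x$config$aggregation,
    epochs = nrow(x$history),
    seed = x$config$seed,
    final_loss = x$history$loss[nrow(x$history)],
    best_epoch = x$best_epoch,
    best_val_acc = x$best_val_acc
  )
}

#' Tidy a metrics report
#'
#' @param x A `dgi_metrics`.
#' @param ... Unused.
#' @return A two-column tibble of metric names and values (the five summary
#'   metrics).
#' @method tidy dgi_metrics
#' @export
tidy.dgi_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("acc", "macro_f1", "auroc", "aupr", "mcc"),
    value = c(x$acc, x$macro_f1, x$auroc, x$aupr, x$mcc)
  )
}

#' Training curves for a fitted model
#'
#' Plots the per-epoch total loss, the cross-entropy component, and the
#' validation accuracy as faceted line charts.
#'
#' @param object A `dgi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dgi_fit
#' @export
autoplot.dgi_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$loss, series = "total loss"),
    tibble::tibble(epoch = h$epoch, value = h$loss_ce, series = "cross-entropy"),
    tibble::tibble(epoch = h$epoch, value = h$val_acc, series = "validation accuracy")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Degree-distribution plot for a bipartite graph
#'
#' Log-log frequency plot of drug and gene degrees; power-law (heavy-tailed)
#' networks appear approximately linear.
#'
#' @param g A `dgi_graph`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g) {
  deg <- tibble::tibble(
    degree = c(tabulate(g$edges$drug_index, n_drugs(g)),
               tabulate(g$edges$gene_index, n_genes(g))),
    side = rep(c("drug", "gene"), c(n_drugs(g), n_genes(g)))
  )
  counts <- dplyr::count(dplyr::filter(deg, .data$degree > 0), .data$side, .data$degree)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$degree, y = .data$n, colour = .data$side)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes", colour = NULL,
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
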