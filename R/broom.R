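# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold results of a fitted model
#'
#' @param x An `msgm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fold: accuracy, macro-F1 (both %),
#'   test subjects, best epoch.
#' @method tidy msgm_fit
#' @export
tidy.msgm_fit <- function(x, ...) x$folds

#' One-row summary of a fitted model
#'
#' @param x An `msgm_fit`.
#' @param ... Unused.
#' @return Tibble: fold count, mean/SD accuracy and macro-F1 (%), trainable
#'   parameter count, ablation flag.
#' @method glance msgm_fit
#' @export
glance.msgm_fit <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    acc_mean = mean(x$folds$accuracy), acc_sd = stats::sd(x$folds$accuracy),
    f1_mean = mean(x$folds$f1), f1_sd = stats::sd(x$folds$f1),
    n_parameters = x$n_parameters,
    ablation = x$config$ablation
  )
}

#' Edge list of a graph pair
#'
#' @param x A `graph_pair` from [build_graph_pair()].
#' @param ... Unused.
#' @return Tibble of upper-triangle edges with a `stream` column
#'   (global/local).
#' @method tidy graph_pair
#' @export
tidy.graph_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(graph_edge_list(unclass(x$W_global)), stream = "global"),
    dplyr::mutate(graph_edge_list(x$W_local), stream = "local")
  )
}

#' Heatmap of the global and local channel graphs
#'
#' @param object A `graph_pair`.
#' @param ... Unused.
#' @return A ggplot object: two adjacency heatmaps side by side.
#' @method autoplot graph_pair
#' @export
autoplot.graph_pair <- function(object, ...) {
  as_df <- function(W, stream) {
    W <- unclass(W)
    labs <- rownames(W) %||% sprintf("CH%02d", seq_len(nrow(W)))
    tibble::tibble(
      ch_i = factor(rep(labs, times = ncol(W)), levels = labs),
      ch_j = factor(rep(labs, each = nrow(W)), levels = rev(labs)),
      weight = as.vector(W), stream = stream
    )
  }
  df <- dplyr::bind_rows(as_df(object$W_global, "global"),
                         as_df(object$W_local, "local"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ch_i, y = .data$ch_j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~stream) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight",
                  title = "Channel connectivity priors") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-fold accuracy plot of a fitted model
#'
#' @param object An `msgm_fit`.
#' @param ... Unused.
#' @return A ggplot object: per-fold test accuracy with the mean as a line.
#' @method autoplot msgm_fit
#' @export
autoplot.msgm_fit <- function(object, ...) {
  df <- object$folds
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(df$accuracy), linetype = 2) +
    ggplot2::labs(x = "fold (held-out subject group)", y = "test accuracy (%)",
                  title = "Subject-independent accuracy per fold") +
    ggplot2::theme_minimal()
}

#' Mean relative band power by class
#'
#' Diagnostic for synthetic or real feature tensors: mean rPSD per band and
#' class at the first scale.
#'
#' @param features From [prepare_features()].
#' @return A ggplot object.
#' @export
plot_band_power <- function(features) {
  F1 <- features$tensors[[1L]]$values
  meta <- features$meta
  bands <- as.character(eeg_band_table()$band)
  df <- purrr::map_dfr(seq_along(bands), function(j) {
    tibble::tibble(
      band = bands[j], label = meta$label,
      power = apply(F1[, , , j, drop = FALSE], 1L, mean)
    )
  })
  df$band <- factor(df$band, levels = bands)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$power,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "relative band power",
                  title = "Class-conditional relative band power") +
    ggplot2::theme_minimal()
}
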