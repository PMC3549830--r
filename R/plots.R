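# ggplot2 visualisations for signatures, PCA, distance matrices and models.

#' Plot the water-number time series
#'
#' @param data tibble from [water_number_series()].
#' @return A ggplot object (frame index vs water number).
#' @export
plot_water_number <- function(data) {
  stopifnot(all(c("frame_index", "water_number") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$frame_index,
                                     y = .data$water_number)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "water number") +
    ggplot2::theme_minimal()
}

#' @describeIn pca_signatures Scatter plot of the first two PCA projections,
#'   optionally colored by a label vector.
#' @param object a `signature_pca`.
#' @param labels optional per-frame grouping for color.
#' @method autoplot signature_pca
#' @export
autoplot.signature_pca <- function(object, labels = NULL, ...) {
  df <- object$projections
  if (!is.null(labels)) df$label <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance_ratio[1]),
      y = if (ncol(object$components) >= 2 && "PC2" %in% names(df))
        sprintf("PC2 (%.1f%%)", 100 * object$explained_variance_ratio[2]) else "PC2") +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$label),
                               alpha = 0.6, size = 0.8)
}

#' Heatmap of a pairwise distance matrix
#'
#' Reveals the block structure that separates metastable solvent states.
#'
#' @param D symmetric matrix from [pairwise_distances()].
#' @return A ggplot tile plot.
#' @export
plot_distance_matrix <- function(D) {
  df <- tidyr::expand_grid(i = seq_len(nrow(D)), j = seq_len(ncol(D)))
  df$distance <- D[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = "frame", fill = "distance") +
    ggplot2::theme_minimal()
}

#' @describeIn transition_matrix Heatmap of the transition probabilities
#'   (columns = source state).
#' @param object a `transition_model`.
#' @method autoplot transition_model
#' @export
autoplot.transition_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(object$K)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$K)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "from state", y = "to state", fill = "P") +
    ggplot2::theme_minimal()
}

#' @describeIn anneal_lump Per-restart best metastability achieved by the
#'   annealer.
#' @param object a `lumping_result`.
#' @method autoplot lumping_result
#' @export
autoplot.lumping_result <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("no per-restart trace available for this result", call. = FALSE)
  }
  df <- tibble::tibble(restart = seq_along(object$trace), Q = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$restart, y = .data$Q)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$Q, linetype = 2) +
    ggplot2::labs(x = "restart", y = "best Q in restart") +
    ggplot2::theme_minimal()
}

#' Compare normalized metastability across fitted models
#'
#' Reproduces the standard model-comparison view: normalized metastability
#' of the split-stage microstate model (`Q/K`) and, where present, the
#' lumped macrostate model (`Q/L`), against the `1/K` random-assignment
#' baseline, for a set of [run_pipeline()] results.
#'
#' @param runs named list of `msm_run` objects.
#' @return A ggplot object.
#' @export
plot_metastability_comparison <- function(runs) {
  df <- purrr::map_dfr(runs, function(r) glance(r), .id = "run")
  long <- tidyr::pivot_longer(
    df, c("Q_split_normalized", "Q_lumped_normalized"),
    names_to = "stage", values_to = "Q_norm")
  long$stage <- ifelse(long$stage == "Q_split_normalized", "split", "lumped")
  long <- long[!is.na(long$Q_norm), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$Q_norm,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = 1 / .data$K),
                        data = df, linetype = 3) +
    ggplot2::labs(x = NULL, y = "normalized metastability") +
    ggplot2::theme_minimal()
}
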