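# ggplot2 views of the main result types. These render the data the tables
# already hold; no statistic is computed here.

dendro_segments <- function(h) {
  n <- length(h$order)
  leaf_x <- setNames(seq_len(n), h$order)
  xpos <- numeric(nrow(h$merge))
  segs <- list()
  for (k in seq_len(nrow(h$merge))) {
    kid <- h$merge[k, ]
    x <- vapply(kid, function(ch) {
      if (ch < 0) leaf_x[[as.character(-ch)]] else xpos[ch]
    }, numeric(1))
    y0 <- vapply(kid, function(ch) if (ch < 0) 0 else h$height[ch], numeric(1))
    xpos[k] <- mean(x)
    segs[[k]] <- tibble::tibble(
      x = c(x[1], x[2], x[1]), xend = c(x[1], x[2], x[2]),
      y = c(y0[1], y0[2], h$height[k]), yend = rep(h$height[k], 3))
  }
  list(segments = dplyr::bind_rows(segs),
       nodes = tibble::tibble(node = seq_len(nrow(h$merge)), x = xpos,
                              y = h$height),
       leaves = tibble::tibble(label = h$labels[h$order], x = seq_len(n)))
}

#' Dendrogram with AU/BP support labels
#'
#' @param object A `supported_dendrogram`.
#' @param au_cutoff Nodes with AU above this are highlighted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot supported_dendrogram
#' @export
autoplot.supported_dendrogram <- function(object, au_cutoff = 95, ...) {
  dd <- dendro_segments(object$hclust)
  nodes <- dplyr::left_join(dd$nodes, object$nodes, by = "node")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dd$segments,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          color = "grey40") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sprintf("AU %.0f | BP %.0f",
                                                    .data$au, .data$bp),
                                    color = .data$au > au_cutoff),
                       vjust = -0.4, size = 3, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red3",
                                           `FALSE` = "grey30"),
                                na.value = "grey60") +
    ggplot2::scale_x_continuous(breaks = dd$leaves$x,
                                labels = dd$leaves$label) +
    ggplot2::labs(x = NULL, y = sprintf("%s distance, complete linkage",
                                        object$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}

#' PCA score plot of CHC percent profiles
#'
#' @param object A `chc_pca` object.
#' @param ... Unused.
#' @return A ggplot object (PC1 vs PC2, colored by phase).
#' @method autoplot chc_pca
#' @export
autoplot.chc_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               color = .data$phase)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Calibration curves with their standard points
#'
#' @param standards The standard-series table used for the fit.
#' @param curves The matching [fit_calibration()] result.
#' @return A ggplot object, one panel per standard.
#' @export
plot_calibration <- function(standards, curves) {
  pts <- dplyr::mutate(tibble::as_tibble(standards),
                       ratio = .data$area / .data$is_area)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$ratio,
                                    y = .data$level_ug_ml)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = tibble::as_tibble(curves),
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         color = "steelblue") +
    ggplot2::facet_wrap(~standard_id, scales = "free") +
    ggplot2::labs(x = "analyte / internal-standard area ratio",
                  y = "amount (\u00b5g/ml)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression comparison
#'
#' @param records A [test_de()] result.
#' @param q_max,min_abs_log2fc Thresholds drawn as guides (defaults match
#'   the study filter).
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, q_max = 0.05, min_abs_log2fc = 1) {
  records <- dplyr::mutate(
    records,
    called = .data$q < q_max & abs(.data$log2FC) >= min_abs_log2fc)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$log2FC,
                                        y = -log10(pmax(.data$q, 1e-300)),
                                        color = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_log2fc,
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(q_max), linetype = "dashed",
                        color = "grey50") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red3",
                                           `FALSE` = "grey60"),
                                guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q") +
    ggplot2::theme_minimal()
}
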