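# ggplot2 views of the main result types.

#' PCA scatter of samples
#'
#' @param object A `pca_result` from [run_pca()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2, coloured by stage when available, with
#'   explained-variance percentages on the axes.
#' @export
autoplot.pca_result <- function(object, ...) {
  ev <- attr(object, "explained_variance_fraction")
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * ev[i])
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if ("stage" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Volcano plot of a differential expression table
#'
#' @param object A `de_result` from [run_de()].
#' @param p_threshold,lfc_threshold Thresholds drawn as guides and used to
#'   colour DEGs (defaults 0.05 and 1.5).
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 p.
#' @export
autoplot.de_result <- function(object, p_threshold = 0.05,
                               lfc_threshold = 1.5, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$p_value < p_threshold & .data$log2fc > lfc_threshold ~ "up",
        .data$p_value < p_threshold & .data$log2fc < -lfc_threshold ~ "down",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one gene set
#'
#' @param gsea A `gsea_result` from [run_absgsea()].
#' @param set_name Name of a set present in the result.
#' @return A ggplot of the weighted-KS running sum with the peak marked.
#' @export
plot_running_sum <- function(gsea, set_name) {
  stopifnot(inherits(gsea, "gsea_result"))
  row <- gsea[gsea$set_name == set_name, ]
  if (!nrow(row)) stop("set '", set_name, "' not in result", call. = FALSE)
  ranked <- attr(gsea, "ranked")
  es <- enrichment_score(ranked, row$members_used[[1]],
                         attr(gsea, "params")$weight_exponent)
  df <- tibble::tibble(rank = seq_along(es$running_sum),
                       running = es$running_sum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(colour = "#27ae60") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = es$peak_rank, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(title = set_name,
                  subtitle = sprintf("ES = %.3f at rank %d", es$es,
                                     es$peak_rank),
                  x = "rank in list", y = "running enrichment") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of estimated cell-type fractions
#'
#' @param estimates A `fraction_estimates` tibble from [deconvolve()].
#' @param meta Optional metadata; if given, samples are facetted by stage.
#' @return A ggplot with one stacked bar per sample.
#' @export
plot_fractions <- function(estimates, meta = NULL) {
  types <- attr(estimates, "cell_types")
  df <- tibble::as_tibble(estimates) |>
    tidyr::pivot_longer(dplyr::all_of(types), names_to = "cell_type",
                        values_to = "fraction")
  if (!is.null(meta)) df <- dplyr::left_join(df, meta, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                        y = .data$fraction,
                                        fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(meta)) {
    p <- p + ggplot2::facet_grid(~stage, scales = "free_x", space = "free_x")
  }
  p
}
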