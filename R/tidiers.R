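# broom-style tidiers for the pipeline's fitted objects.

#' @importFrom generics tidy glance
NULL

#' Tidy a gene set enrichment result
#'
#' @param x A `gsea_result` from [run_absgsea()].
#' @param ... Unused.
#' @return A plain tibble with one row per set: `set_name`, `set_size_used`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `peak_rank`, `n_leading_edge`,
#'   `significant`.
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(n_leading_edge = lengths(.data$leading_edge)) |>
    dplyr::select("set_name", "set_size_used", "es", "nes", "p_nominal",
                  "fdr_q", "peak_rank", "n_leading_edge", "significant")
}

#' Summarize a gene set enrichment run
#'
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @return One-row tibble: number of sets tested/skipped/significant, the
#'   permutation settings, and the contrast.
#' @export
glance.gsea_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_sets = nrow(x),
    n_skipped = nrow(attr(x, "skipped")),
    n_significant = sum(x$significant),
    n_permutations = p$n_permutations,
    permutation_mode = p$permutation_mode,
    contrast = paste(attr(x, "contrast"), collapse = " vs ")
  )
}

#' Tidy a differential expression table
#'
#' @param x A `de_result` from [run_de()].
#' @param ... Unused.
#' @return The underlying tibble (already tidy), with the contrast attached
#'   as columns `stage_a`, `stage_b`.
#' @export
tidy.de_result <- function(x, ...) {
  ctr <- attr(x, "contrast")
  dplyr::mutate(tibble::as_tibble(x), stage_a = ctr[1], stage_b = ctr[2])
}

#' Summarize a differential expression run
#'
#' @param x A `de_result`.
#' @param ... Passed to [call_degs()] (thresholds).
#' @return One-row tibble: gene counts, DEG counts at the default (or given)
#'   thresholds, and the contrast.
#' @export
glance.de_result <- function(x, ...) {
  degs <- call_degs(x, ...)
  tibble::tibble(
    n_genes = nrow(x),
    n_up = length(degs$up_genes),
    n_down = length(degs$down_genes),
    n_degenerate = sum(x$degenerate),
    contrast = paste(attr(x, "contrast"), collapse = " vs ")
  )
}

#' Tidy a qPCR fold-change result
#'
#' @param x A `ddct_result` from [delta_delta_ct()].
#' @param ... Unused.
#' @return Per-sample tibble with `dct`, `ddct`, `fold_change`.
#' @export
tidy.ddct_result <- function(x, ...) x$fold_changes

#' Summarize a qPCR comparison
#'
#' @param x A `ddct_result`.
#' @param ... Unused.
#' @return The one-row group comparison tibble (mean folds, Welch test).
#' @export
glance.ddct_result <- function(x, ...) x$comparison
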