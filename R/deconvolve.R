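# Immune cell fraction estimation by non-negative least squares against a
# cell-type signature matrix, with sum-to-one renormalization. The mixture
# model is linear on the natural expression scale: m = B beta + noise.

#' Estimate cell-type fractions by constrained least squares
#'
#' For each sample, solves `min || B beta - m ||^2` subject to `beta >= 0`
#' over the genes shared by the mixture and the signature, then renormalizes
#' `beta` to sum to one. Log-scale input is exponentiated back to the linear
#' scale with a warning, since the mixture model is linear.
#'
#' @param mixture An [expression_matrix()] of bulk profiles (genes x
#'   samples), linear scale.
#' @param signature A [signature_matrix()] (genes x cell types).
#' @return A tibble of class `fraction_estimates`: `sample_id`, one fraction
#'   column per cell type (non-negative, summing to 1), `residual_norm`, and
#'   `correlation_with_fit` (Pearson r between fitted and observed values).
#'   Attribute `n_genes_used` records the overlap size.
#' @export
deconvolve <- function(mixture, signature) {
  stopifnot(inherits(mixture, "expression_matrix"),
            inherits(signature, "signature_matrix"))
  M <- mixture$values
  if (mixture$scale == "log2fpkm") {
    warning("log-scale mixture; exponentiating back to the linear scale",
            call. = FALSE)
    M <- 2^M - 1
    M[M < 0] <- 0
  }
  B <- signature$values
  shared <- intersect(rownames(M), rownames(B))
  K <- ncol(B)
  if (length(shared) < K) {
    stop("only ", length(shared), " shared genes for ", K,
         " cell types; system under-determined", call. = FALSE)
  }
  M <- M[shared, , drop = FALSE]
  B <- B[shared, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(M)), function(s) {
    m <- M[, s]
    if (all(m == 0)) {
      stop("sample '", colnames(M)[s], "' is all zero; cannot deconvolve",
           call. = FALSE)
    }
    fit <- pracma::lsqnonneg(B, m)
    beta <- fit$x
    fitted <- as.vector(B %*% beta)
    total <- sum(beta)
    fr <- if (total > 0) beta / total else rep(1 / K, K)
    row <- stats::setNames(as.list(fr), colnames(B))
    row$sample_id <- colnames(M)[s]
    row$residual_norm <- sqrt(sum((fitted - m)^2))
    row$correlation_with_fit <-
      if (stats::sd(fitted) > 0) stats::cor(fitted, m) else NA_real_
    tibble::as_tibble(row)
  })
  out <- dplyr::relocate(res, "sample_id")
  attr(out, "n_genes_used") <- length(shared)
  attr(out, "cell_types") <- colnames(B)
  class(out) <- c("fraction_estimates", class(out))
  out
}

#' Mean cell-type fractions per stage
#'
#' @param estimates A `fraction_estimates` tibble from [deconvolve()].
#' @param meta Metadata tibble (`sample_id`, `stage`).
#' @return A tibble: `stage`, `cell_type`, `mean_fraction`; per-stage means
#'   each sum to 1. Stages with no estimated samples are omitted with a
#'   warning.
#' @export
stage_fraction_summary <- function(estimates, meta) {
  types <- attr(estimates, "cell_types")
  if (is.null(types)) {
    types <- setdiff(names(estimates),
                     c("sample_id", "residual_norm", "correlation_with_fit"))
  }
  joined <- dplyr::inner_join(estimates, meta, by = "sample_id")
  empty <- setdiff(levels(meta$stage), unique(as.character(joined$stage)))
  if (length(empty)) {
    warning("stage(s) with no estimates omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  joined |>
    tidyr::pivot_longer(dplyr::all_of(types), names_to = "cell_type",
                        values_to = "fraction") |>
    dplyr::group_by(.data$stage, .data$cell_type) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop") |>
    dplyr::arrange(.data$stage, .data$cell_type)
}
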