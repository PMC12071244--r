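# Low-count filtering, FPKM normalization, log transform and the two QC
# views (PCA, hierarchical clustering).

#' Remove genes with too few total reads
#'
#' Retains genes whose total read count across all samples is at least
#' `min_total_reads` (default 10, the conventional low-count exclusion for
#' small cohorts). Gene order is preserved and the operation is idempotent.
#'
#' @param counts A [count_matrix()].
#' @param min_total_reads Minimum summed reads across samples for a gene to
#'   be kept.
#' @return The filtered [count_matrix()], with attributes `n_removed` and
#'   `removed_genes`.
#' @examples
#' m <- matrix(c(3L, 6L, 50L, 50L), 2, 2,
#'             dimnames = list(c("low", "high"), c("S1", "S2")))
#' cm <- count_matrix(m, c(low = 1000L, high = 1000L))
#' filter_low_counts(cm)   # keeps only "high"
#' @export
filter_low_counts <- function(counts, min_total_reads = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- rowSums(counts$counts)
  keep <- totals >= min_total_reads
  if (!any(keep)) {
    stop("all ", length(keep), " genes fall below ", min_total_reads,
         " total reads; nothing left to analyse", call. = FALSE)
  }
  out <- count_matrix(counts$counts[keep, , drop = FALSE],
                      counts$gene_lengths_bp[keep])
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_genes") <- names(totals)[!keep]
  out
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM_gs = count_gs / ((length_g / 1e3) * (libsize_s / 1e6))`, where the
#' library size is the column total of the matrix as given (i.e. computed
#' after any low-count filtering already applied).
#'
#' @param counts A [count_matrix()] with gene lengths.
#' @return An [expression_matrix()] on the fpkm scale.
#' @examples
#' m <- matrix(c(10L, 999990L), 2, 1,
#'             dimnames = list(c("G1", "G2"), "S1"))
#' cm <- count_matrix(m, c(G1 = 1000L, G2 = 1000L))
#' fpkm_normalize(cm)$values["G1", ]  # 10
#' @export
fpkm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (isFALSE(attr(counts, "lengths_available"))) {
    stop("count matrix has no gene lengths; FPKM undefined", call. = FALSE)
  }
  lib <- colSums(counts$counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts$counts)[lib == 0], collapse = ", "),
         call. = FALSE)
  }
  kb <- counts$gene_lengths_bp / 1e3
  per_million <- lib / 1e6
  fpkm <- sweep(counts$counts / kb, 2, per_million, "/")
  expression_matrix(fpkm, scale = "fpkm")
}

#' Log2 transform with pseudocount
#'
#' `value -> log2(value + pseudocount)`. The default pseudocount of 1 keeps
#' zeros at zero on the log scale.
#'
#' @param expr An [expression_matrix()] on the fpkm scale.
#' @param pseudocount Positive offset added before taking logs.
#' @return An [expression_matrix()] on the log2fpkm scale.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "fpkm") {
    stop("log_transform expects fpkm-scale input", call. = FALSE)
  }
  if (pseudocount <= 0 && any(expr$values == 0)) {
    stop("non-positive pseudocount with zero values present", call. = FALSE)
  }
  expression_matrix(log2(expr$values + pseudocount), scale = "log2fpkm")
}

#' Principal component analysis of samples
#'
#' PCA of the samples x genes matrix of log-scale expression, gene-centered
#' but not unit-scaled, via singular value decomposition.
#'
#' @param expr An [expression_matrix()] on the log2fpkm scale.
#' @param n_components Number of components to keep (<= min(genes, samples)).
#' @param meta Optional metadata tibble; if given, a `stage` column is joined
#'   onto the scores.
#' @return A tibble of class `pca_result`: `sample_id`, `PC1..PCk` scores and
#'   optionally `stage`; attribute `explained_variance_fraction` holds the
#'   per-component variance fractions (non-increasing, summing to <= 1) and
#'   attribute `rotation` the gene loadings.
#' @export
run_pca <- function(expr, n_components = 2, meta = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "log2fpkm") {
    stop("run_pca expects log-scale expression", call. = FALSE)
  }
  X <- t(expr$values)                    # samples x genes
  if (n_components > min(dim(X))) {
    stop("n_components exceeds min(genes, samples)", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    stop("expression matrix is constant; PCA degenerate", call. = FALSE)
  }
  sv <- svd(Xc)
  var_all <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(X)),
                          tibble::as_tibble(scores))
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, meta, by = "sample_id")
  }
  attr(out, "explained_variance_fraction") <- var_all[seq_len(n_components)]
  attr(out, "rotation") <- sv$v[, seq_len(n_components), drop = FALSE]
  class(out) <- c("pca_result", class(out))
  out
}

#' Agglomerative hierarchical clustering of samples or genes
#'
#' Defaults to 1 - Pearson correlation distance with average linkage, the
#' usual choices for expression heatmaps; both are configurable. Euclidean
#' distance is required when items have zero variance (correlation is then
#' undefined).
#'
#' @param expr An [expression_matrix()].
#' @param axis Cluster `"samples"` (columns) or `"genes"` (rows).
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An [stats::hclust] tree; leaves cover every item exactly once and
#'   merge heights are non-decreasing for the default linkages.
#' @export
hierarchical_cluster <- function(expr, axis = c("samples", "genes"),
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  stopifnot(inherits(expr, "expression_matrix"))
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  X <- if (axis == "samples") t(expr$values) else expr$values
  if (nrow(X) < 2) stop("need >= 2 items to cluster", call. = FALSE)
  if (distance == "correlation") {
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) {
      stop("item(s) with zero variance; correlation distance undefined — ",
           "use distance = \"euclidean\"", call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(t(X)))
  } else {
    d <- stats::dist(X)
  }
  stats::hclust(d, method = linkage)
}
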