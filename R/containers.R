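#' Construct a validated count matrix
#'
#' The raw-count container used throughout the pipeline: a genes x samples
#' matrix of non-negative integer read counts together with per-gene
#' transcript lengths in base pairs (needed for FPKM normalization).
#'
#' @param counts Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids). All entries must be
#'   non-negative integers (integer-valued doubles are accepted).
#' @param gene_lengths_bp Positive integer vector of transcript lengths,
#'   one per gene, either named by gene id or in row order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `gene_lengths_bp` (named integer vector).
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 3L), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("S1", "S2")))
#' cm <- count_matrix(m, c(G1 = 1000L, G2 = 500L))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_lengths_bp) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`counts` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  if (!is.null(names(gene_lengths_bp))) {
    missing <- setdiff(gene_ids, names(gene_lengths_bp))
    if (length(missing)) {
      stop("gene lengths missing for: ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    gene_lengths_bp <- gene_lengths_bp[gene_ids]
  } else if (length(gene_lengths_bp) != nrow(counts)) {
    stop("`gene_lengths_bp` must have one entry per gene", call. = FALSE)
  } else {
    names(gene_lengths_bp) <- gene_ids
  }
  if (anyNA(gene_lengths_bp) || any(gene_lengths_bp <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         gene_lengths_bp = stats::setNames(as.integer(round(gene_lengths_bp)), gene_ids)),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("gene lengths: ", min(x$gene_lengths_bp), "-", max(x$gene_lengths_bp),
      " bp\n", sep = "")
  invisible(x)
}

#' Gene and sample accessors
#'
#' @param x A `count_matrix` or `expression_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$counts %||% x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$counts %||% x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an expression matrix
#'
#' Container for normalized expression values: FPKM (`scale = "fpkm"`) or
#' log2(FPKM + pseudocount) (`scale = "log2fpkm"`). The log scale is only
#' ever derived from the fpkm scale via [log_transform()].
#'
#' @param values Numeric matrix, genes x samples, dimnames required.
#' @param scale One of `"fpkm"` or `"log2fpkm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("fpkm", "log2fpkm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene and sample dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate gene or sample ids", call. = FALSE)
  }
  if (scale == "fpkm" && any(values < 0)) {
    stop("fpkm values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$scale, "]\n", sep = "")
  invisible(x)
}

#' Validate a sample metadata table
#'
#' @param meta Data frame with columns `sample_id` and `stage`.
#' @param stages Allowed stage labels, ordered from earliest to latest;
#'   defaults to the adenoma-carcinoma progression sequence.
#' @param counts Optional `count_matrix`; if given, the sample id sets must
#'   match exactly.
#' @return A tibble with `sample_id` (character) and `stage` (factor with the
#'   declared level order).
#' @export
sample_metadata <- function(meta,
                            stages = c("adenoma", "CIS", "adenocarcinoma"),
                            counts = NULL) {
  if (!all(c("sample_id", "stage") %in% names(meta))) {
    stop("metadata needs `sample_id` and `stage` columns", call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(meta$stage)), stages)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$stage <- factor(as.character(meta$stage), levels = stages)
  if (!is.null(counts)) {
    if (!setequal(meta$sample_id, sample_ids(counts))) {
      stop("metadata sample ids do not match count matrix sample ids",
           call. = FALSE)
    }
  }
  meta
}

#' Construct a cell-type signature matrix
#'
#' Reference expression profiles used for deconvolution: genes x cell types,
#' non-negative, each column non-zero.
#'
#' @param values Non-negative numeric matrix with gene rownames and cell-type
#'   colnames.
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("signature needs gene and cell-type dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate gene or cell-type labels in signature", call. = FALSE)
  }
  if (any(values < 0) || anyNA(values)) {
    stop("signature values must be non-negative and complete", call. = FALSE)
  }
  if (any(colSums(values) == 0)) {
    stop("signature has an all-zero cell-type column", call. = FALSE)
  }
  structure(list(values = values), class = "signature_matrix")
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cell types\n", sep = "")
  invisible(x)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (set members); names are set
#'   names and must be unique.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @param collection_name Label for the collection (e.g. `"C5"`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                collection_name = "custom") {
  if (!length(sets)) stop("empty gene set collection", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    stop("set names must be present and unique", call. = FALSE)
  }
  for (nm in names(sets)) {
    m <- sets[[nm]]
    if (!length(m)) stop("set '", nm, "' has no members", call. = FALSE)
    if (anyDuplicated(m)) stop("set '", nm, "' has duplicate members", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) {
    stop("one description per set required", call. = FALSE)
  }
  structure(
    list(sets = sets,
         descriptions = stats::setNames(descriptions, names(sets)),
         collection_name = collection_name),
    class = "gene_set_collection"
  )
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("<gene_set_collection> '", x$collection_name, "': ", length(x$sets),
      " sets, sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}
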