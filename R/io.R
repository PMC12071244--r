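# All tabular i/o is TSV, UTF-8, '.' decimal, to match the tab convention of
# the GMT gene-set format and avoid locale ambiguity. Gene identifiers are
# opaque case-sensitive strings; no symbol aliasing.

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' (optionally) a gene-length column in base pairs. All remaining columns are
#' taken as sample counts.
#'
#' @param path Path to a tab-separated file.
#' @param length_column Name of the gene-length column, or `NULL` if the file
#'   has none (lengths must then be supplied downstream before FPKM).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, length_column = "length_bp") {
  tab <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) stop("count TSV needs gene ids plus at least one sample",
                          call. = FALSE)
  gene_col <- names(tab)[1]
  if (anyNA(tab[[gene_col]]) || anyDuplicated(tab[[gene_col]])) {
    stop("missing or duplicate gene id rows in ", path, call. = FALSE)
  }
  to_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric value in ", what, " column", call. = FALSE)
    v
  }
  if (!is.null(length_column)) {
    if (!length_column %in% names(tab)) {
      stop("length column '", length_column, "' not found in ", path,
           call. = FALSE)
    }
    lengths <- to_num(tab[[length_column]], "length")
  } else {
    lengths <- NULL
  }
  sample_cols <- setdiff(names(tab), c(gene_col, length_column))
  m <- vapply(tab[sample_cols], to_num, numeric(nrow(tab)), what = "count")
  m <- matrix(m, nrow = nrow(tab),
              dimnames = list(tab[[gene_col]], sample_cols))
  if (is.null(lengths)) {
    # placeholder unit lengths; fpkm_normalize() refuses them
    cm <- count_matrix(m, stats::setNames(rep(1L, nrow(m)), rownames(m)))
    attr(cm, "lengths_available") <- FALSE
  } else {
    cm <- count_matrix(m, stats::setNames(lengths, rownames(m)))
    attr(cm, "lengths_available") <- TRUE
  }
  cm
}

#' Write a count matrix to TSV
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @param length_column Name used for the gene-length column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, length_column = "length_bp") {
  stopifnot(inherits(x, "count_matrix"))
  tab <- tibble::as_tibble(x$counts, rownames = "gene_id")
  tab[[length_column]] <- unname(x$gene_lengths_bp)
  tab <- tab[, c("gene_id", length_column,
                 setdiff(names(tab), c("gene_id", length_column)))]
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id` and `stage`.
#' @param stages Allowed stage labels in progression order.
#' @return A validated metadata tibble (see [sample_metadata()]).
#' @export
read_sample_metadata <- function(path,
                                 stages = c("adenoma", "CIS", "adenocarcinoma")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  sample_metadata(tab, stages = stages)
}

#' Read a GMT gene-set file
#'
#' One set per line: `set_name TAB description TAB member1 TAB member2 ...`
#' (the MSigDB dialect). Blank lines are skipped; member order is preserved.
#'
#' @param path Path to a GMT file.
#' @param collection_name Label attached to the parsed collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, collection_name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  desc <- vapply(fields, `[[`, character(1), 2)
  gene_set_collection(sets, descriptions = desc,
                      collection_name = collection_name)
}

#' Write a gene set collection as GMT
#'
#' Emits canonical GMT: tab-separated, newline-terminated, set order
#' preserved, so that `write_gmt(read_gmt(f))` is byte-identical for
#' canonical files.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a signature matrix from TSV
#'
#' First column gene id, header row of cell-type names.
#'
#' @param path Path to a TSV file.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  tab <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  m <- vapply(tab[-1], function(x) suppressWarnings(as.numeric(x)),
              numeric(nrow(tab)))
  m <- matrix(m, nrow = nrow(tab),
              dimnames = list(tab[[1]], names(tab)[-1]))
  signature_matrix(m)
}

#' Write a signature matrix to TSV
#'
#' @param x A [signature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(x, path) {
  stopifnot(inherits(x, "signature_matrix"))
  tab <- tibble::as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Floats are rendered with full precision (>= 6 significant digits) so a
#' read-back reproduces values to 1e-9; list columns (e.g. leading-edge gene
#' lists) are serialized pipe-separated; missing values serialize as "NA".
#' Row order is preserved as given.
#'
#' @param rows A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  is_list <- vapply(rows, is.list, logical(1))
  for (col in names(rows)[is_list]) {
    rows[[col]] <- vapply(rows[[col]], function(v) paste(v, collapse = "|"),
                          character(1))
  }
  readr::write_tsv(rows, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble with column types guessed from content.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  na = "NA")
}
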