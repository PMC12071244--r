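# Gene-frequency prioritization across significant gene sets, top-fraction
# selection, and the multi-criterion candidate-biomarker filter cascade.

#' Gene frequency across significant gene sets
#'
#' Counts, for every gene, the number of significant sets whose counted
#' membership includes it. The counted membership defaults to the
#' leading-edge subset (the genes actually driving each enrichment signal);
#' `"full_set"` counts complete set memberships instead.
#'
#' @param gsea A `gsea_result` from [run_absgsea()], or any tibble with
#'   `set_name`, `significant`, and list columns `leading_edge` and
#'   `members_used`.
#' @param membership_basis `"leading_edge"` (default) or `"full_set"`.
#' @param significant_only Count only sets flagged significant (default).
#' @return A tibble of class `frequency_table`: `gene_id`, `frequency`,
#'   `sets_containing` (list column), `rank` (1..G; frequency descending,
#'   ties broken by gene id).
#' @examples
#' # three sets with leading edges {A,B}, {A,C}, {A} give A:3, B:1, C:1
#' @export
gene_frequency <- function(gsea,
                           membership_basis = c("leading_edge", "full_set"),
                           significant_only = TRUE) {
  membership_basis <- match.arg(membership_basis)
  tab <- tibble::as_tibble(gsea)
  if (significant_only) {
    if (!"significant" %in% names(tab)) {
      stop("result table lacks a `significant` column", call. = FALSE)
    }
    tab <- tab[tab$significant, ]
  }
  if (!nrow(tab)) {
    stop("no significant gene sets; relax p/q thresholds or check inputs",
         call. = FALSE)
  }
  members <- if (membership_basis == "leading_edge") tab$leading_edge
             else tab$members_used
  long <- tibble::tibble(
    set_name = rep(tab$set_name, lengths(members)),
    gene_id = unlist(members, use.names = FALSE)
  )
  out <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(frequency = dplyr::n(),
                     sets_containing = list(.data$set_name),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "membership_basis") <- membership_basis
  class(out) <- c("frequency_table", class(out))
  out
}

#' Top-fraction selection from a frequency table
#'
#' Takes the first `ceil(fraction * G)` genes of the frequency-ranked table
#' and expands the cut to include every gene tied with the last included
#' frequency, so the selection never depends on tie order.
#'
#' @param freq A `frequency_table` from [gene_frequency()].
#' @param fraction Fraction of genes to keep, in `(0, 1]` (default 0.20).
#' @param n_top Alternative absolute cutoff (e.g. top 20 genes); overrides
#'   `fraction` when given. Tie expansion applies the same way.
#' @return The selected rows of `freq`, in rank order.
#' @export
top_fraction <- function(freq, fraction = 0.20, n_top = NULL) {
  stopifnot(inherits(freq, "data.frame"))
  G <- nrow(freq)
  if (is.null(n_top)) {
    if (fraction <= 0 || fraction > 1) {
      stop("fraction must be in (0, 1]", call. = FALSE)
    }
    n_cut <- ceiling(fraction * G)
  } else {
    n_cut <- min(n_top, G)
  }
  freq <- dplyr::arrange(freq, .data$rank)
  cut_freq <- freq$frequency[n_cut]
  freq[freq$frequency >= cut_freq, ]
}

#' Candidate-biomarker filter cascade
#'
#' Evaluates, per gene, the four selection criteria:
#' \enumerate{
#'   \item `p_ok` — Welch p-value < `p_threshold` (strict);
#'   \item `lfc_ok` — `|log2FC|` > `lfc_threshold` (strict);
#'   \item `expression_floor_ok` — mean raw count strictly above
#'     `high_floor` in the higher-expressing group and at least `low_floor`
#'     in the other (the floors guard against unstable fold changes from
#'     weakly expressed genes in degraded samples);
#'   \item `multi_pathway_ok` — membership in at least `min_pathways`
#'     significant sets (counted membership of the frequency analysis).
#' }
#' A gene is `selected` iff all four pass; `direction` is `"up"` when the
#' later stage is higher.
#'
#' @param de A `de_result` from [run_de()].
#' @param freq A `frequency_table` from [gene_frequency()] (genes absent
#'   from it have pathway count 0).
#' @param p_threshold,lfc_threshold,high_floor,low_floor,min_pathways
#'   Filter thresholds; defaults 0.05, 1.5, 100, 30, 2.
#' @param use_adjusted Threshold BH-adjusted p-values instead.
#' @return A tibble of class `biomarker_calls`: `gene_id`, `direction`,
#'   the four filter booleans, `selected`, `n_pathways`, plus the DE
#'   statistics; attributes `contrast` and `thresholds`.
#' @export
biomarker_filter <- function(de, freq,
                             p_threshold = 0.05,
                             lfc_threshold = 1.5,
                             high_floor = 100,
                             low_floor = 30,
                             min_pathways = 2,
                             use_adjusted = FALSE) {
  req <- c("gene_id", "p_value", "log2fc", "mean_count_a", "mean_count_b")
  if (!all(req %in% names(de))) {
    stop("DE table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(de$mean_count_a) || anyNA(de$mean_count_b)) {
    stop("missing group mean counts", call. = FALSE)
  }
  p <- if (use_adjusted) de$adjusted_p else de$p_value
  hi <- pmax(de$mean_count_a, de$mean_count_b)
  lo <- pmin(de$mean_count_a, de$mean_count_b)
  n_path <- freq$frequency[match(de$gene_id, freq$gene_id)]
  n_path[is.na(n_path)] <- 0L
  out <- tibble::tibble(
    gene_id = de$gene_id,
    direction = ifelse(de$log2fc > 0, "up", "down"),
    p_ok = p < p_threshold,
    lfc_ok = abs(de$log2fc) > lfc_threshold,
    expression_floor_ok = hi > high_floor & lo >= low_floor,
    multi_pathway_ok = n_path >= min_pathways,
    n_pathways = n_path,
    log2fc = de$log2fc,
    p_value = de$p_value,
    mean_count_a = de$mean_count_a,
    mean_count_b = de$mean_count_b
  )
  out$selected <- out$p_ok & out$lfc_ok & out$expression_floor_ok &
    out$multi_pathway_ok
  attr(out, "contrast") <- attr(de, "contrast")
  attr(out, "thresholds") <- list(p = p_threshold, lfc = lfc_threshold,
                                  high_floor = high_floor,
                                  low_floor = low_floor,
                                  min_pathways = min_pathways,
                                  adjusted = use_adjusted)
  class(out) <- c("biomarker_calls", class(out))
  out
}

#' Assign selected biomarkers to the stage where they are overexpressed
#'
#' Reorganizes per-contrast biomarker calls into per-stage marker lists: a
#' gene selected with direction "up" belongs to the later stage of its
#' contrast, "down" to the earlier stage. A gene assigned to more than one
#' stage across contrasts is flagged as conflicting rather than silently
#' resolved.
#'
#' @param calls A list of `biomarker_calls` tibbles (one per contrast, each
#'   carrying its `contrast` attribute).
#' @return A tibble: `gene_id`, `stage` (where overexpressed), `contrasts`
#'   (list column of supporting contrasts), `conflict` (TRUE when the gene
#'   is claimed by several stages; such genes keep one row per stage).
#' @export
stage_signature_report <- function(calls) {
  if (inherits(calls, "biomarker_calls")) calls <- list(calls)
  if (!length(calls)) stop("no biomarker calls supplied", call. = FALSE)
  rows <- purrr::map_dfr(calls, function(cl) {
    ctr <- attr(cl, "contrast")
    if (is.null(ctr)) stop("calls missing contrast attribute", call. = FALSE)
    sel <- cl[cl$selected, ]
    if (!nrow(sel)) return(NULL)
    tibble::tibble(
      gene_id = sel$gene_id,
      stage = ifelse(sel$direction == "up", ctr[2], ctr[1]),
      contrast = paste(ctr, collapse = " vs ")
    )
  })
  if (is.null(rows) || !nrow(rows)) {
    return(tibble::tibble(gene_id = character(), stage = character(),
                          contrasts = list(), conflict = logical()))
  }
  out <- rows |>
    dplyr::group_by(.data$gene_id, .data$stage) |>
    dplyr::summarise(contrasts = list(unique(.data$contrast)),
                     .groups = "drop_last") |>
    dplyr::mutate(conflict = dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stage, .data$gene_id)
  out
}
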