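# Welch unequal-variance differential expression on log2(FPKM + 1), with
# raw-count group means carried alongside for the expression-floor filters,
# and the 2^-ddCt qPCR fold-change calculator.

#' Welch's unequal-variance t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/n + s2y/m)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution. If both groups have zero variance and equal
#' means the test is degenerate and `p = 1` is returned with `t = 0`;
#' zero variance with unequal means gives `p = 0` and infinite `t`, flagged
#' via the `degenerate` field.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `degenerate`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p = 0.0214
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  res <- welch_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  tibble::tibble(t_stat = res$t, df = res$df, p_value = res$p,
                 degenerate = res$degenerate)
}

# Vectorized Welch over matrix rows; x, y are genes x samples slices.
welch_rows <- function(x, y) {
  n <- ncol(x); m <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (m - 1)
  se2 <- vx / n + vy / m
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  degenerate <- se2 == 0
  p <- 2 * stats::pt(-abs(t), df)
  # zero variance in both groups: equal means -> no evidence (p = 1);
  # unequal means -> t infinite, p -> 0 but flagged
  p[degenerate & mx == my] <- 1
  t[degenerate & mx == my] <- 0
  p[degenerate & mx != my] <- 0
  df[degenerate] <- NA_real_
  list(t = unname(t), df = unname(df), p = unname(p),
       degenerate = unname(degenerate), mean_x = unname(mx), mean_y = unname(my))
}

#' Log2 fold change of two group means
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, oriented later
#' stage (`mean_b`) over earlier stage (`mean_a`).
#'
#' @param mean_b,mean_a Non-negative group means (later, earlier stage).
#' @param pseudocount Offset; must be positive if either mean is zero.
#' @return Numeric log2 fold change.
#' @export
log2_fold_change <- function(mean_b, mean_a, pseudocount = 0) {
  if (any(mean_b < 0) || any(mean_a < 0)) {
    stop("group means must be non-negative", call. = FALSE)
  }
  if (pseudocount <= 0 && any(mean_b == 0 | mean_a == 0)) {
    stop("zero mean requires a positive pseudocount", call. = FALSE)
  }
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Per-gene differential expression between two stages
#'
#' Welch's t-test per gene on log2fpkm expression, log2 fold change oriented
#' `stage_b` over `stage_a` computed from group mean FPKM (with pseudocount),
#' and group mean raw counts carried from the count matrix for the
#' expression-floor filters. Benjamini-Hochberg adjusted p-values are
#' reported in `adjusted_p`; the unadjusted `p_value` drives the default
#' thresholds (see [call_degs()]).
#'
#' @param expr An [expression_matrix()] on the log2fpkm scale.
#' @param counts The matching [count_matrix()] (same genes/samples), source
#'   of raw-count group means.
#' @param meta Metadata tibble with `sample_id`, `stage`.
#' @param contrast Length-2 character vector `c(stage_a, stage_b)`, earlier
#'   stage first.
#' @param pseudocount Pseudocount for the FPKM-mean fold change.
#' @return A tibble of class `de_result`, one row per gene: `gene_id`,
#'   `mean_count_a`, `mean_count_b`, `mean_expr_a`, `mean_expr_b`, `log2fc`,
#'   `t_stat`, `df`, `p_value`, `adjusted_p`, `degenerate`. Attribute
#'   `contrast` records the stage pair.
#' @export
run_de <- function(expr, counts, meta, contrast, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(counts, "count_matrix"))
  if (expr$scale != "log2fpkm") {
    stop("run_de expects log2fpkm expression", call. = FALSE)
  }
  if (length(contrast) != 2) stop("contrast must name two stages", call. = FALSE)
  unknown <- setdiff(contrast, levels(meta$stage))
  if (length(unknown)) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids_a <- meta$sample_id[meta$stage == contrast[1]]
  ids_b <- meta$sample_id[meta$stage == contrast[2]]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each contrast stage needs >= 2 samples", call. = FALSE)
  }
  genes <- rownames(expr$values)
  if (!identical(genes, rownames(counts$counts))) {
    counts_m <- counts$counts[genes, , drop = FALSE]
  } else {
    counts_m <- counts$counts
  }
  Xa <- expr$values[, ids_a, drop = FALSE]
  Xb <- expr$values[, ids_b, drop = FALSE]
  w <- welch_rows(Xb, Xa)   # orientation: b vs a
  fpkm_a <- rowMeans(2^Xa - 1)   # invert the log2(FPKM+1) transform
  fpkm_b <- rowMeans(2^Xb - 1)
  fpkm_a[fpkm_a < 0] <- 0        # numeric noise guard
  fpkm_b[fpkm_b < 0] <- 0
  out <- tibble::tibble(
    gene_id = genes,
    mean_count_a = rowMeans(counts_m[, ids_a, drop = FALSE]),
    mean_count_b = rowMeans(counts_m[, ids_b, drop = FALSE]),
    mean_expr_a = rowMeans(Xa),
    mean_expr_b = rowMeans(Xb),
    log2fc = log2_fold_change(fpkm_b, fpkm_a, pseudocount),
    t_stat = w$t,
    df = w$df,
    p_value = w$p,
    adjusted_p = stats::p.adjust(w$p, method = "BH"),
    degenerate = w$degenerate
  )
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", class(out))
  out
}

#' Call differentially expressed genes from a DE table
#'
#' Strict inequalities exactly as conventionally reported:
#' up = `p < p_threshold` and `log2fc > lfc_threshold`;
#' down = `p < p_threshold` and `log2fc < -lfc_threshold`.
#'
#' @param de A `de_result` tibble from [run_de()].
#' @param p_threshold Nominal p-value cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1.5).
#' @param use_adjusted If `TRUE`, threshold the BH-adjusted p-values instead
#'   of the unadjusted defaults.
#' @return A list of class `deg_set`: `up_genes`, `down_genes`, `contrast`,
#'   `thresholds`.
#' @export
call_degs <- function(de, p_threshold = 0.05, lfc_threshold = 1.5,
                      use_adjusted = FALSE) {
  p <- if (use_adjusted) de$adjusted_p else de$p_value
  structure(
    list(up_genes = de$gene_id[p < p_threshold & de$log2fc > lfc_threshold],
         down_genes = de$gene_id[p < p_threshold & de$log2fc < -lfc_threshold],
         contrast = attr(de, "contrast"),
         thresholds = list(p = p_threshold, lfc = lfc_threshold,
                           adjusted = use_adjusted)),
    class = "deg_set"
  )
}

#' @export
print.deg_set <- function(x, ...) {
  cat("<deg_set> ", paste(x$contrast, collapse = " vs "), ": ",
      length(x$up_genes), " up, ", length(x$down_genes), " down (p < ",
      x$thresholds$p, ", |log2FC| > ", x$thresholds$lfc, ")\n", sep = "")
  invisible(x)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = target_ct - reference_ct`; `ddCt = dCt - mean(dCt of
#' the control group)`; fold change `= 2^(-ddCt)`. Groups are compared by an
#' unpaired two-tailed Welch t-test on the per-sample fold changes.
#'
#' @param measurements Tibble with columns `sample_id`, `group`, `target_ct`,
#'   `reference_ct` (threshold cycles; finite and positive).
#' @param control_group Group label used as the ddCt baseline.
#' @param target_group Group label compared against the control.
#' @return A list of class `ddct_result`: `fold_changes` (per-sample tibble
#'   with `dct`, `ddct`, `fold_change`) and `comparison` (one-row tibble with
#'   group mean folds and the Welch test).
#' @export
delta_delta_ct <- function(measurements, control_group, target_group) {
  req <- c("sample_id", "group", "target_ct", "reference_ct")
  if (!all(req %in% names(measurements))) {
    stop("measurements need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ct <- c(measurements$target_ct, measurements$reference_ct)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  m <- tibble::as_tibble(measurements)
  if (!any(m$group == control_group)) {
    stop("control group '", control_group, "' has no measurements",
         call. = FALSE)
  }
  if (!any(m$group == target_group)) {
    stop("target group '", target_group, "' has no measurements",
         call. = FALSE)
  }
  m$dct <- m$target_ct - m$reference_ct
  control_mean_dct <- mean(m$dct[m$group == control_group])
  m$ddct <- m$dct - control_mean_dct
  m$fold_change <- 2^(-m$ddct)
  fc_ctrl <- m$fold_change[m$group == control_group]
  fc_tgt <- m$fold_change[m$group == target_group]
  test <- if (length(fc_ctrl) >= 2 && length(fc_tgt) >= 2) {
    welch_t_test(fc_tgt, fc_ctrl)
  } else {
    tibble::tibble(t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                   degenerate = NA)
  }
  comparison <- dplyr::bind_cols(
    tibble::tibble(control_group = control_group,
                   target_group = target_group,
                   mean_fold_control = mean(fc_ctrl),
                   mean_fold_target = mean(fc_tgt)),
    test
  )
  structure(list(fold_changes = m, comparison = comparison),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("<ddct_result> ", x$comparison$target_group, " vs ",
      x$comparison$control_group, ": mean fold ",
      signif(x$comparison$mean_fold_target, 4), " (p = ",
      signif(x$comparison$p_value, 3), ")\n", sep = "")
  invisible(x)
}
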