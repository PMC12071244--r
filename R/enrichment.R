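# Gene set enrichment engine: weighted Kolmogorov-Smirnov running-sum
# statistic over a ranked gene list, permutation null, NES, permutation FDR
# q-values and leading-edge extraction. The absolute mode ranks genes by the
# magnitude of the differential metric, so sets perturbed in either
# direction enrich at the top of the list.

#' Enrichment parameters
#'
#' @param weight_exponent Weight on the ranking metric in the running sum
#'   (0 = classic Kolmogorov-Smirnov, 1 = standard weighted statistic).
#' @param n_permutations Size of the permutation null (>= 1; < 100 triggers
#'   a warning because q-values become unstable).
#' @param permutation_mode `"phenotype"` (relabel samples and re-rank; the
#'   default) or `"gene_set"` (resample member labels from the universe, for
#'   tiny cohorts).
#' @param min_set_size,max_set_size Retain sets whose overlap with the
#'   expression universe lies within this range.
#' @param p_threshold,q_threshold Significance cutoffs used to flag sets
#'   (defaults: nominal p < 0.05 and FDR q < 0.25).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(weight_exponent = 1,
                              n_permutations = 1000,
                              permutation_mode = c("phenotype", "gene_set"),
                              min_set_size = 5,
                              max_set_size = 500,
                              p_threshold = 0.05,
                              q_threshold = 0.25,
                              seed = 1L) {
  permutation_mode <- match.arg(permutation_mode)
  stopifnot(weight_exponent >= 0, min_set_size <= max_set_size,
            p_threshold > 0, p_threshold < 1,
            q_threshold > 0, q_threshold < 1)
  if (n_permutations < 1) stop("need at least one permutation", call. = FALSE)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations; q-values will be unstable",
            call. = FALSE)
  }
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 permutation_mode = permutation_mode,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 p_threshold = p_threshold,
                 q_threshold = q_threshold,
                 seed = as.integer(seed)),
            class = "enrichment_params")
}

# ranking metric per gene; X is genes x samples (log scale), a/b are column
# index vectors for the earlier/later stage
gene_metric <- function(X, idx_a, idx_b, metric) {
  if (metric == "signal2noise") {
    Xa <- X[, idx_a, drop = FALSE]
    Xb <- X[, idx_b, drop = FALSE]
    n_a <- ncol(Xa); n_b <- ncol(Xb)
    mu_a <- rowMeans(Xa)
    mu_b <- rowMeans(Xb)
    sd_a <- sqrt(pmax(rowSums((Xa - mu_a)^2), 0) / (n_a - 1))
    sd_b <- sqrt(pmax(rowSums((Xb - mu_b)^2), 0) / (n_b - 1))
    # GSEA-style floor keeps small-n standard deviations away from zero
    sd_a <- pmax(sd_a, 0.2 * abs(mu_a), 1e-8)
    sd_b <- pmax(sd_b, 0.2 * abs(mu_b), 1e-8)
    (mu_b - mu_a) / (sd_a + sd_b)
  } else if (metric == "t_stat") {
    w <- welch_rows(X[, idx_b, drop = FALSE], X[, idx_a, drop = FALSE])
    w$t
  } else if (metric == "log2fc") {
    rowMeans(X[, idx_b, drop = FALSE]) - rowMeans(X[, idx_a, drop = FALSE])
  } else {
    stop("unknown ranking metric '", metric, "'", call. = FALSE)
  }
}

#' Rank genes by a differential metric
#'
#' Computes a per-gene differential metric between two stages and sorts
#' descending; ties are broken by gene id so the ranking is deterministic.
#' In absolute mode the metric is replaced by its magnitude before sorting,
#' which makes downstream enrichment direction-agnostic.
#'
#' @param expr An [expression_matrix()] on the log2fpkm scale.
#' @param meta Metadata tibble (`sample_id`, `stage`).
#' @param contrast `c(stage_a, stage_b)`, earlier stage first; signed
#'   metrics are oriented `stage_b` minus `stage_a`.
#' @param metric `"signal2noise"` (default; mean difference over the sum of
#'   floored standard deviations), `"t_stat"` (Welch t) or `"log2fc"` (mean
#'   log-expression difference).
#' @param absolute_mode Rank by `|metric|` (default `TRUE`).
#' @return A tibble of class `ranked_list`: `gene_id`, `metric`, sorted
#'   non-increasing; attributes `metric_name`, `absolute_mode`, `contrast`.
#' @export
rank_genes <- function(expr, meta, contrast,
                       metric = c("signal2noise", "t_stat", "log2fc"),
                       absolute_mode = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  metric <- match.arg(metric)
  ids_a <- meta$sample_id[meta$stage == contrast[1]]
  ids_b <- meta$sample_id[meta$stage == contrast[2]]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each contrast stage needs >= 2 samples", call. = FALSE)
  }
  X <- expr$values
  r <- gene_metric(X, match(ids_a, colnames(X)), match(ids_b, colnames(X)),
                   metric)
  if (absolute_mode) r <- abs(r)
  ord <- order(-r, rownames(X))
  out <- tibble::tibble(gene_id = rownames(X)[ord], metric = unname(r[ord]))
  attr(out, "metric_name") <- metric
  attr(out, "absolute_mode") <- absolute_mode
  attr(out, "contrast") <- contrast
  class(out) <- c("ranked_list", class(out))
  out
}

# Core weighted-KS statistic from sorted hit positions.
# hr: strictly increasing hit ranks in 1..N; wt: non-negative raw weights
# (|metric|^w) aligned to hr. Returns es and peak_rank without materializing
# the running sum.
es_core <- function(hr, wt, N) {
  k <- length(hr)
  S <- sum(wt)
  wt <- if (S > 0) wt / S else rep(1 / k, k)
  miss <- if (N > k) 1 / (N - k) else 0
  cw <- cumsum(wt)
  drop_ <- (hr - seq_len(k)) * miss   # misses accumulated before hit i
  top <- cw - drop_                   # running sum at hit i
  bot <- c(0, cw[-k]) - drop_         # running sum just before hit i
  # tolerance-based argmax/argmin (earliest index) so exact ties computed
  # in different summation orders resolve identically
  i_max <- which(top > max(top) - 1e-12)[1]
  i_min <- which(bot < min(bot) + 1e-12)[1]
  max_pos <- top[i_max]
  min_neg <- bot[i_min]
  if (max_pos >= -min_neg - 1e-12) {  # ties resolve to the positive peak
    list(es = unname(max_pos), peak_rank = unname(hr[i_max]))
  } else {
    list(es = unname(min_neg), peak_rank = unname(hr[i_min]) - 1L)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|r_g|^w / sum_members(|r|^w)` at
#' member genes ("hits") and `-1/(N - N_hits)` at non-members ("misses");
#' the enrichment score is the running-sum value of maximal absolute
#' deviation from zero, with ties between a positive and negative peak
#' resolved to the positive one.
#'
#' @param ranked A `ranked_list` from [rank_genes()] (or any tibble with
#'   `gene_id` and `metric`, sorted non-increasing).
#' @param members Character vector of member gene ids; at least one must
#'   appear in the ranked list.
#' @param weight_exponent Non-negative weight exponent `w`.
#' @return A list: `es` (in `[-1, 1]`), `peak_rank` (position of the peak),
#'   and `running_sum` (numeric vector over all N positions).
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% members
  k <- sum(hit)
  if (k == 0) stop("no member of the set overlaps the ranked list",
                   call. = FALSE)
  w <- abs(ranked$metric)^weight_exponent
  S <- sum(w[hit])
  steps <- numeric(N)
  steps[hit] <- if (S > 0) w[hit] / S else 1 / k
  steps[!hit] <- if (N > k) -1 / (N - k) else 0
  running <- cumsum(steps)
  core <- es_core(which(hit), w[hit], N)
  list(es = core$es, peak_rank = core$peak_rank, running_sum = running)
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the members ranked at or before the
#' running-sum peak; for a negative score, the members ranked after it.
#'
#' @param ranked A `ranked_list`.
#' @param members Member gene ids.
#' @param peak_rank Peak position from [enrichment_score()].
#' @param es_sign Sign of the enrichment score (>= 0 treated as positive).
#' @return Character vector of leading-edge gene ids (a subset of
#'   `members`), in rank order.
#' @export
leading_edge <- function(ranked, members, peak_rank, es_sign) {
  pos <- which(ranked$gene_id %in% members)
  keep <- if (es_sign >= 0) pos[pos <= peak_rank] else pos[pos > peak_rank]
  ranked$gene_id[keep]
}

#' Normalize enrichment scores and assign permutation significance
#'
#' NES divides each observed score by the mean of its own same-sign null
#' scores (a single sign in absolute mode). The nominal p-value is the
#' continuity-corrected fraction of same-sign nulls strictly exceeding the
#' observed magnitude, `(1 + #{|null| > |es|}) / (1 + n_same_sign)`. The FDR
#' q-value follows the permutation convention of pooling all normalized null
#' scores: the raw estimate is the tail fraction of pooled null NES at least
#' as extreme, divided by the tail fraction of observed NES at least as
#' extreme (same sign), clipped to `[0, 1]`; a final step-up pass makes q
#' monotone non-increasing in `|NES|`.
#'
#' @param observed_es Numeric vector of observed enrichment scores, one per
#'   set.
#' @param null_es Numeric matrix, sets x permutations, of null scores (row
#'   order matching `observed_es`).
#' @param set_names Optional set names for the output.
#' @return A tibble: `set_name`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `flagged` (TRUE where the null was degenerate and q forced to 1).
#' @export
gsea_significance <- function(observed_es, null_es,
                              set_names = names(observed_es)) {
  stopifnot(is.matrix(null_es), nrow(null_es) == length(observed_es))
  n_sets <- length(observed_es)
  if (is.null(set_names)) set_names <- paste0("set", seq_len(n_sets))
  nes <- rep(NA_real_, n_sets)
  p <- rep(NA_real_, n_sets)
  flagged <- rep(FALSE, n_sets)
  null_nes <- matrix(NA_real_, n_sets, ncol(null_es))
  for (i in seq_len(n_sets)) {
    es_i <- observed_es[i]
    nulls <- null_es[i, ]
    same <- if (es_i >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    if (!length(same) || all(same == 0)) {
      flagged[i] <- TRUE
      nes[i] <- 0
      p[i] <- 1
    } else {
      nes[i] <- es_i / abs(mean(same))
      p[i] <- (1 + sum(abs(same) > abs(es_i))) / (1 + length(same))
    }
    pos <- nulls >= 0
    mp <- mean(nulls[pos]); mn <- mean(nulls[!pos])
    scaled <- nulls
    if (any(pos) && mp > 0) scaled[pos] <- nulls[pos] / mp
    if (any(!pos) && mn < 0) scaled[!pos] <- nulls[!pos] / abs(mn)
    null_nes[i, ] <- scaled
  }
  pooled <- as.vector(null_nes)
  q <- rep(1, n_sets)
  for (i in seq_len(n_sets)) {
    if (flagged[i] || is.na(nes[i])) next
    v <- nes[i]
    if (v >= 0) {
      null_tail <- mean(pooled[pooled >= 0] >= v)
      obs_tail <- mean(nes[nes >= 0] >= v)
    } else {
      null_tail <- mean(pooled[pooled < 0] <= v)
      obs_tail <- mean(nes[nes < 0] <= v)
    }
    if (is.nan(null_tail)) null_tail <- 0
    q[i] <- if (obs_tail > 0) min(1, null_tail / obs_tail) else 1
  }
  # step-up: q must not increase with |NES|
  ord <- order(-abs(nes))
  q_sorted <- q[ord]
  if (length(q_sorted) >= 2) {
    for (j in rev(seq_len(length(q_sorted) - 1))) {
      q_sorted[j] <- min(q_sorted[j], q_sorted[j + 1])
    }
  }
  q[ord] <- q_sorted
  tibble::tibble(set_name = set_names, es = unname(observed_es),
                 nes = nes, p_nominal = p, fdr_q = q, flagged = flagged)
}

# hit positions and weights for one set under a ranking; idx are row indices
# of members in the (unsorted) universe, pos maps row index -> rank,
# wvec = |metric|^w per gene (unsorted)
set_es <- function(idx, pos, wvec, N) {
  hr <- pos[idx]
  o <- order(hr)
  es_core(hr[o], wvec[idx][o], N)
}

#' Run gene set enrichment for one contrast
#'
#' The full engine: ranks genes, computes the weighted-KS score for every
#' set that survives the size filter, builds a permutation null (phenotype
#' relabelling or gene-set resampling), normalizes, and extracts
#' leading-edge subsets. Deterministic given `params$seed`.
#'
#' @param expr An [expression_matrix()] on the log2fpkm scale.
#' @param meta Metadata tibble.
#' @param contrast `c(stage_a, stage_b)`.
#' @param collection A [gene_set_collection()].
#' @param params An [enrichment_params()].
#' @param metric Ranking metric (see [rank_genes()]).
#' @param absolute_mode Rank by metric magnitude (default `TRUE`).
#' @return A tibble of class `gsea_result`, one row per retained set:
#'   `set_name`, `set_size_used`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `peak_rank`, `leading_edge` (list column), `significant` (nominal
#'   p < p_threshold and q < q_threshold). Attributes: `ranked` (the ranked
#'   list), `skipped` (tibble of excluded sets with reasons), `params`,
#'   `contrast`.
#' @export
run_absgsea <- function(expr, meta, contrast, collection,
                        params = enrichment_params(),
                        metric = "signal2noise",
                        absolute_mode = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(collection, "gene_set_collection"),
            inherits(params, "enrichment_params"))
  universe <- rownames(expr$values)
  N <- length(universe)

  overlap <- lapply(collection$sets, function(m) m[m %in% universe])
  sizes <- lengths(overlap)
  reason <- dplyr::case_when(
    sizes == 0 ~ "no overlap",
    sizes < params$min_set_size ~ "below min_set_size",
    sizes > params$max_set_size ~ "above max_set_size",
    TRUE ~ NA_character_
  )
  skipped <- tibble::tibble(set_name = names(collection$sets),
                            reason = reason)[!is.na(reason), ]
  keep <- is.na(reason)
  if (!any(keep)) {
    stop("no gene set survives the size filter (",
         params$min_set_size, "-", params$max_set_size, ")", call. = FALSE)
  }
  sets <- overlap[keep]

  ranked <- rank_genes(expr, meta, contrast, metric = metric,
                       absolute_mode = absolute_mode)
  X <- expr$values
  ids_a <- meta$sample_id[meta$stage == contrast[1]]
  ids_b <- meta$sample_id[meta$stage == contrast[2]]
  cols <- match(c(ids_a, ids_b), colnames(X))
  n_a <- length(ids_a)

  metric_obs <- gene_metric(X, match(ids_a, colnames(X)),
                            match(ids_b, colnames(X)), metric)
  if (absolute_mode) metric_obs <- abs(metric_obs)
  wexp <- params$weight_exponent
  wvec <- abs(metric_obs)^wexp
  ord <- order(-metric_obs, universe)
  pos <- integer(N); pos[ord] <- seq_len(N)
  idx_list <- lapply(sets, function(m) match(m, universe))

  obs <- lapply(idx_list, set_es, pos = pos, wvec = wvec, N = N)
  es_obs <- vapply(obs, `[[`, numeric(1), "es")
  peak <- vapply(obs, function(o) as.integer(o$peak_rank), integer(1))

  n_perm <- params$n_permutations
  null_es <- matrix(NA_real_, length(sets), n_perm,
                    dimnames = list(names(sets), NULL))
  set.seed(params$seed)
  if (params$permutation_mode == "phenotype") {
    for (b in seq_len(n_perm)) {
      perm <- sample(cols)
      r <- gene_metric(X, perm[seq_len(n_a)], perm[-seq_len(n_a)], metric)
      if (absolute_mode) r <- abs(r)
      wv <- abs(r)^wexp
      po <- integer(N); po[order(-r, universe)] <- seq_len(N)
      for (j in seq_along(idx_list)) {
        null_es[j, b] <- set_es(idx_list[[j]], po, wv, N)$es
      }
    }
  } else {
    for (j in seq_along(idx_list)) {
      k <- length(idx_list[[j]])
      for (b in seq_len(n_perm)) {
        idx <- sample.int(N, k)
        null_es[j, b] <- set_es(idx, pos, wvec, N)$es
      }
    }
  }

  sig <- gsea_significance(es_obs, null_es, set_names = names(sets))
  le <- lapply(seq_along(sets), function(j) {
    leading_edge(ranked, sets[[j]], peak[j], sign(es_obs[j]))
  })
  out <- dplyr::mutate(
    sig,
    set_size_used = lengths(sets),
    peak_rank = peak,
    members_used = unname(sets),
    leading_edge = le,
    significant = .data$p_nominal < params$p_threshold &
      .data$fdr_q < params$q_threshold,
    .after = "set_name"
  )
  attr(out, "ranked") <- ranked
  attr(out, "skipped") <- skipped
  attr(out, "params") <- params
  attr(out, "contrast") <- contrast
  class(out) <- c("gsea_result", class(out))
  out
}

#' Per-sample enrichment scores
#'
#' For each sample, genes are ranked by that sample's expression and the
#' score of a set is the integrated difference between the weighted hit
#' ECDF and the miss ECDF over the whole list (single-sample GSEA style).
#' Sets with no overlap score `NA`.
#'
#' @param expr An [expression_matrix()] on the log2fpkm scale.
#' @param collection A [gene_set_collection()].
#' @param weight_exponent Weight on the expression value (default 1).
#' @param min_set_size,max_set_size Size filter on the overlap with the
#'   expression universe.
#' @return A tibble: `sample_id` plus one numeric column per retained set.
#' @export
sample_wise_scores <- function(expr, collection, weight_exponent = 1,
                               min_set_size = 5, max_set_size = 500) {
  stopifnot(inherits(expr, "expression_matrix"))
  universe <- rownames(expr$values)
  N <- length(universe)
  overlap <- lapply(collection$sets, function(m) m[m %in% universe])
  keep <- lengths(overlap) >= min_set_size & lengths(overlap) <= max_set_size
  sets <- overlap[keep]
  if (!length(sets)) stop("no gene set survives the size filter", call. = FALSE)
  idx_list <- lapply(sets, function(m) match(m, universe))
  X <- expr$values
  scores <- matrix(NA_real_, ncol(X), length(sets),
                   dimnames = list(colnames(X), names(sets)))
  for (s in seq_len(ncol(X))) {
    v <- X[, s]
    wv <- abs(v)^weight_exponent
    po <- integer(N); po[order(-v, universe)] <- seq_len(N)
    for (j in seq_along(idx_list)) {
      idx <- idx_list[[j]]
      k <- length(idx)
      hr <- po[idx]
      wt <- wv[idx]
      S <- sum(wt)
      wt <- if (S > 0) wt / S else rep(1 / k, k)
      # integral of the hit ECDF minus the miss ECDF over all N positions
      hit_area <- sum(wt * (N - hr + 1))
      miss_area <- if (N > k) {
        (N * (N + 1) / 2 - sum(N - hr + 1)) / (N - k)
      } else 0
      scores[s, j] <- (hit_area - miss_area) / N
    }
  }
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(X)),
                   tibble::as_tibble(scores))
}
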