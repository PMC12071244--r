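#' Run the full biomarker-discovery pipeline on a synthetic cohort
#'
#' Convenience driver used for end-to-end testing and reproducibility
#' checks: simulates a cohort and gene sets, preprocesses (low-count filter,
#' FPKM, log2), runs Welch differential expression and absolute-mode
#' enrichment for one contrast, prioritizes genes by frequency across
#' significant sets, and applies the biomarker filter cascade. Every
#' stochastic step derives its stream from `seed`, so two runs with the same
#' arguments are identical.
#'
#' @param config A [sim_config()].
#' @param contrast `c(stage_a, stage_b)`; defaults to the first and last
#'   stage of the configured groups.
#' @param n_sets,n_planted,planted_de_fraction,set_size_range Gene-set
#'   simulation parameters (see [simulate_gene_sets()]).
#' @param params An [enrichment_params()].
#' @param top_select Fraction of the frequency ranking retained before the
#'   filter cascade.
#' @param membership_basis Counted membership for frequency analysis.
#' @return A list: `sim`, `collection`, `truth`, `expr`, `de`, `gsea`,
#'   `freq`, `top`, `calls`, `report`.
#' @export
run_pipeline <- function(config = sim_config(),
                         contrast = NULL,
                         n_sets = 50,
                         n_planted = 3,
                         planted_de_fraction = 0.6,
                         set_size_range = c(10, 40),
                         params = enrichment_params(n_permutations = 200,
                                                    seed = config$seed),
                         top_select = 0.20,
                         membership_basis = "leading_edge") {
  sim <- simulate_counts(config)
  if (is.null(contrast)) {
    st <- names(config$group_sizes)
    contrast <- c(st[1], st[length(st)])
  }
  gs <- simulate_gene_sets(sim$truth, universe = gene_ids(sim$counts),
                           n_sets = n_sets, size_range = set_size_range,
                           n_planted = n_planted,
                           planted_de_fraction = planted_de_fraction,
                           seed = config$seed + 1L)
  filtered <- filter_low_counts(sim$counts)
  expr <- log_transform(fpkm_normalize(filtered))
  de <- run_de(expr, filtered, sim$meta, contrast)
  gsea <- run_absgsea(expr, sim$meta, contrast, gs$collection,
                      params = params)
  freq <- tryCatch(
    gene_frequency(gsea, membership_basis = membership_basis),
    error = function(e) NULL
  )
  top <- if (!is.null(freq)) top_fraction(freq, fraction = top_select) else NULL
  calls <- if (!is.null(freq)) biomarker_filter(de, freq) else NULL
  report <- if (!is.null(calls)) stage_signature_report(list(calls)) else NULL
  list(sim = sim, collection = gs$collection, truth = gs$truth,
       expr = expr, de = de, gsea = gsea, freq = freq, top = top,
       calls = calls, report = report)
}
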