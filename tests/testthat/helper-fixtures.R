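# Shared fixture builders; everything is generated in code at test time.

tiny_count_matrix <- function() {
  m <- matrix(c(10L, 5L, 0L,
                2L, 8L, 1L,
                100L, 50L, 25L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("S1", "S2", "S3")))
  count_matrix(m, c(G1 = 1000L, G2 = 500L, G3 = 2000L))
}

tiny_collection <- function() {
  gene_set_collection(
    list(SET_A = c("G1", "G2"), SET_B = c("G2", "G3", "G4")),
    descriptions = c("first", "second"),
    collection_name = "toy"
  )
}

# ranked list with explicit metric values, already sorted
make_ranked <- function(metric, gene_ids = sprintf("g%02d", seq_along(metric))) {
  out <- tibble::tibble(gene_id = gene_ids, metric = metric)
  class(out) <- c("ranked_list", class(out))
  out
}

# Naive O(N) step-by-step running-sum oracle for the weighted-KS statistic.
# Independent of es_core: literal walk down the list.
naive_es <- function(metric, hit, weight_exponent) {
  N <- length(metric)
  k <- sum(hit)
  w <- abs(metric)^weight_exponent
  S <- sum(w[hit])
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + (if (S > 0) w[i] / S else 1 / k)
    } else {
      cur <- cur - (if (N > k) 1 / (N - k) else 0)
    }
    running[i] <- cur
  }
  # same tie conventions as the package states: 1e-12 tolerance, earliest
  # position, positive peak wins an exact tie
  i_pos <- which(running > max(running) - 1e-12)[1]
  i_neg <- which(running < min(running) + 1e-12)[1]
  if (running[i_pos] >= -running[i_neg] - 1e-12) {
    list(es = running[i_pos], peak_rank = i_pos, running_sum = running)
  } else {
    list(es = running[i_neg], peak_rank = i_neg, running_sum = running)
  }
}

# small cohort + expression for enrichment/DE tests
small_cohort <- function(seed = 11, n_genes = 300, n_de = 15, lfc = 2,
                         groups = c(adenoma = 6, CIS = 5, adenocarcinoma = 6)) {
  sim <- simulate_counts(sim_config(
    n_genes = n_genes, group_sizes = groups, n_de_genes = n_de,
    de_log2fc = lfc, seed = seed))
  filtered <- filter_low_counts(sim$counts)
  expr <- log_transform(fpkm_normalize(filtered))
  list(sim = sim, filtered = filtered, expr = expr)
}
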