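test_that("enrichment score matches hand-enumerated single-member cases", {
  ranked <- make_ranked(c(4, 3, 2, 1))
  top <- enrichment_score(ranked, "g01", weight_exponent = 0)
  expect_equal(top$es, 1.0)
  expect_identical(top$peak_rank, 1L)
  bottom <- enrichment_score(ranked, "g04", weight_exponent = 0)
  expect_equal(bottom$es, -1.0)
  expect_identical(bottom$peak_rank, 3L)
  expect_equal(bottom$running_sum, c(-1/3, -2/3, -1, 0), tolerance = 1e-12)
  whole <- enrichment_score(ranked, ranked$gene_id, weight_exponent = 1)
  expect_equal(whole$es, 1.0)
  expect_error(enrichment_score(ranked, "absent"), "no member")
})

test_that("fast ES equals the naive running-sum oracle on exhaustive cases", {
  # every list length <= 8, every member subset of size <= 3, several
  # weight exponents, randomized distinct metric values
  set.seed(41)
  for (N in 2:8) {
    metric <- sort(runif(N, 0.1, 5), decreasing = TRUE)
    ranked <- make_ranked(metric)
    subsets <- unlist(lapply(1:3, function(k) {
      if (k > N) return(NULL)
      asplit(utils::combn(N, k), 2)
    }), recursive = FALSE)
    for (idx in subsets) {
      hit <- seq_len(N) %in% idx
      for (w in c(0, 1, 1.5)) {
        fast <- enrichment_score(ranked, ranked$gene_id[idx],
                                 weight_exponent = w)
        slow <- naive_es(metric, hit, w)
        expect_equal(fast$es, slow$es, tolerance = 1e-12)
        expect_identical(as.integer(fast$peak_rank),
                         as.integer(slow$peak_rank))
        expect_equal(fast$running_sum, slow$running_sum, tolerance = 1e-12)
      }
    }
  }
})

test_that("ES stays within [-1, 1] and tops out on a perfect set", {
  set.seed(43)
  for (rep in 1:50) {
    N <- sample(5:40, 1)
    metric <- sort(abs(rnorm(N)), decreasing = TRUE)
    ranked <- make_ranked(metric)
    k <- sample(1:round(N / 2), 1)
    members <- sample(ranked$gene_id, k)
    es <- enrichment_score(ranked, members, weight_exponent = 1)$es
    expect_gte(es, -1); expect_lte(es, 1)
  }
  ranked <- make_ranked(10:1)
  perfect <- enrichment_score(ranked, ranked$gene_id[1:4], weight_exponent = 0)
  expect_equal(perfect$es, 1.0)
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  vals <- matrix(c(5, 5, 1, 1,
                   5, 5, 1, 1,
                   1, 1, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gB", "gA", "gC"),
                                 c("a1", "a2", "b1", "b2")))
  expr <- expression_matrix(vals, scale = "log2fpkm")
  meta <- sample_metadata(tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    stage = c("adenoma", "adenoma", "adenocarcinoma", "adenocarcinoma")))
  r1 <- rank_genes(expr, meta, c("adenoma", "adenocarcinoma"))
  r2 <- rank_genes(expr, meta, c("adenoma", "adenocarcinoma"))
  expect_identical(r1, r2)
  # gA and gB have identical |metric|; lexicographic order breaks the tie
  tied <- r1$gene_id[r1$metric == max(r1$metric)]
  expect_identical(tied, sort(tied))
  expect_true(all(r1$metric >= 0))  # absolute mode default
  # signed metrics negate under contrast swap; absolute ones do not change
  s1 <- rank_genes(expr, meta, c("adenoma", "adenocarcinoma"),
                   absolute_mode = FALSE)
  s2 <- rank_genes(expr, meta, c("adenocarcinoma", "adenoma"),
                   absolute_mode = FALSE)
  m1 <- s1$metric[match(rownames(vals), s1$gene_id)]
  m2 <- s2$metric[match(rownames(vals), s2$gene_id)]
  expect_equal(m1, -m2, tolerance = 1e-12)
  a2 <- rank_genes(expr, meta, c("adenocarcinoma", "adenoma"))
  expect_identical(r1$gene_id, a2$gene_id)
  expect_equal(r1$metric, a2$metric, tolerance = 1e-12)
})

test_that("leading edge selects members on the peak side of the running sum", {
  ranked <- make_ranked(8:1)
  expect_identical(leading_edge(ranked, "g01", peak_rank = 1, es_sign = 1),
                   "g01")
  members_bottom <- c("g07", "g08")
  es <- enrichment_score(ranked, members_bottom, weight_exponent = 0)
  expect_lt(es$es, 0)
  le <- leading_edge(ranked, members_bottom, es$peak_rank, es$es)
  expect_identical(le, members_bottom)
  # always a subset of the members present in the list
  set.seed(47)
  for (rep in 1:20) {
    members <- sample(ranked$gene_id, sample(2:5, 1))
    es <- enrichment_score(ranked, members, weight_exponent = 1)
    le <- leading_edge(ranked, members, es$peak_rank, es$es)
    expect_true(all(le %in% members))
  }
})

test_that("significance normalization follows the stated conventions", {
  # observed equal to the null mean -> NES 1; observed above every null ->
  # p at the continuity floor 1/(n+1)
  nulls <- matrix(rep(c(0.3, 0.3, 0.4), each = 99), nrow = 3, byrow = TRUE)
  obs <- c(0.3, 0.9, 0.05)
  res <- gsea_significance(obs, nulls, set_names = c("mid", "high", "low"))
  expect_equal(res$nes[1], 1, tolerance = 1e-12)
  expect_equal(res$p_nominal[2], 1 / 100, tolerance = 1e-12)
  expect_equal(res$p_nominal[3], 1)  # every null exceeds it
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  # degenerate all-zero null is flagged with q = 1
  res0 <- gsea_significance(c(0.5), matrix(0, 1, 50))
  expect_true(res0$flagged[1])
  expect_equal(res0$fdr_q[1], 1)
})

test_that("q-values are monotone non-increasing in |NES|", {
  set.seed(53)
  for (rep in 1:10) {
    n_sets <- 40
    obs <- abs(rnorm(n_sets, 0.4, 0.2))
    nulls <- matrix(abs(rnorm(n_sets * 200, 0.3, 0.15)), n_sets, 200)
    res <- gsea_significance(obs, nulls)
    ord <- order(-abs(res$nes))
    expect_true(all(diff(res$fdr_q[ord]) >= -1e-12))
  }
})

test_that("the permutation engine is reproducible and seed-sensitive", {
  co <- small_cohort(seed = 59, n_genes = 150, n_de = 8)
  gs <- simulate_gene_sets(co$sim$truth, gene_ids(co$filtered),
                           n_sets = 10, n_planted = 1, seed = 60)
  p <- enrichment_params(n_permutations = 100, seed = 10)
  r1 <- run_absgsea(co$expr, co$sim$meta, c("adenoma", "adenocarcinoma"),
                    gs$collection, params = p)
  r2 <- run_absgsea(co$expr, co$sim$meta, c("adenoma", "adenocarcinoma"),
                    gs$collection, params = p)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  r3 <- run_absgsea(co$expr, co$sim$meta, c("adenoma", "adenocarcinoma"),
                    gs$collection,
                    params = enrichment_params(n_permutations = 100, seed = 11))
  expect_false(identical(r1$p_nominal, r3$p_nominal))
})

test_that("size filtering reports skipped sets with reasons", {
  co <- small_cohort(seed = 61, n_genes = 100, n_de = 5)
  sets <- list(
    TOO_SMALL = gene_ids(co$filtered)[1:2],
    NO_OVERLAP = c("ZZZ1", "ZZZ2", "ZZZ3", "ZZZ4", "ZZZ5"),
    OK = gene_ids(co$filtered)[3:12]
  )
  col <- gene_set_collection(sets)
  res <- run_absgsea(co$expr, co$sim$meta, c("adenoma", "adenocarcinoma"),
                     col, params = enrichment_params(n_permutations = 100,
                                                     seed = 1))
  expect_identical(res$set_name, "OK")
  skipped <- attr(res, "skipped")
  expect_identical(sort(skipped$set_name), c("NO_OVERLAP", "TOO_SMALL"))
  expect_identical(skipped$reason[skipped$set_name == "NO_OVERLAP"],
                   "no overlap")
  only_small <- gene_set_collection(sets["TOO_SMALL"])
  expect_error(
    run_absgsea(co$expr, co$sim$meta, c("adenoma", "adenocarcinoma"),
                only_small,
                params = enrichment_params(n_permutations = 100, seed = 1)),
    "size filter")
})

test_that("signed-mode ES agrees with fgsea as an independent reference", {
  skip_if_not_installed("fgsea")
  co <- small_cohort(seed = 67, n_genes = 200, n_de = 10)
  meta <- co$sim$meta
  ranked <- rank_genes(co$expr, meta, c("adenoma", "adenocarcinoma"),
                       metric = "signal2noise", absolute_mode = FALSE)
  gs <- simulate_gene_sets(co$sim$truth, gene_ids(co$filtered),
                           n_sets = 8, n_planted = 1, seed = 68)
  stats_vec <- stats::setNames(ranked$metric, ranked$gene_id)
  for (nm in names(gs$collection$sets)) {
    members <- intersect(gs$collection$sets[[nm]], ranked$gene_id)
    mine <- enrichment_score(ranked, members, weight_exponent = 1)
    ref <- fgsea::calcGseaStat(stats_vec,
                               selectedStats = match(members, ranked$gene_id),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine$es, ref, tolerance = 1e-9)
  }
})

test_that("sample-wise scores respond monotonically to member expression", {
  set.seed(71)
  vals <- matrix(abs(rnorm(40 * 2, 3, 1)), 40, 2,
                 dimnames = list(sprintf("g%02d", 1:40), c("S1", "S2")))
  vals[, 2] <- vals[, 1]                       # identical samples
  expr <- expression_matrix(vals, scale = "log2fpkm")
  members <- sprintf("g%02d", 1:8)
  col <- gene_set_collection(list(M = members,
                                  OTHER = sprintf("g%02d", 31:40)))
  sc <- sample_wise_scores(expr, col)
  expect_identical(nrow(sc), 2L)
  expect_equal(sc$M[1], sc$M[2], tolerance = 1e-12)
  # raising the members' expression in S2 strictly increases its score
  vals2 <- vals
  vals2[members, 2] <- vals2[members, 2] + 2
  sc2 <- sample_wise_scores(expression_matrix(vals2, scale = "log2fpkm"), col)
  expect_gt(sc2$M[2], sc2$M[1])
})
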