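test_that("low-count filter is threshold-exact, idempotent, order-preserving", {
  m <- matrix(c(4L, 5L,    # total 9: removed at default threshold
                5L, 5L,    # total 10: kept (>= 10)
                60L, 40L), # total 100: kept
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G9", "G10", "G100"), c("S1", "S2")))
  cm <- count_matrix(m, c(G9 = 1000L, G10 = 1000L, G100 = 1000L))
  f <- filter_low_counts(cm)
  expect_identical(rownames(f$counts), c("G10", "G100"))
  expect_identical(attr(f, "n_removed"), 1L)
  expect_identical(attr(f, "removed_genes"), "G9")
  # idempotent
  f2 <- filter_low_counts(f)
  expect_identical(f2$counts, f$counts)
  # threshold 0 is the identity
  expect_identical(filter_low_counts(cm, 0)$counts, cm$counts)
  # everything below threshold errors
  expect_error(filter_low_counts(cm, 1000), "nothing left")
})

test_that("filter agrees with an independent per-gene summation oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rpois(500, 4), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
    cm <- count_matrix(m, setNames(rep(1000L, 50), rownames(m)))
    kept <- rownames(filter_low_counts(cm, 40)$counts)
    oracle <- rownames(m)[vapply(seq_len(nrow(m)),
                                 function(i) sum(m[i, ]) >= 40, logical(1))]
    expect_identical(kept, oracle)
  }
})

test_that("FPKM matches its definition and hand-computed values", {
  m <- matrix(c(10L, 5L, 999985L), 3, 1,
              dimnames = list(c("A", "B", "filler"), "S1"))
  cm <- count_matrix(m, c(A = 1000L, B = 500L, filler = 1000L))
  # library size is exactly 1e6
  fp <- fpkm_normalize(cm)$values
  expect_equal(fp["A", 1], 10)           # 10 / (1 * 1)
  expect_equal(fp["B", 1], 10)           # 5 / (0.5 * 1)
  expect_identical(fpkm_normalize(cm)$scale, "fpkm")
})

test_that("FPKM is column scale-invariant and inversely proportional to length", {
  set.seed(7)
  m <- matrix(rpois(60, 20) + 1L, 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  lens <- setNames(sample(500:3000, 10), rownames(m))
  f1 <- fpkm_normalize(count_matrix(m, lens))$values
  m2 <- m; m2[, 3] <- m2[, 3] * 7L
  f2 <- fpkm_normalize(count_matrix(m2, lens))$values
  expect_equal(f1[, 3], f2[, 3], tolerance = 1e-12)
  lens2 <- lens; lens2["g4"] <- lens["g4"] * 2L
  f3 <- fpkm_normalize(count_matrix(m, lens2))$values
  expect_equal(f3["g4", ], f1["g4", ] / 2, tolerance = 1e-12)
})

test_that("FPKM rejects zero library sizes and missing lengths", {
  m <- matrix(c(0L, 0L, 5L, 5L), 2, 2,
              dimnames = list(c("A", "B"), c("empty", "ok")))
  m[, "empty"] <- 0L
  cm <- count_matrix(m, c(A = 100L, B = 100L))
  expect_error(fpkm_normalize(cm), "zero library")
})

test_that("log transform matches log2(x + pseudocount) and is monotone", {
  m <- matrix(c(0L, 3L, 10L, 999987L), 4, 1,
              dimnames = list(c("z", "three", "ten", "fill"), "S1"))
  cm <- count_matrix(m, setNames(rep(1000L, 4), rownames(m)))
  fp <- fpkm_normalize(cm)
  lg <- log_transform(fp)
  expect_identical(lg$scale, "log2fpkm")
  expect_equal(lg$values["z", 1], 0)                    # log2(0 + 1)
  expect_equal(lg$values["three", 1], log2(fp$values["three", 1] + 1))
  expect_true(all(diff(lg$values[order(fp$values[, 1]), 1]) >= 0))
  expect_error(log_transform(fp, pseudocount = 0), "pseudocount")
  expect_error(log_transform(lg), "fpkm")
})

test_that("PCA reconstructs the centered matrix and orders variance", {
  co <- small_cohort(seed = 13, n_genes = 60,
                     groups = c(adenoma = 4, CIS = 3, adenocarcinoma = 4))
  expr <- co$expr
  k <- min(dim(expr$values)) - 1
  pc <- run_pca(expr, n_components = k, meta = co$sim$meta)
  ev <- attr(pc, "explained_variance_fraction")
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)
  # SVD identity: scores %*% t(rotation) reproduces the centered data
  X <- t(expr$values)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- as.matrix(tibble::as_tibble(pc)[paste0("PC", 1:k)])
  recon <- S %*% t(attr(pc, "rotation"))
  expect_equal(unname(recon), unname(Xc[, , drop = FALSE]), tolerance = 1e-8)
  expect_error(run_pca(expr, n_components = 100), "exceeds")
})

test_that("two samples yield one component carrying all the variance", {
  m <- matrix(c(5L, 50L, 20L, 10L, 40L, 80L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  expr <- log_transform(fpkm_normalize(
    count_matrix(m, c(a = 1000L, b = 1000L, c = 1000L))))
  pc <- run_pca(expr, n_components = 1)
  expect_equal(attr(pc, "explained_variance_fraction")[1], 1, tolerance = 1e-12)
})

test_that("hierarchical clustering merges closest items first", {
  # Euclidean: d(A,B) = 1 < d(A,C) = d(B,C)
  vals <- matrix(c(0, 0.995, 5,
                   1, 0,     4,
                   2, 2.005, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("A", "B", "C")))
  expr <- expression_matrix(vals, scale = "log2fpkm")
  tree <- hierarchical_cluster(expr, axis = "samples", distance = "euclidean")
  first_pair <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first_pair, c("A", "B"))
  expect_true(all(diff(tree$height) >= -1e-12))
  # identical samples merge at height zero (correlation distance)
  vals2 <- cbind(vals, A2 = vals[, "A"])
  tree2 <- hierarchical_cluster(expression_matrix(vals2, scale = "log2fpkm"),
                                axis = "samples")
  expect_lt(tree2$height[1], 1e-12)
})

test_that("average-linkage heights match a naive O(n^3) agglomeration", {
  naive_average_hclust <- function(d) {
    # d: full symmetric distance matrix; returns sorted merge heights
    active <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(NA, NA); best_h <- Inf
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (i >= j) next
        h <- mean(d[active[[i]], active[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
      heights <- c(heights, best_h)
      merged <- c(active[[best[1]]], active[[best[2]]])
      active <- active[-best]
      active[[length(active) + 1]] <- merged
    }
    heights
  }
  set.seed(17)
  for (rep in 1:3) {
    vals <- matrix(rnorm(8 * 5), 8, 5,
                   dimnames = list(paste0("i", 1:8), paste0("v", 1:5)))
    expr <- expression_matrix(abs(vals), scale = "fpkm")
    tree <- hierarchical_cluster(expr, axis = "genes", distance = "euclidean",
                                 linkage = "average")
    d <- as.matrix(dist(abs(vals)))
    expect_equal(tree$height, naive_average_hclust(d), tolerance = 1e-10)
  }
})

test_that("correlation distance refuses zero-variance items", {
  vals <- matrix(c(1, 1, 1, 2, 5, 3), 2, 3, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), c("A", "B", "C")))
  expr <- expression_matrix(vals, scale = "fpkm")
  expect_error(hierarchical_cluster(expr, axis = "genes"), "euclidean")
})
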