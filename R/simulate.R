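# Synthetic cohorts with recorded ground truth. Every planted effect is
# written into the returned ground-truth object; generators are pure
# functions of (config, seed).

#' Simulation configuration
#'
#' Defines a synthetic three-stage cohort. Defaults emulate a small FFPE
#' biopsy series: 10 adenoma, 8 carcinoma in situ (CIS) and 11 adenocarcinoma
#' samples, overdispersed negative-binomial counts with sample-specific
#' library-size factors, and stage-specific differentially expressed genes
#' planted at a configurable log2 fold change.
#'
#' The negative binomial is parameterized by mean `mu` and size `k`
#' (`dispersion` stores `k`), so the variance is `mu + mu^2 / k`; large `k`
#' approaches Poisson.
#'
#' @param n_genes Number of genes simulated.
#' @param group_sizes Named integer vector mapping stage label to sample
#'   count; each must be >= 2 (Welch needs two per group).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters (natural
#'   log) for per-gene baseline mean counts.
#' @param dispersion Negative-binomial size parameter `k` (> 0).
#' @param library_size_range Length-2 positive range; per-sample library
#'   factors are drawn log-uniform within it.
#' @param n_de_genes Number of stage-signature genes planted per stage
#'   (disjoint across stages; half up, half down).
#' @param de_log2fc Absolute log2 fold change applied to each planted gene in
#'   its stage; `0` gives a null cohort.
#' @param gene_length_range_bp Length-2 integer range for transcript lengths.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(adenoma = 10, CIS = 8, adenocarcinoma = 11),
                       baseline_log_mean = log(80),
                       baseline_log_sd = 1,
                       dispersion = 10,
                       library_size_range = c(0.5, 2),
                       n_de_genes = 50,
                       de_log2fc = 2,
                       gene_length_range_bp = c(500L, 4000L),
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(group_sizes) >= 2,
            !is.null(names(group_sizes)),
            dispersion > 0, length(library_size_range) == 2,
            all(library_size_range > 0),
            de_log2fc >= 0, is.finite(de_log2fc),
            n_de_genes >= 0,
            length(gene_length_range_bp) == 2,
            all(gene_length_range_bp >= 1))
  if (any(group_sizes < 2)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (n_de_genes * length(group_sizes) > n_genes) {
    stop("n_de_genes per stage exceed available genes", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         group_sizes = group_sizes,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         dispersion = dispersion,
         library_size_range = library_size_range,
         n_de_genes = as.integer(n_de_genes),
         de_log2fc = de_log2fc,
         gene_length_range_bp = as.integer(gene_length_range_bp),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a stage-labelled count matrix with known ground truth
#'
#' Counts are drawn negative-binomial with mean
#' `baseline_mean_g * library_factor_s * 2^(lfc_{g,stage})`. Each stage
#' receives a disjoint block of `n_de_genes` signature genes whose mean is
#' shifted by `+/- de_log2fc` (half up, half down) in that stage only, so
#' every pairwise contrast carries the signature genes of its two stages.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{[count_matrix()]}
#'     \item{meta}{metadata tibble (see [sample_metadata()])}
#'     \item{truth}{ground truth: `de_genes` tibble (contrast stages, gene,
#'       true oriented log2 fold change, direction), `stage_genes` tibble
#'       (stage, gene, signed planted lfc), plus the config}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, n_de_genes = 5, seed = 42))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  stages <- names(config$group_sizes)
  n_s <- sum(config$group_sizes)
  gene_id <- sprintf("G%04d", seq_len(G))
  samp_id <- sprintf("S%02d", seq_len(n_s))
  stage_of <- rep(stages, times = config$group_sizes)

  base_mean <- stats::rlnorm(G, config$baseline_log_mean, config$baseline_log_sd)
  lib <- exp(stats::runif(n_s, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  lengths <- sample(seq(config$gene_length_range_bp[1],
                        config$gene_length_range_bp[2]), G, replace = TRUE)

  # disjoint stage-signature blocks, half up / half down within each
  lfc <- matrix(0, G, length(stages), dimnames = list(gene_id, stages))
  stage_genes <- NULL
  if (config$n_de_genes > 0) {
    picked <- sample(G, config$n_de_genes * length(stages))
    blocks <- split(picked, rep(seq_along(stages), each = config$n_de_genes))
    for (i in seq_along(stages)) {
      idx <- blocks[[i]]
      n_up <- ceiling(length(idx) / 2)
      sgn <- rep(c(1, -1), c(n_up, length(idx) - n_up))
      lfc[idx, i] <- sgn * config$de_log2fc
      stage_genes <- rbind(stage_genes,
                           data.frame(stage = stages[i],
                                      gene_id = gene_id[idx],
                                      planted_log2fc = sgn * config$de_log2fc))
    }
  }

  mu <- outer(base_mean, lib) * 2^lfc[, match(stage_of, stages)]
  counts <- matrix(stats::rnbinom(G * n_s, mu = mu, size = config$dispersion),
                   G, n_s, dimnames = list(gene_id, samp_id))

  meta <- sample_metadata(
    tibble::tibble(sample_id = samp_id, stage = stage_of),
    stages = stages
  )

  # per-contrast oriented truth: log2fc of later stage over earlier stage
  de <- NULL
  pairs <- utils::combn(seq_along(stages), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    delta <- lfc[, b] - lfc[, a]
    hit <- which(delta != 0 | (config$de_log2fc == 0 & lfc[, a] != lfc[, b]))
    if (config$de_log2fc == 0 && !is.null(stage_genes)) {
      # null cohort: record the planted (zero-effect) genes of both stages
      hit <- match(unique(stage_genes$gene_id[
        stage_genes$stage %in% stages[c(a, b)]]), gene_id)
    }
    if (length(hit)) {
      de <- rbind(de, data.frame(
        stage_a = stages[a], stage_b = stages[b],
        gene_id = gene_id[hit],
        true_log2fc = delta[hit],
        direction = ifelse(delta[hit] > 0, "up",
                           ifelse(delta[hit] < 0, "down", "null"))
      ))
    }
  }
  truth <- list(
    de_genes = tibble::as_tibble(de %||% data.frame(
      stage_a = character(), stage_b = character(), gene_id = character(),
      true_log2fc = numeric(), direction = character())),
    stage_genes = tibble::as_tibble(stage_genes %||% data.frame(
      stage = character(), gene_id = character(), planted_log2fc = numeric())),
    config = config
  )

  list(counts = count_matrix(counts, stats::setNames(lengths, gene_id)),
       meta = meta,
       truth = truth)
}

#' Simulate a gene set collection with planted enriched sets
#'
#' `n_planted` sets draw at least `planted_de_fraction` of their members from
#' the planted differentially expressed genes of one stage contrast (sets are
#' assigned to contrasts round-robin); the remaining members, and all
#' background sets, are drawn uniformly from the gene universe.
#'
#' @param truth Ground truth from [simulate_counts()].
#' @param universe Character vector of candidate member gene ids (usually all
#'   simulated genes).
#' @param n_sets Total number of sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param n_planted Number of enriched sets planted (<= n_sets).
#' @param planted_de_fraction Fraction in `[0, 1]` of each planted set's
#'   members drawn from that contrast's DE genes.
#' @param seed Integer seed.
#' @return A list: `collection` ([gene_set_collection()]) and `truth` with an
#'   added `enriched_sets` tibble (set name, stage_a, stage_b).
#' @export
simulate_gene_sets <- function(truth, universe,
                               n_sets = 50,
                               size_range = c(10, 40),
                               n_planted = 3,
                               planted_de_fraction = 0.6,
                               seed = 1L) {
  stopifnot(planted_de_fraction >= 0, planted_de_fraction <= 1,
            n_planted <= n_sets, length(size_range) == 2)
  if (max(size_range) > length(universe)) {
    stop("set size range exceeds universe size", call. = FALSE)
  }
  de <- truth$de_genes
  missing_de <- setdiff(unique(de$gene_id), universe)
  if (length(missing_de)) {
    stop("universe does not cover all planted DE genes", call. = FALSE)
  }
  set.seed(seed)
  contrasts <- unique(de[c("stage_a", "stage_b")])
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  planted_rows <- NULL
  for (i in seq_len(n_sets)) {
    size <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1)
    if (i <= n_planted && nrow(contrasts) > 0 && planted_de_fraction > 0) {
      ctr <- contrasts[((i - 1) %% nrow(contrasts)) + 1, ]
      pool <- de$gene_id[de$stage_a == ctr$stage_a & de$stage_b == ctr$stage_b]
      n_from_de <- min(ceiling(planted_de_fraction * size), length(pool))
      members_de <- sample(pool, n_from_de)
      rest <- sample(setdiff(universe, members_de), size - n_from_de)
      sets[[i]] <- sample(c(members_de, rest))
      planted_rows <- rbind(planted_rows,
                            data.frame(set_name = names(sets)[i],
                                       stage_a = ctr$stage_a,
                                       stage_b = ctr$stage_b))
    } else {
      sets[[i]] <- sample(universe, size)
      if (i <= n_planted) {
        # planted_de_fraction == 0 degenerates to background draws
        planted_rows <- rbind(planted_rows,
                              data.frame(set_name = names(sets)[i],
                                         stage_a = NA_character_,
                                         stage_b = NA_character_))
      }
    }
  }
  truth$enriched_sets <- tibble::as_tibble(
    planted_rows %||% data.frame(set_name = character(),
                                 stage_a = character(),
                                 stage_b = character()))
  list(collection = gene_set_collection(sets, collection_name = "synthetic"),
       truth = truth)
}

#' Simulate a cell-type signature matrix
#'
#' Block-marker design emulating the shape of the LM22 leukocyte signature
#' (547 genes x 22 hematopoietic cell types by default): each cell type
#' receives a block of marker genes with strongly elevated expression over a
#' low shared baseline, yielding a well-conditioned (full column rank)
#' matrix.
#'
#' @param n_genes Number of signature genes (>= `n_cell_types`).
#' @param n_cell_types Number of cell types.
#' @param marker_high Mean expression of a marker gene in its own cell type.
#' @param base_mean Mean background expression elsewhere.
#' @param seed Integer seed.
#' @return A [signature_matrix()].
#' @export
simulate_signature <- function(n_genes = 547, n_cell_types = 22,
                               marker_high = 100, base_mean = 5,
                               seed = 1L) {
  if (n_genes < n_cell_types) {
    stop("need at least one gene per cell type", call. = FALSE)
  }
  set.seed(seed)
  gene_id <- sprintf("SG%04d", seq_len(n_genes))
  types <- sprintf("CT%02d", seq_len(n_cell_types))
  vals <- matrix(stats::rgamma(n_genes * n_cell_types, shape = 2,
                               scale = base_mean / 2),
                 n_genes, n_cell_types, dimnames = list(gene_id, types))
  block <- rep(seq_len(n_cell_types), length.out = n_genes)
  for (k in seq_len(n_cell_types)) {
    idx <- which(block == k)
    vals[idx, k] <- vals[idx, k] +
      stats::rgamma(length(idx), shape = 4, scale = marker_high / 4)
  }
  signature_matrix(vals)
}

#' Simulate bulk mixtures of a signature matrix
#'
#' Fractions are drawn from the flat Dirichlet (uniform on the simplex); the
#' mixture is `signature %*% fractions` plus Gaussian noise with standard
#' deviation `noise_sd_fraction` times the mean signal, truncated at zero.
#'
#' @param signature A [signature_matrix()].
#' @param n_samples Number of mixtures (>= 1).
#' @param noise_sd_fraction Noise level as a fraction of the mean mixture
#'   signal (>= 0).
#' @param seed Integer seed.
#' @return A list: `mixture` ([expression_matrix()], linear scale stored as
#'   fpkm-scale values) and `fractions` tibble (sample_id, one column per
#'   cell type; rows sum to 1).
#' @export
simulate_mixtures <- function(signature, n_samples, noise_sd_fraction = 0.05,
                              seed = 1L) {
  stopifnot(inherits(signature, "signature_matrix"),
            noise_sd_fraction >= 0)
  if (n_samples < 1) stop("need at least one mixture sample", call. = FALSE)
  set.seed(seed)
  B <- signature$values
  K <- ncol(B)
  samp_id <- sprintf("M%03d", seq_len(n_samples))
  # flat Dirichlet via normalized unit-rate gamma draws
  g <- matrix(stats::rgamma(n_samples * K, shape = 1), n_samples, K)
  fr <- g / rowSums(g)
  mix <- B %*% t(fr)
  if (noise_sd_fraction > 0) {
    sd <- noise_sd_fraction * mean(mix)
    mix <- mix + matrix(stats::rnorm(length(mix), 0, sd), nrow(mix))
    mix[mix < 0] <- 0
  }
  dimnames(mix) <- list(rownames(B), samp_id)
  colnames(fr) <- colnames(B)
  fractions <- dplyr::bind_cols(tibble::tibble(sample_id = samp_id),
                                tibble::as_tibble(fr))
  list(mixture = expression_matrix(mix, scale = "fpkm"),
       fractions = fractions)
}
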