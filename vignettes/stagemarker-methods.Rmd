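---
title: "Methods: stage-specific biomarker discovery from bulk RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific biomarker discovery from bulk RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagemarker)
```

# Overview

`stagemarker` implements a complete discovery pipeline for stage-specific
transcriptomic biomarkers in the colorectal adenoma → carcinoma in situ
(CIS) → adenocarcinoma progression sequence, working from a raw gene ×
sample read-count matrix. The stages of the pipeline are:

1. **Preprocessing** — low-count filtering, FPKM normalization, log2
   transform, PCA and hierarchical clustering QC.
2. **Differential expression** — per-gene Welch unequal-variance t-tests
   between stage pairs, with log2 fold-change and significance thresholds.
3. **Enrichment** — a weighted Kolmogorov–Smirnov gene set enrichment
   engine with an *absolute* (direction-agnostic) ranking mode, permutation
   significance, and leading-edge extraction.
4. **Prioritization** — gene-frequency counting across significant sets,
   top-fraction selection, and a four-criterion biomarker filter cascade.
5. **Deconvolution** — immune cell-type fraction estimation against a
   signature matrix by non-negative least squares.
6. **qPCR support** — 2^−ΔΔCt relative quantification for wet-lab
   validation data.

A synthetic-data module generates cohorts, gene-set collections and immune
mixtures with fully recorded ground truth, so every downstream stage is
testable without access to patient data.

# Preprocessing

Genes with fewer than 10 total reads across all samples are removed
(`filter_low_counts()`, threshold configurable); the filter is idempotent
and order-preserving. FPKM is then

$$\mathrm{FPKM}_{gs} = \frac{c_{gs}}{(\ell_g/10^3)\,(N_s/10^6)},$$

with $c_{gs}$ the read count, $\ell_g$ the transcript length in bp and
$N_s$ the library size. Library sizes are the column totals of the matrix
*after* filtering (the exclusion precedes normalization in the pipeline
order); since the filter removes only near-empty genes the difference from
pre-filter totals is negligible, but the choice is fixed and documented
here. FPKM is invariant to rescaling a sample's counts and inversely
proportional to gene length — both are asserted in the test suite at
1e-12.

Downstream statistics operate on $\log_2(\mathrm{FPKM} + 1)$. The
pseudocount of 1 keeps zeros at zero on the log scale and bounds the
fold-change contribution of weakly expressed genes. PCA
(`run_pca()`) is computed by SVD of the sample × gene matrix, gene-centered
but not unit-scaled: after log transformation the variance structure is
already comparable across genes, and unit scaling would up-weight
near-constant genes. Hierarchical clustering defaults to 1 − Pearson
correlation distance with average linkage, the common choice for
expression heatmaps; Euclidean distance is available and is required when
items have zero variance.

# Differential expression

For each gene the two stage groups are compared with Welch's
unequal-variance t-statistic on log2 FPKM,

$$t = \frac{\bar{x}_B - \bar{x}_A}{\sqrt{s_B^2/n_B + s_A^2/n_A}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
t-tests on raw counts would violate the variance assumptions badly;
raw-count group means are nevertheless carried through the table because
the biomarker expression-floor filter is defined on raw counts. Zero
variance in both groups with equal means yields the convention $t = 0,
p = 1$ and a `degenerate` flag rather than a dropped row, keeping table
shapes stable.

The log2 fold change is oriented later-stage over earlier-stage and
computed from group mean FPKM with a pseudocount:
$\log_2((\bar{m}_B + 1)/(\bar{m}_A + 1))$. This form is exactly
antisymmetric under contrast reversal, which the suite asserts.

DEGs are called with strict inequalities, p < 0.05 and |log2FC| > 1.5, on
*unadjusted* p-values by default: the pipeline deliberately prioritizes
sensitivity at this stage because enrichment analysis downstream provides
pathway-level refinement. Benjamini–Hochberg adjusted values are always
computed and can drive the thresholds via a flag; both conventions appear
in practice and the default is documented rather than silently chosen.

qPCR measurements are reduced by the 2^−ΔΔCt method: per sample
ΔCt = target Ct − reference Ct, ΔΔCt is centered on the control group's
mean ΔCt, and the fold change is 2^−ΔΔCt, compared between groups with the
same Welch test.

# Enrichment

`run_absgsea()` ranks genes by a differential metric — by default the
signal-to-noise ratio $(\mu_B - \mu_A)/(\sigma_A + \sigma_B)$ with each
standard deviation floored at $\max(\sigma, 0.2|\mu|, 10^{-8})$, the usual
guard when group sizes are in the 8–11 range — and in absolute mode ranks
by the metric's magnitude, so sets perturbed in either direction enrich at
the top. Ties are broken lexicographically by gene id, making every
ranking deterministic.

The enrichment score of a set is the classical weighted-KS running sum:
walking down the list, member genes add $|r_g|^w / \sum_{members}|r|^w$
and non-members subtract $1/(N - N_{hits})$; the ES is the running-sum
value of maximal absolute deviation, with an exact tie between positive
and negative peaks resolved to the positive one (ties are compared with a
1e-12 tolerance so that algebraically equal excursions computed in
different summation orders resolve identically). The implementation is an
O(set size) closed form over hit positions; the test suite proves it
equal to a literal step-by-step enumeration over every list length ≤ 8 and
member subset of size ≤ 3.

Significance comes from a permutation null, in two modes:

- **phenotype** (default): stage labels are permuted within the contrast
  and the entire ranking recomputed per permutation. This preserves
  gene–gene correlation and is the default recommendation for cohorts of
  this size.
- **gene_set**: member labels are resampled uniformly from the universe,
  giving a size-matched null that is independent across sets.

NES divides the observed ES by the mean of its same-sign null scores (a
single sign in absolute mode). The nominal p-value is continuity-corrected,
$(1 + \#\{|null| > |ES|\})/(1 + n)$, so an observation at the maximum of
its own null sample reports $1/(n+1)$. The FDR q-value follows the
permutation convention of pooling all per-set-normalized null scores: the
tail fraction of pooled null NES at least as extreme, divided by the tail
fraction of observed NES at least as extreme, clipped to [0, 1], followed
by a step-up pass that makes q monotone non-increasing in |NES| (the
q-value reading: the smallest estimated FDR among thresholds at least as
permissive). Sets are flagged significant at nominal p < 0.05 **and**
q < 0.25. Set-size filtering defaults to 5–500 members of the expression
universe; skipped sets are reported with reasons, never dropped silently.

The choice of permutation mode matters under strong global signal: with
many large planted effects, phenotype relabelling leaves differential
genes with elevated metric magnitudes (their bimodal expression inflates
permuted group-mean differences), so sets rich in true signal also have
inflated null means and *deflated* NES relative to clean background sets.
The ground-truth recovery benchmarks in the test suite therefore run in
gene-set mode, where the null is size-matched and independent of a set's
actual members; the same mode underlies the null-calibration check, since
phenotype-mode p-values across sets share one relabelling stream and are
not exchangeable with independent uniforms. Phenotype mode remains the
default for ordinary analysis.

The leading edge of a positively enriched set is its members at or before
the running-sum peak (after it, for negative ES) — the genes that actually
drive the signal. `sample_wise_scores()` additionally provides
single-sample scores (the integrated difference between the weighted hit
ECDF and the miss ECDF of each sample's own expression ranking), the
per-sample view of enrichment.

# Prioritization and the filter cascade

`gene_frequency()` counts, for each gene, the number of significant sets
containing it, by default over leading-edge membership (the genes driving
each signal) with full-set membership as an option. `top_fraction()` keeps
the first $\lceil 0.20 \cdot G \rceil$ genes of the frequency ranking and
expands the cut to include all genes tied with the last included
frequency, so selection never depends on the order of tied genes; an
absolute cutoff (e.g. top 20 genes) is also supported because both usages
occur.

`biomarker_filter()` applies four criteria per gene, each recorded
separately so a failure is attributable:

1. Welch p < 0.05 (strict);
2. |log2FC| > 1.5 (strict);
3. expression floor: mean raw count strictly above 100 in the
   higher-expressing group and at least 30 in the other — a guard against
   fold changes driven by near-zero expression in degraded FFPE material.
   The asymmetric strictness (> 100, ≥ 30) mirrors the stated
   thresholds exactly; the "higher-expressing group" is decided by the
   raw-count means, independent of fold-change orientation;
4. membership in ≥ 2 significant pathways.

A gene is selected iff all four hold. `stage_signature_report()`
reorganizes per-contrast calls into per-stage marker lists (a gene up in
the later stage belongs to that stage); genes claimed by different stages
across contrasts are flagged as conflicts rather than silently resolved.

# Deconvolution

The mixture model is linear on the natural scale: $m = B\beta +
\varepsilon$ with $B$ the signature matrix (by default shaped like the
LM22 leukocyte signature, 547 genes × 22 hematopoietic cell types).
`deconvolve()` solves non-negative least squares per sample over the genes
shared with the signature and renormalizes to the simplex, reporting the
residual norm and the correlation between fitted and observed values. This
is a deliberate, documented estimator choice: it has exact recovery
guarantees on noise-free mixtures (asserted at 1e-6) and known behaviour
under noise, which is what a reproducible benchmark needs. ν-SVR-based
estimators with feature selection are out of scope. Log-scale input is
detected and exponentiated back with a warning, since the model is linear.

# The synthetic-data generator

`simulate_counts()` emulates the cohort shape of a three-stage FFPE biopsy
series: by default 10 adenoma, 8 CIS and 11 adenocarcinoma samples. Counts
are negative binomial with mean $\mu_{gs} = b_g \cdot f_s \cdot
2^{\lambda_{g,\mathrm{stage}(s)}}$ and variance $\mu + \mu^2/k$ (the
`dispersion` field stores $k$; large $k$ approaches Poisson — asserted via
the variance-to-mean ratio in the suite). Baselines $b_g$ are log-normal;
library factors $f_s$ are log-uniform in 0.5–2× to emulate the depth
variability of archival material — a stand-in for a quantitative FFPE
noise model that the source data do not provide. Each stage receives a
disjoint block of `n_de_genes` signature genes shifted by ±`de_log2fc`
(half up, half down) in that stage only; a pairwise contrast therefore
carries the blocks of both its stages with oriented effects, and every
planted effect is recorded in the returned ground truth. With
`de_log2fc = 0` the generator produces an exact null cohort: planted genes
are still recorded (with zero effect) so type-I-error tests can interrogate
them.

`simulate_gene_sets()` plants `n_planted` sets drawing at least
`planted_de_fraction` of their members from one contrast's DE genes
(round-robin across contrasts) and fills the rest uniformly;
`simulate_signature()` builds a block-marker signature (each cell type a
block of elevated marker genes over a low shared gamma baseline, full
column rank across seeds); `simulate_mixtures()` draws fractions from the
flat Dirichlet and adds truncated Gaussian noise scaled to the mean
signal.

What the generator does *not* model: read-level FFPE degradation,
batch effects, gene–gene correlation beyond what planted effects induce,
and mutational genotypes. Passing recovery tests on this generator
demonstrates the pipeline's statistical machinery — calibration, power at
the planted effect sizes, exactness of the deterministic stages — not
performance on any particular patient cohort.

# Numerical choices and problem sizes

- ES ties and sign selection use a 1e-12 tolerance; positive peak wins an
  exact tie; tied metric values rank lexicographically by gene id.
- Permutation p-values are continuity-corrected and can never be 0.
- All generators and the permutation engine are pure functions of their
  seed; the suite asserts bit-identical results across repeated runs.
- The recovery benchmarks in the test suite use 2,000-gene cohorts of
  10 vs 10 samples with 500 permutations (enrichment recovery), 800-gene
  cohorts with 300 permutations (biomarker cascade recovery, with the
  baseline mean raised to log(400) and σ = 0.25 so that down-regulated
  planted genes clear the 30-count floor), and 20 seeded replicates each —
  sizes at which the planted effects are comfortably identifiable and a
  full run of the suite stays fast.

# Known limitations

- The Welch path is the implemented DE statistic; no negative-binomial GLM
  or shrinkage estimation is provided, so very-low-count genes rely on the
  log transform and the expression floor downstream.
- FDR q-values inherit the granularity of the permutation count; with
  n_perm below a few hundred they are unstable (the constructor warns
  below 100).
- The deconvolution estimator does not model platform batch effects or
  perform feature selection; gene overlap with the signature is by exact
  identifier match.
- Stage assignment in the report is per-contrast majority-free: any
  cross-contrast inconsistency is surfaced as a conflict for the analyst
  rather than auto-resolved.
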