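#' Configuration for the PLINK-style set-based test
#'
#' Defaults mirror PLINK's set test: tag SNPs pruned at pairwise r-squared
#' 0.5, pathway statistic = mean allelic chi-square of tag SNPs with
#' per-SNP p below 0.05, significance from phenotype permutations.
#'
#' @param r2_threshold Pairwise r-squared at or above which a SNP is pruned
#'   by an already-selected tag (default 0.5).
#' @param snp_p_cut Per-SNP p-value cut for entering the mean (default 0.05).
#' @param n_permutations Number of phenotype permutations K (default 2000).
#' @param seed Integer seed for the permutation stream.
#' @param prune_per_permutation Re-run the (phenotype-aware) greedy tag
#'   selection inside every permutation (default `TRUE`, which keeps the
#'   permutation null exchangeable with the observed pipeline).  `FALSE`
#'   freezes the observed tags for all permutations, for sensitivity
#'   analysis.
#' @return An object of class `set_test_config`.
#' @export
set_test_config <- function(r2_threshold = 0.5, snp_p_cut = 0.05,
                            n_permutations = 2000, seed = 1,
                            prune_per_permutation = TRUE) {
  stopifnot(is_prob(r2_threshold), is_prob(snp_p_cut))
  if (!is_count(n_permutations)) abort("`n_permutations` must be >= 1")
  if (!is_count(seed, min = 0)) abort("`seed` must be a non-negative integer")
  structure(
    list(r2_threshold = r2_threshold, snp_p_cut = snp_p_cut,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         prune_per_permutation = isTRUE(prune_per_permutation)),
    class = "set_test_config"
  )
}

# Allelic chi-square statistics for all columns of a dosage matrix at once.
# The 2x2 table per SNP counts minor/major alleles in cases and controls
# (allele counts: sum of dosages vs 2n minus that); Pearson chi-square with
# 1 df and no continuity correction.  Monomorphic SNPs score 0 with p = 1.
chisq_stats <- function(X, y, mtot = colSums(X)) {
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  a <- as.vector(crossprod(X, y))        # minor alleles in cases
  b <- mtot - a                          # minor alleles in controls
  A1 <- 2 * n1
  A0 <- 2 * n0
  N <- A1 + A0
  m <- a + b
  stat <- rep(0, ncol(X))
  poly <- m > 0 & m < N
  num <- (a[poly] * (A0 - b[poly]) - b[poly] * (A1 - a[poly]))^2
  stat[poly] <- N * num / (A1 * A0 * m[poly] * (N - m[poly]))
  p <- rep(1, ncol(X))
  p[poly] <- pchisq(stat[poly], df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

#' Allelic chi-square test of single-SNP association
#'
#' One-degree-of-freedom Pearson chi-square on the 2x2 allele-count table
#' (minor vs major allele counts in cases vs controls, allele counts taken as
#' the sum of dosages), without continuity correction — the classic allelic
#' association test.  Monomorphic SNPs return statistic 0 and p-value 1.
#'
#' @param dosages A dosage vector (one SNP) or matrix (SNPs in columns).
#' @param phenotype 0/1 phenotype vector.
#' @return A tibble with one row per SNP: `snp_id` (when column names exist),
#'   `statistic`, `p_value`.
#' @export
allelic_chisq <- function(dosages, phenotype) {
  if (!is.matrix(dosages)) dosages <- matrix(dosages, ncol = 1)
  phenotype <- as.integer(phenotype)
  stopifnot(nrow(dosages) == length(phenotype),
            all(phenotype %in% c(0L, 1L)))
  if (length(unique(phenotype)) < 2) {
    abort("phenotype must contain both cases and controls")
  }
  cs <- chisq_stats(dosages, phenotype)
  out <- tibble(statistic = cs$statistic, p_value = cs$p_value)
  if (!is.null(colnames(dosages))) {
    out <- dplyr::bind_cols(tibble(snp_id = colnames(dosages)), out)
  }
  out
}

#' Composite-genotype linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors.  Defined as 0 when
#' either vector is constant.
#'
#' @param snp_a,snp_b Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(snp_a, snp_b) {
  stopifnot(length(snp_a) == length(snp_b))
  if (stats::sd(snp_a) == 0 || stats::sd(snp_b) == 0) return(0)
  cor(snp_a, snp_b)^2
}

# r-squared matrix with the constant-column convention (0) applied
r2_matrix <- function(X) {
  sds <- apply(X, 2, stats::sd)
  r2 <- suppressWarnings(cor(X))^2
  r2[is.na(r2)] <- 0
  r2[sds == 0, ] <- 0
  r2[, sds == 0] <- 0
  diag(r2) <- 1
  r2
}

# Greedy tag selection on precomputed per-SNP p-values and r2 matrix:
# repeatedly take the most significant remaining SNP (ties -> smaller column
# index), emit it as a tag, and drop every remaining SNP with r2 >= threshold
# to it.  Walking the SNPs once in significance order (order() is stable, so
# p-value ties resolve to the smaller column index) and skipping pruned ones
# is equivalent to re-scanning the remainder each round.
greedy_tags <- function(p_values, r2, r2_threshold, prunable = NULL) {
  ord <- order(p_values)
  # SNPs whose r2 row never reaches the threshold (beyond the diagonal) can
  # never prune a neighbour; when none can, the greedy walk is just the
  # significance order.  The mask depends only on the genotypes, so callers
  # that permute phenotypes precompute it once.
  if (is.null(prunable)) prunable <- colSums(r2 >= r2_threshold) > 1L
  if (!any(prunable)) return(ord)
  removed <- logical(length(p_values))
  tags <- integer(length(p_values))
  n_tags <- 0L
  for (j in ord) {
    if (removed[j]) next
    n_tags <- n_tags + 1L
    tags[n_tags] <- j
    if (prunable[j]) removed[r2[, j] >= r2_threshold] <- TRUE
    else removed[j] <- TRUE
  }
  tags[seq_len(n_tags)]
}

#' Greedy tag-SNP selection
#'
#' Orders SNPs by allelic chi-square significance and greedily retains a set
#' of tags whose pairwise r-squared stays below the threshold: the most
#' significant remaining SNP becomes a tag and removes every remaining SNP
#' correlated with it at `r2 >= r2_threshold`.  Ties on p-value go to the
#' smaller column index.
#'
#' @param dosages Dosage matrix restricted to the SNP set.
#' @param phenotype 0/1 phenotype vector.
#' @param config A [set_test_config()].
#' @return Integer vector of tag column indices, in selection order.
#' @export
select_tag_snps <- function(dosages, phenotype, config = set_test_config()) {
  stopifnot(is.matrix(dosages), inherits(config, "set_test_config"))
  phenotype <- as.integer(phenotype)
  cs <- chisq_stats(dosages, phenotype)
  greedy_tags(cs$p_value, r2_matrix(dosages), config$r2_threshold)
}

# one pass of the set-based pipeline: chi-squares, tags, pathway statistic
set_stat_once <- function(X, y, r2, cfg, tags = NULL, mtot = colSums(X),
                          prunable = NULL) {
  cs <- chisq_stats(X, y, mtot)
  if (is.null(tags)) {
    tags <- greedy_tags(cs$p_value, r2, cfg$r2_threshold, prunable)
  }
  qual <- tags[cs$p_value[tags] < cfg$snp_p_cut]
  s <- if (length(qual) == 0) 0 else mean(cs$statistic[qual])
  list(statistic = s, tags = tags)
}

#' PLINK-style set-based pathway test
#'
#' Reimplementation of the set-based association test popularised by PLINK:
#' tag SNPs are selected greedily at an r-squared threshold, the pathway
#' statistic is the mean allelic chi-square over tag SNPs with per-SNP p
#' below the cut (0 when none qualifies), and the p-value compares the
#' observed statistic against `K` phenotype permutations that each re-run
#' the entire pipeline (chi-squares, tag selection, statistic).  Larger
#' statistics are more extreme:
#' `p = (1 + #\{S_i >= S_obs\}) / (K + 1)`.
#'
#' @param x A [genotype_matrix()] without missing values.
#' @param snps SNP selection as in [fit_forest()].
#' @param config A [set_test_config()].
#' @param pathway_id Optional label stored in the result.
#' @return An object of class `pathway_test` (see [trf_pathway_test()]) with
#'   `method = "setbased"`, `direction = "greater"`, `statistic` the mean
#'   chi-square `S`, and `selected` the observed tag SNP ids.
#' @export
set_based_test <- function(x, snps = NULL, config = set_test_config(),
                           pathway_id = NULL) {
  stopifnot(inherits(x, "genotype_matrix"),
            inherits(config, "set_test_config"))
  idx <- resolve_snp_subset(x, snps)
  check_testable(x, idx)
  if (inherits(snps, "pathway_snp_set") && is.null(pathway_id)) {
    pathway_id <- snps$pathway_id
  }
  X <- x$dosages[, idx, drop = FALSE]
  storage.mode(X) <- "double"  # avoid re-coercion inside every permutation
  y <- x$phenotype
  r2 <- r2_matrix(X)  # genotypes are fixed under phenotype permutation
  mtot <- colSums(X)
  prunable <- colSums(r2 >= config$r2_threshold) > 1L
  obs <- set_stat_once(X, y, r2, config, mtot = mtot, prunable = prunable)
  K <- config$n_permutations
  perm_stats <- numeric(K)
  fixed_tags <- if (config$prune_per_permutation) NULL else obs$tags
  with_seed(derive_seed(config$seed, 4242), {
    for (i in seq_len(K)) {
      yi <- sample(y)
      perm_stats[i] <- set_stat_once(X, yi, r2, config, tags = fixed_tags,
                                     mtot = mtot,
                                     prunable = prunable)$statistic
    }
  })
  p <- (1 + sum(perm_stats >= obs$statistic)) / (K + 1)
  structure(
    list(pathway_id = pathway_id %||% "pathway",
         method = "setbased",
         statistic = obs$statistic,
         perm_statistics = perm_stats,
         p_value = p,
         n_snps_stage1 = length(idx),
         n_snps_stage2 = length(obs$tags),
         importance_z = NULL,
         selected = x$snp_ids[idx][obs$tags],
         direction = "greater",
         n_permutations = K,
         seed = config$seed,
         config = config),
    class = "pathway_test"
  )
}
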