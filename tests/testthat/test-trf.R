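test_that("the add-one permutation p-value counts ties as extreme", {
  expect_equal(permutation_pvalue(0.30, c(0.5, 0.5, 0.5)), 0.25)
  expect_equal(permutation_pvalue(0.30, c(0.2, 0.5, 0.5)), 0.5)
  # all permuted scores larger -> minimum attainable p
  expect_equal(permutation_pvalue(0.1, rep(0.9, 99)), 1 / 100)
  # all permuted scores at or below -> 1
  expect_equal(permutation_pvalue(0.9, rep(0.1, 7)), 1)
  # K = 9 with exactly 4 of 9 at or below
  expect_equal(permutation_pvalue(0.5, c(0.1, 0.2, 0.3, 0.5, 0.8, 0.9, 1, 1, 1)),
               0.5)
})

test_that("permutation p-values agree with brute-force counting on random cases", {
  set.seed(31)
  for (i in 1:50) {
    K <- sample(1:30, 1)
    R <- runif(1)
    Rp <- runif(K)
    count <- 0L
    for (r in Rp) if (r <= R) count <- count + 1L  # independent tally
    expect_identical(permutation_pvalue(R, Rp), (1 + count) / (K + 1))
  }
})

test_that("no threshold and threshold -Inf both reproduce the single-stage test", {
  gm <- make_noise_gm(n = 100, p = 12, seed = 21)
  base <- forest_config(n_trees = 40, seed = 5)
  rf <- trf_pathway_test(gm, config = trf_config(
    importance_threshold = NULL, n_permutations = 19, forest = base))
  neg_inf <- trf_pathway_test(gm, config = trf_config(
    importance_threshold = -Inf, n_permutations = 19, forest = base))
  expect_equal(rf$method, "rf")
  expect_equal(rf$n_snps_stage2, rf$n_snps_stage1)
  expect_equal(neg_inf$n_snps_stage2, neg_inf$n_snps_stage1)
  expect_identical(rf$statistic, neg_inf$statistic)
  expect_identical(rf$perm_statistics, neg_inf$perm_statistics)
  expect_identical(rf$p_value, neg_inf$p_value)
})

test_that("the perfect separator attains the minimum attainable p-value", {
  gm <- make_separator_gm(n = 150, p_noise = 8, seed = 4)
  K <- 39
  fit <- trf_pathway_test(gm, config = trf_config(
    n_permutations = K, forest = forest_config(n_trees = 60, seed = 2)))
  expect_equal(fit$p_value, 1 / (K + 1))
  expect_true("rs_sep" %in% fit$selected)
  expect_lte(fit$n_snps_stage2, fit$n_snps_stage1)
})

test_that("p-values respect their attainable range and determinism", {
  gm <- make_noise_gm(n = 80, p = 10, seed = 22)
  cfg <- trf_config(n_permutations = 19,
                    forest = forest_config(n_trees = 30, seed = 11))
  f1 <- trf_pathway_test(gm, config = cfg)
  f2 <- trf_pathway_test(gm, config = cfg)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$perm_statistics, f2$perm_statistics)
  expect_gte(f1$p_value, 1 / 20)
  expect_lte(f1$p_value, 1)
})

test_that("empty stage-2 selection follows the fallback policy", {
  gm <- make_noise_gm(n = 100, p = 8, seed = 23)
  # a threshold no Z can clear forces the fallback on every fit
  all_snps <- trf_pathway_test(gm, config = trf_config(
    importance_threshold = 99, n_permutations = 9,
    forest = forest_config(n_trees = 30, seed = 3)))
  expect_equal(all_snps$n_snps_stage2, all_snps$n_snps_stage1)
  top_one <- trf_pathway_test(gm, config = trf_config(
    importance_threshold = 99, n_permutations = 9,
    forest = forest_config(n_trees = 30, seed = 3),
    fallback_policy = "top_one"))
  expect_equal(top_one$n_snps_stage2, 1L)
  expect_equal(top_one$selected,
               names(which.max(all_snps$importance_z)))
})

test_that("under the global null the two-stage p-values are calibrated", {
  # the permuted pipeline re-runs the stage-1 selection, so null p-values are
  # (super-)uniform; check rejection at 0.05 and overall uniformity
  n_rep <- 120
  K <- 39
  pvals <- vapply(seq_len(n_rep), function(r) {
    gm <- make_noise_gm(n = 100, p = 20, seed = 4000 + r)
    trf_pathway_test(gm, config = trf_config(
      n_permutations = K,
      forest = forest_config(n_trees = 50, seed = 7000 + r)))$p_value
  }, numeric(1))
  expect_true(ci_contains(sum(pvals <= 0.05), n_rep, 0.05))
  # coarse KS-style check against uniformity on the attainable grid
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("a pathway collection reports results, skips, and adjustment", {
  gm <- make_noise_gm(n = 80, p = 6, seed = 24)
  genes <- tibble::tibble(gene_id = c("G1", "G2", "G3"), chromosome = "1",
                          start = c(100L, 1000L, 99000L),
                          end = c(400L, 1500L, 99500L))
  snps <- tibble::tibble(snp_id = gm$snp_ids, chromosome = "1",
                         position = c(150L, 200L, 1100L, 1200L, 300L, 1400L))
  pathways <- tibble::tibble(
    pathway_id = c("P1", "P2", "P3"),
    name = c("both genes", "gene two", "unmappable"),
    gene_ids = list(c("G1", "G2"), "G2", "G3"),
    n_genes = c(2L, 1L, 1L))
  cfg <- trf_config(n_permutations = 19, window_kb = 0,
                    forest = forest_config(n_trees = 30, seed = 5))
  res <- run_pathway_collection(gm, pathways, genes, snps, config = cfg,
                                methods = c("trf", "rf", "setbased"))
  expect_equal(nrow(res), 3)
  expect_equal(sum(res$skipped), 1)
  expect_true(all(c("trf_p", "rf_p", "plink_p", "p_bonferroni") %in% names(res)))
  tested <- res[!res$skipped, ]
  expect_true(all(tested$trf_p >= 1 / 20 & tested$trf_p <= 1))
  expect_equal(tested$p_bonferroni, pmin(1, tested$trf_p * 2))
  expect_true(is.na(res$trf_p[res$skipped]))
  # results come back sorted by the primary p-value, skips last
  expect_true(!is.unsorted(tested$trf_p))
})

test_that("identical SNP sets under the same seed give identical p-values", {
  gm <- make_noise_gm(n = 80, p = 8, seed = 25)
  genes <- tibble::tibble(gene_id = c("GA", "GB"), chromosome = "1",
                          start = c(100L, 100L), end = c(900L, 900L))
  snps <- tibble::tibble(snp_id = gm$snp_ids, chromosome = "1",
                         position = seq(150L, by = 100L, length.out = 8))
  pathways <- tibble::tibble(pathway_id = c("PA", "PB"), name = c("a", "b"),
                             gene_ids = list("GA", "GB"), n_genes = 1L)
  cfg <- trf_config(n_permutations = 19, window_kb = 0,
                    forest = forest_config(n_trees = 30, seed = 5))
  res1 <- run_pathway_collection(gm, pathways, genes, snps, config = cfg)
  # per-pathway seeds hash the SNP set, so identical sets give identical
  # p-values wherever they appear in the collection
  expect_equal(res1$trf_p[res1$pathway_id == "PA"],
               res1$trf_p[res1$pathway_id == "PB"])
})

test_that("minimum attainable p is 1/(K+1)", {
  expect_equal(permutation_pvalue(-1, runif(2000)), 1 / 2001)
})
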