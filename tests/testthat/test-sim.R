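test_that("the intercept solver hits closed forms and an enumeration oracle", {
  # no effects: prevalence = expit(alpha) exactly
  expect_lt(abs(solve_alpha(rep(0, 7), c(0.25, 0.15, 0.15), 0.01) -
                  qlogis(0.01)), 1e-8)

  # main-effects model: compare against an independent uniroot enumeration
  betas <- c(rep(0.92, 3), rep(0, 4))
  mafs <- c(0.25, 0.15, 0.15)
  ours <- solve_alpha(betas, mafs, 0.01)
  carrier <- 1 - (1 - mafs)^2
  states <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  w <- apply(states, 1, function(s) prod(ifelse(s == 1, carrier, 1 - carrier)))
  lp <- states %*% betas[1:3]
  oracle <- uniroot(function(a) sum(w * plogis(a + lp)) - 0.01,
                    c(-20, 5), tol = 1e-12)$root
  expect_lt(abs(ours - oracle), 1e-8)

  # higher prevalence needs a larger intercept
  expect_gt(solve_alpha(betas, mafs, 0.05), ours)
})

test_that("the solved intercept reproduces the prevalence in a large cohort", {
  sc <- scenario_spec("S1")
  ef <- effect_model_spec("M4")
  dm <- disease_model(sc, ef)
  set.seed(404)
  n <- 1e6
  X <- sapply(dm$causal_mafs, function(m) rbinom(n, 1, 1 - (1 - m)^2))
  prev_hat <- mean(runif(n) < penetrance(X, dm))
  expect_lt(abs(prev_hat - sc$prevalence), 0.002)
})

test_that("penetrance follows the log-odds interaction model", {
  sc <- scenario_spec("S1")
  null_dm <- disease_model(sc, effect_model_spec("null"))
  # all betas zero: penetrance equals the prevalence whatever the genotype
  expect_equal(penetrance(rbind(c(0, 0, 0), c(1, 1, 1)), null_dm),
               rep(sc$prevalence, 2), tolerance = 1e-6)

  # alpha = 0, betas = 0 would give 1/2
  free <- null_dm; free$alpha <- 0
  expect_equal(penetrance(c(1, 0, 1), free), 0.5)

  # main-effects model: carrying all three risk genotypes shifts the log-odds
  # by 3 x 0.92 = 2.76
  m1 <- disease_model(sc, effect_model_spec("M1"))
  lo <- function(p) log(p / (1 - p))
  expect_equal(lo(penetrance(c(1, 1, 1), m1)) - lo(penetrance(c(0, 0, 0), m1)),
               2.76, tolerance = 1e-9)
})

test_that("effect models encode the multiplicative interaction scheme", {
  m4 <- effect_model_spec("M4")
  expect_equal(m4$betas, c(0.26, 0.26, 0.26, 0.52, 0.52, 0.52, 0.78))
  expect_equal(effect_model_spec("M2")$phi, 0.18)
  expect_equal(effect_model_spec("M1")$betas, c(0.92, 0.92, 0.92, 0, 0, 0, 0))
  expect_equal(effect_model_spec("null")$betas, rep(0, 7))
  expect_equal(effect_model_spec("M3")$extra_beta, 0.22)
})

test_that("scenario definitions carry the study design constants", {
  s1 <- scenario_spec("S1")
  expect_equal(s1$n_cases, 1000L)
  expect_equal(s1$n_snps, 1038L)
  expect_equal(s1$n_genes, 50L)
  expect_equal(s1$prevalence, 0.01)
  expect_equal(s1$causal_mafs, c(0.25, 0.15, 0.15))
  expect_equal(scenario_spec("S2")$n_cases, 500L)
  expect_equal(scenario_spec("S3")$prevalence, 0.05)
  s4 <- scenario_spec("S4")
  expect_equal(s4$n_snps, 1527L)
  expect_equal(s4$n_genes, 100L)
  expect_true(s4$extra_locus)
  expect_equal(s4$extra_maf, 0.25)
  # proportional scaling
  s1s <- scenario_spec("S1", scale = 0.2)
  expect_equal(s1s$n_cases, 200L)
  expect_equal(s1s$n_snps, 208L)
  expect_equal(s1s$prevalence, 0.01)
})

test_that("genotype simulation honours MAF targets, HWE and block correlation", {
  # independence: near-zero mean pairwise dosage r2 when rho = 0
  ld0 <- ld_block_model(12, n_blocks = 1, within_block_rho = 0,
                        maf_range = c(0.2, 0.4), seed = 2)
  g0 <- simulate_genotypes(2000, ld0, seed = 3)
  r2s <- cor(g0)^2
  expect_lt(mean(r2s[upper.tri(r2s)]), 0.01)

  # strong latent correlation survives the genotype thresholding
  ld9 <- ld_block_model(12, n_blocks = 1, within_block_rho = 0.9,
                        maf_range = c(0.2, 0.4), seed = 2)
  g9 <- simulate_genotypes(2000, ld9, seed = 3)
  r2s9 <- cor(g9)^2
  expect_gt(mean(r2s9[upper.tri(r2s9)]), 0.4)

  # realized MAF concentrates on the target
  ldm <- ld_block_model(4, n_blocks = 2, mafs = rep(0.25, 4), seed = 1)
  gm <- simulate_genotypes(5000, ldm, seed = 9)
  expect_true(all(abs(colMeans(gm) / 2 - 0.25) < 0.02))

  # marginal HWE: genotype frequencies match (1-m)^2, 2m(1-m), m^2
  tab <- table(factor(gm[, 1], levels = 0:2)) / 5000
  expect_lt(max(abs(tab - c(0.75^2, 2 * 0.25 * 0.75, 0.25^2))), 0.02)
})

test_that("case-control sampling returns exact counts and null symmetry", {
  sc <- scenario_spec("S1", scale = 0.05)  # 50/50 at desk scale
  sc$n_cases <- 10L; sc$n_controls <- 10L
  gm <- simulate_case_control(sc, effect_model_spec("null"), seed = 5)
  expect_equal(sum(gm$phenotype == 1L), 10L)
  expect_equal(sum(gm$phenotype == 0L), 10L)

  # under the null the case and control genotype distributions coincide;
  # seeds fixed, so at most one of 20 x 3 locus tests may dip below 0.001
  sc2 <- scenario_spec("S1", scale = 0.1)
  fails <- 0
  for (s in 1:20) {
    g <- simulate_case_control(sc2, effect_model_spec("null"), seed = 100 + s)
    ci <- attr(g, "causal_indices")
    for (j in ci) {
      p <- allelic_chisq(g$dosages[, j], g$phenotype)$p_value
      if (p < 0.001) fails <- fails + 1
    }
  }
  expect_lte(fails, 1)
})

test_that("risk models raise the causal carrier frequency in cases", {
  sc <- scenario_spec("S1", scale = 0.3)
  gm <- simulate_case_control(sc, effect_model_spec("M4"), seed = 6)
  ci <- attr(gm, "causal_indices")
  for (j in ci) {
    carrier <- gm$dosages[, j] > 0
    expect_gt(mean(carrier[gm$phenotype == 1]),
              mean(carrier[gm$phenotype == 0]))
  }
})

test_that("causal loci sit in distinct blocks with the designated MAFs", {
  sc <- scenario_spec("S4", scale = 0.2)
  ld <- scenario_ld_model(sc, seed = 3)
  expect_length(ld$causal_indices, 4)
  expect_equal(length(unique(ld$block[ld$causal_indices])), 4)
  expect_equal(ld$mafs[ld$causal_indices], c(0.25, 0.15, 0.15, 0.25))
})

test_that("experiments tabulate rejection rates with binomial CIs deterministically", {
  sc <- scenario_spec("S1", scale = 0.05)
  e1 <- run_experiment(sc, effect_model_spec("null"), method = "setbased",
                       n_replicates = 20, alpha_levels = c(0.05, 1),
                       n_permutations = 19, seed = 12)
  e2 <- run_experiment(sc, effect_model_spec("null"), method = "setbased",
                       n_replicates = 20, alpha_levels = c(0.05, 1),
                       n_permutations = 19, seed = 12)
  expect_identical(e1$p_values, e2$p_values)
  expect_identical(tidy(e1), tidy(e2))
  # level 1 rejects everything
  expect_equal(e1$rates$rate[e1$rates$level == 1], 1)
  r <- e1$rates[e1$rates$level == 0.05, ]
  expect_true(r$ci_lo <= r$rate && r$rate <= r$ci_hi)
  expect_s3_class(tidy(e1), "tbl_df")
  expect_equal(glance(e1)$n_replicates, 20)
})
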