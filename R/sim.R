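#' Linkage-disequilibrium block model for genotype simulation
#'
#' Genotypes are simulated from a Gaussian copula: within each block the two
#' haplotypes of a sample are thresholded latent normal vectors with
#' exchangeable correlation `within_block_rho`, independent between blocks,
#' and each SNP's threshold is the quantile of its minor-allele frequency.
#' Marginally every SNP is in Hardy-Weinberg equilibrium at its MAF;
#' within-block dosage correlation decays from `rho` through the double
#' thresholding.  Blocks play the role of genes: a pathway's LD structure is
#' a sequence of internally correlated, mutually independent gene blocks.
#'
#' @param n_snps Total number of SNPs.
#' @param block_sizes Integer vector partitioning the SNPs into blocks;
#'   overrides `n_blocks`.
#' @param n_blocks Number of near-equal blocks when `block_sizes` is `NULL`.
#' @param within_block_rho Latent exchangeable correlation within a block, in
#'   `[0, 1)` (default 0.5, moderate LD).
#' @param maf_range Range from which per-SNP minor-allele frequencies are
#'   drawn uniformly (default 0.05-0.45).
#' @param mafs Optional explicit per-SNP MAF vector (overrides `maf_range`).
#' @param seed Seed fixing the drawn MAFs (the model is deterministic once
#'   built; genotype draws take their own seed).
#' @return An object of class `ld_block_model`.
#' @export
ld_block_model <- function(n_snps, block_sizes = NULL, n_blocks = NULL,
                           within_block_rho = 0.5,
                           maf_range = c(0.05, 0.45), mafs = NULL, seed = 1) {
  if (!is_count(n_snps)) abort("`n_snps` must be a positive integer")
  stopifnot(is.numeric(within_block_rho), within_block_rho >= 0,
            within_block_rho < 1)
  if (is.null(block_sizes)) {
    n_blocks <- n_blocks %||% max(1L, round(n_snps / 20))
    cuts <- round(seq(0, n_snps, length.out = n_blocks + 1))
    block_sizes <- diff(cuts)
    block_sizes <- block_sizes[block_sizes > 0]
  }
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != n_snps || any(block_sizes < 1)) {
    abort("`block_sizes` must be positive and sum to `n_snps`")
  }
  if (is.null(mafs)) {
    stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 0.5,
              maf_range[1] <= maf_range[2])
    mafs <- with_seed(derive_seed(seed, 11),
                      runif(n_snps, maf_range[1], maf_range[2]))
  }
  stopifnot(length(mafs) == n_snps, all(mafs > 0), all(mafs < 0.5))
  structure(
    list(n_snps = as.integer(n_snps), block_sizes = block_sizes,
         block = rep(seq_along(block_sizes), block_sizes),
         within_block_rho = within_block_rho, mafs = mafs,
         seed = as.integer(seed)),
    class = "ld_block_model"
  )
}

#' @export
print.ld_block_model <- function(x, ...) {
  cat(sprintf("<ld_block_model> %d SNPs in %d blocks (rho = %.2f, MAF %.3f-%.3f)\n",
              x$n_snps, length(x$block_sizes), x$within_block_rho,
              min(x$mafs), max(x$mafs)))
  invisible(x)
}

#' Simulate genotype dosages from an LD block model
#'
#' @param n Number of samples.
#' @param model An [ld_block_model()].
#' @param seed Integer seed for this draw.
#' @return Integer dosage matrix (`n` x `n_snps`) with column names
#'   `snp0001`, ...
#' @export
simulate_genotypes <- function(n, model, seed = 1) {
  stopifnot(inherits(model, "ld_block_model"), is_count(n))
  rho <- model$within_block_rho
  with_seed(derive_seed(seed, 21), {
    out <- matrix(0L, n, model$n_snps)
    offset <- 0L
    for (m in model$block_sizes) {
      thr <- qnorm(model$mafs[offset + seq_len(m)])
      for (h in 1:2) {
        z <- sqrt(rho) * rnorm(n) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
        out[, offset + seq_len(m)] <- out[, offset + seq_len(m)] +
          (z < rep(thr, each = n))
      }
      offset <- offset + m
    }
    colnames(out) <- sprintf("snp%04d", seq_len(model$n_snps))
    out
  })
}

#' Simulation scenario definitions
#'
#' The four study designs used in the type-I-error and power experiments:
#' * `S1`: 1000 cases / 1000 controls, 50 genes, 1038 SNPs, prevalence 1%,
#'   three causal loci with MAFs 0.25 / 0.15 / 0.15 in distinct genes;
#' * `S2`: as S1 with 500 cases / 500 controls;
#' * `S3`: as S1 with prevalence 5%;
#' * `S4`: a larger pathway of 100 genes and 1527 SNPs with a fourth,
#'   main-effect-only causal locus of MAF 0.25.
#'
#' `scale` shrinks the sample sizes, gene count and SNP count proportionally
#' (rounded, with small floors) for desk-scale runs; prevalence, MAFs and the
#' causal architecture are untouched.
#'
#' @param name `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param scale Proportional size factor in (0, 1] (default 1 = full scale).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("S1", "S2", "S3", "S4"), scale = 1) {
  name <- match.arg(name)
  stopifnot(is.numeric(scale), scale > 0, scale <= 1)
  base <- switch(name,
    S1 = list(n_cases = 1000, n_controls = 1000, n_genes = 50, n_snps = 1038,
              prevalence = 0.01, causal_mafs = c(0.25, 0.15, 0.15),
              extra_locus = FALSE),
    S2 = list(n_cases = 500, n_controls = 500, n_genes = 50, n_snps = 1038,
              prevalence = 0.01, causal_mafs = c(0.25, 0.15, 0.15),
              extra_locus = FALSE),
    S3 = list(n_cases = 1000, n_controls = 1000, n_genes = 50, n_snps = 1038,
              prevalence = 0.05, causal_mafs = c(0.25, 0.15, 0.15),
              extra_locus = FALSE),
    S4 = list(n_cases = 1000, n_controls = 1000, n_genes = 100, n_snps = 1527,
              prevalence = 0.01, causal_mafs = c(0.25, 0.15, 0.15),
              extra_locus = TRUE, extra_maf = 0.25)
  )
  n_loci <- length(base$causal_mafs) + isTRUE(base$extra_locus)
  base$n_cases <- max(20L, as.integer(round(base$n_cases * scale)))
  base$n_controls <- max(20L, as.integer(round(base$n_controls * scale)))
  base$n_genes <- max(n_loci + 1L, as.integer(round(base$n_genes * scale)))
  base$n_snps <- max(base$n_genes * 2L,
                     as.integer(round(base$n_snps * scale)))
  base$name <- name
  base$scale <- scale
  structure(base, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s%s: %d/%d cases/controls, %d genes, %d SNPs, prevalence %g%%\n",
              x$name, if (x$scale != 1) sprintf(" (scale %g)", x$scale) else "",
              x$n_cases, x$n_controls, x$n_genes, x$n_snps,
              100 * x$prevalence))
  invisible(x)
}

#' Effect-size models for the causal loci
#'
#' The penetrance model couples up to three interacting causal loci through
#' log-odds coefficients `beta[1:3]` (conditional main effects), `beta[4:6]`
#' (pairwise interactions) and `beta[7]` (three-way interaction):
#' * `null`: all coefficients 0 (type-I-error setting);
#' * `M1`: main effects only, `beta[1:3] = 0.92`;
#' * `M2`, `M3`, `M4`: multiplicative interaction models with
#'   `beta[1:3] = phi`, `beta[4:6] = 2 phi`, `beta[7] = 3 phi` for
#'   `phi = 0.18, 0.22, 0.26` — on the odds scale the joint effect of two or
#'   three loci is the product of their marginal effects.
#'
#' The fourth locus of scenario S4 carries a main effect only; its
#' coefficient defaults to the model's main-effect size (0.92 under M1,
#' `phi` under M2-M4, 0 under null) and can be overridden.
#'
#' @param name One of `"null"`, `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param extra_beta Optional override for the S4 fourth-locus main effect.
#' @return An object of class `effect_model` with elements `name`, `phi`,
#'   `betas` (length 7) and `extra_beta`.
#' @export
effect_model_spec <- function(name = c("null", "M1", "M2", "M3", "M4"),
                              extra_beta = NULL) {
  name <- match.arg(name)
  phi <- switch(name, null = NA_real_, M1 = NA_real_,
                M2 = 0.18, M3 = 0.22, M4 = 0.26)
  betas <- switch(name,
    null = rep(0, 7),
    M1 = c(rep(0.92, 3), rep(0, 4)),
    c(rep(phi, 3), rep(2 * phi, 3), 3 * phi)
  )
  extra_default <- switch(name, null = 0, M1 = 0.92, phi)
  structure(
    list(name = name, phi = phi, betas = betas,
         extra_beta = extra_beta %||% extra_default),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf("<effect_model> %s: betas = (%s), extra main effect %g\n",
              x$name, paste(format(x$betas), collapse = ", "), x$extra_beta))
  invisible(x)
}

# design matrix of the penetrance linear predictor for dominant-coded causal
# indicators: main effects, pairwise products, three-way product (first three
# loci), plus a main-effect-only column for an optional fourth locus
dominant_design <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) %in% c(3, 4), all(X %in% c(0, 1)))
  d <- cbind(X[, 1], X[, 2], X[, 3],
             X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 2] * X[, 3],
             X[, 1] * X[, 2] * X[, 3])
  if (ncol(X) == 4) d <- cbind(d, X[, 4])
  d
}

#' Disease penetrance under the interaction model
#'
#' `P(disease | X) = expit(alpha + b' d(X))` where `X` are dominant-coded
#' causal-locus indicators (1 = at least one minor allele) and `d(X)` stacks
#' main effects, pairwise products and the three-way product of the first
#' three loci (plus the fourth locus' main effect when present).
#'
#' @param X Matrix (or vector) of 0/1 dominant indicators, 3 or 4 columns.
#' @param model A [disease_model()].
#' @return Vector of penetrances in (0, 1).
#' @export
penetrance <- function(X, model) {
  stopifnot(inherits(model, "disease_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  d <- dominant_design(X)
  stopifnot(ncol(d) == length(model$coef))
  plogis(model$alpha + as.vector(d %*% model$coef))
}

#' Solve the penetrance intercept for a target prevalence
#'
#' Finds `alpha` such that the population disease probability
#' `E_X[penetrance(X)]` equals `prevalence`, where the causal-locus
#' indicators are independent with carrier probabilities
#' `P(X_i = 1) = 1 - (1 - maf_i)^2` (Hardy-Weinberg).  The expectation is an
#' exact enumeration over the `2^L` indicator states and the equation is
#' solved by bisection on `[-50, 50]` to an absolute tolerance of 1e-10
#' (the expectation is strictly increasing in `alpha`).
#'
#' @param betas Coefficient vector: length 7 for three loci
#'   (main/pairwise/three-way), or length 8 with a fourth main-effect-only
#'   locus.
#' @param causal_mafs Minor-allele frequencies of the causal loci (length 3
#'   or 4, matching `betas`).
#' @param prevalence Target disease prevalence in (0, 1).
#' @return The intercept `alpha`.
#' @examples
#' solve_alpha(rep(0, 7), c(0.25, 0.15, 0.15), 0.01)  # qlogis(0.01)
#' @export
solve_alpha <- function(betas, causal_mafs, prevalence) {
  stopifnot(length(betas) %in% c(7, 8),
            length(causal_mafs) == (if (length(betas) == 7) 3 else 4),
            all(causal_mafs > 0), all(causal_mafs <= 0.5),
            is_prob(prevalence), prevalence > 0, prevalence < 1)
  L <- length(causal_mafs)
  states <- as.matrix(expand.grid(rep(list(0:1), L)))
  carrier <- 1 - (1 - causal_mafs)^2
  w <- apply(states, 1, function(s) prod(ifelse(s == 1, carrier, 1 - carrier)))
  lp0 <- as.vector(dominant_design(states) %*% betas)
  f <- function(alpha) sum(w * plogis(alpha + lp0)) - prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) abort("no intercept in [-50, 50] attains the prevalence")
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < 1e-10 && (hi - lo) < 1e-6) break
  }
  (lo + hi) / 2
}

#' Disease model: coefficients, causal loci, intercept
#'
#' Binds an effect model to a scenario's causal architecture: dominant-coded
#' causal loci with given MAFs, log-odds coefficients, and the intercept
#' `alpha` solved so that the population prevalence matches the scenario
#' ([solve_alpha()]).
#'
#' @param scenario A [scenario_spec()].
#' @param effects An [effect_model_spec()].
#' @return An object of class `disease_model` with `coef` (length 7 or 8),
#'   `causal_mafs`, `prevalence`, `alpha`.
#' @export
disease_model <- function(scenario, effects) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(effects, "effect_model"))
  coefs <- effects$betas
  mafs <- scenario$causal_mafs
  if (isTRUE(scenario$extra_locus)) {
    coefs <- c(coefs, effects$extra_beta)
    mafs <- c(mafs, scenario$extra_maf)
  }
  alpha <- solve_alpha(coefs, mafs, scenario$prevalence)
  structure(
    list(coef = coefs, causal_mafs = mafs,
         prevalence = scenario$prevalence, alpha = alpha),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("<disease_model> %d causal loci, prevalence %g%%, alpha = %.4f\n",
              length(x$causal_mafs), 100 * x$prevalence, x$alpha))
  invisible(x)
}

#' LD model matching a scenario's pathway
#'
#' One block per gene (sizes near-equal, summing to the scenario's SNP
#' count); the causal loci sit at the centres of evenly spaced distinct
#' blocks and their MAFs are fixed to the scenario's values.
#'
#' @param scenario A [scenario_spec()].
#' @param within_block_rho,maf_range,seed Passed to [ld_block_model()].
#' @return An [ld_block_model()] with an extra element `causal_indices`.
#' @export
scenario_ld_model <- function(scenario, within_block_rho = 0.5,
                              maf_range = c(0.05, 0.45), seed = 1) {
  stopifnot(inherits(scenario, "scenario_spec"))
  ld <- ld_block_model(scenario$n_snps, n_blocks = scenario$n_genes,
                       within_block_rho = within_block_rho,
                       maf_range = maf_range, seed = seed)
  n_loci <- length(scenario$causal_mafs) + isTRUE(scenario$extra_locus)
  n_blocks <- length(ld$block_sizes)
  causal_blocks <- unique(floor(seq(1, n_blocks, length.out = n_loci)))
  stopifnot(length(causal_blocks) == n_loci)  # guaranteed by scenario floors
  causal_idx <- vapply(causal_blocks, function(b) {
    in_block <- which(ld$block == b)
    in_block[ceiling(length(in_block) / 2)]
  }, integer(1))
  mafs <- scenario$causal_mafs
  if (isTRUE(scenario$extra_locus)) mafs <- c(mafs, scenario$extra_maf)
  ld$mafs[causal_idx] <- mafs
  ld$causal_indices <- causal_idx
  ld
}

#' Simulate a case-control study under the penetrance model
#'
#' Draws genotype rows from the LD model, computes the dominant-coded causal
#' indicators, assigns disease status with probability `penetrance(X)`, and
#' collects exactly `n_cases` cases and `n_controls` controls (retrospective
#' case-control sampling from the population model).  Once one stratum's
#' quota is filled, the remaining draws for the other stratum are accepted by
#' stratum-conditional rejection (acceptance probability proportional to the
#' penetrance, or its complement), which reproduces the same conditional
#' genotype distributions without discarding draws — important at 1%
#' prevalence, where naive collection would discard 99% of rows while
#' waiting for cases.
#'
#' @param scenario A [scenario_spec()].
#' @param effects An [effect_model_spec()].
#' @param ld Optional [scenario_ld_model()] (built from `seed` when `NULL`).
#' @param seed Integer seed.
#' @param max_batches Safety cap on sampling batches; exceeded only under
#'   pathologically extreme penetrance configurations.
#' @return A [genotype_matrix()] (cases first) with attributes
#'   `causal_indices` and `disease_model`.
#' @export
simulate_case_control <- function(scenario, effects, ld = NULL, seed = 1,
                                  max_batches = 1000) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(effects, "effect_model"))
  ld <- ld %||% scenario_ld_model(scenario, seed = derive_seed(seed, 31))
  stopifnot(!is.null(ld$causal_indices))
  model <- disease_model(scenario, effects)

  # bounds of the penetrance over the indicator states, for the
  # stratum-conditional acceptance probabilities
  L <- length(model$causal_mafs)
  states <- as.matrix(expand.grid(rep(list(0:1), L)))
  pen_states <- penetrance(states, model)
  pen_max <- max(pen_states)
  pen_min <- min(pen_states)

  need_cases <- scenario$n_cases
  need_controls <- scenario$n_controls
  cases <- controls <- vector("list", 0)
  batch <- 0L
  while ((need_cases > 0 || need_controls > 0) && batch < max_batches) {
    batch <- batch + 1L
    # batch size targets the scarcer stratum's expected acceptance rate
    rate_case <- if (need_cases > 0) {
      if (need_controls > 0) model$prevalence else model$prevalence / pen_max
    } else Inf
    rate_ctrl <- if (need_controls > 0) {
      if (need_cases > 0) 1 - model$prevalence
      else (1 - model$prevalence) / (1 - pen_min)
    } else Inf
    need_draws <- max(need_cases / min(rate_case, 1),
                      need_controls / min(rate_ctrl, 1))
    B <- as.integer(min(50000, max(200, ceiling(1.3 * need_draws))))
    G <- simulate_genotypes(B, ld, seed = derive_seed(seed, 41, batch))
    X <- (G[, ld$causal_indices, drop = FALSE] > 0) + 0
    pen <- penetrance(X, model)
    u <- with_seed(derive_seed(seed, 51, batch), runif(B))
    if (need_cases > 0 && need_controls > 0) {
      # both strata open: plain Bernoulli(penetrance) assignment
      is_case <- u < pen
      take_case <- which(is_case)[seq_len(min(need_cases, sum(is_case)))]
      take_ctrl <- which(!is_case)[seq_len(min(need_controls, sum(!is_case)))]
    } else if (need_cases > 0) {
      # controls full: rejection-sample cases (accept w.p. pen / pen_max)
      acc <- which(u < pen / pen_max)
      take_case <- acc[seq_len(min(need_cases, length(acc)))]
      take_ctrl <- integer(0)
    } else {
      acc <- which(u < (1 - pen) / (1 - pen_min))
      take_ctrl <- acc[seq_len(min(need_controls, length(acc)))]
      take_case <- integer(0)
    }
    if (length(take_case)) {
      cases[[length(cases) + 1]] <- G[take_case, , drop = FALSE]
      need_cases <- need_cases - length(take_case)
    }
    if (length(take_ctrl)) {
      controls[[length(controls) + 1]] <- G[take_ctrl, , drop = FALSE]
      need_controls <- need_controls - length(take_ctrl)
    }
  }
  if (need_cases > 0 || need_controls > 0) {
    abort(sprintf(
      paste("case-control sampling budget exceeded (%d batches):",
            "still need %d cases, %d controls; prevalence %g, penetrance",
            "range [%g, %g]"),
      batch, need_cases, need_controls, model$prevalence, pen_min, pen_max))
  }
  G <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  gm <- genotype_matrix(
    G, c(rep(1L, scenario$n_cases), rep(0L, scenario$n_controls)),
    snp_ids = colnames(G)
  )
  attr(gm, "causal_indices") <- ld$causal_indices
  attr(gm, "disease_model") <- model
  gm
}

#' Monte-Carlo rejection-rate experiment
#'
#' Runs `n_replicates` independent simulated studies under a scenario and
#' effect model, applies the chosen pathway test to the full simulated SNP
#' set of each replicate, and tabulates rejection rates (`p <= level`) with
#' exact binomial 95% confidence intervals.  Under the `null` effect model
#' this estimates type-I error; under `M1`-`M4` it estimates power.
#'
#' @param scenario A [scenario_spec()].
#' @param effects An [effect_model_spec()].
#' @param method `"trf"`, `"rf"` or `"setbased"`.
#' @param n_replicates Number of simulated studies.
#' @param alpha_levels Nominal significance levels (default 0.05 and 0.01).
#' @param n_permutations Permutations K per test.
#' @param n_trees Trees per forest (forest methods).
#' @param importance_threshold Stage-1 threshold for `"trf"` (default 1.64).
#' @param within_block_rho,maf_range LD model parameters.
#' @param seed Master seed; expands deterministically into the LD model, the
#'   per-replicate data seeds and the per-replicate test seeds.
#' @param verbose Progress messages every 50 replicates.
#' @return An object of class `pathway_experiment` with `p_values`, `rates`
#'   (tibble: `level`, `n_reject`, `rate`, `ci_lo`, `ci_hi`), and the run
#'   metadata.  `tidy()` returns the rates table; `glance()` a one-row
#'   summary at the first level.
#' @export
run_experiment <- function(scenario, effects, method = c("trf", "rf", "setbased"),
                           n_replicates = 100, alpha_levels = c(0.05, 0.01),
                           n_permutations = 199, n_trees = 100,
                           importance_threshold = 1.64,
                           within_block_rho = 0.5, maf_range = c(0.05, 0.45),
                           seed = 1, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(effects, "effect_model"), is_count(n_replicates),
            all(alpha_levels > 0 & alpha_levels <= 1))
  ld <- scenario_ld_model(scenario, within_block_rho = within_block_rho,
                          maf_range = maf_range, seed = derive_seed(seed, 61))
  pvals <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    gm <- simulate_case_control(scenario, effects, ld = ld,
                                seed = derive_seed(seed, 71, r))
    test_seed <- derive_seed(seed, 81, r)
    fit <- if (method == "setbased") {
      set_based_test(gm, config = set_test_config(
        n_permutations = n_permutations, seed = test_seed))
    } else {
      trf_pathway_test(gm, config = trf_config(
        importance_threshold = if (method == "trf") importance_threshold else NULL,
        n_permutations = n_permutations,
        forest = forest_config(n_trees = n_trees, seed = test_seed)))
    }
    pvals[r] <- fit$p_value
    if (verbose && r %% 50 == 0) {
      message(sprintf("[%s %s %s] replicate %d/%d", scenario$name,
                      effects$name, method, r, n_replicates))
    }
  }
  rates <- dplyr::bind_rows(lapply(alpha_levels, function(a) {
    k <- sum(pvals <= a)
    ci <- binom.test(k, n_replicates)$conf.int
    tibble(level = a, n_reject = k, rate = k / n_replicates,
           ci_lo = ci[1], ci_hi = ci[2])
  }))
  structure(
    list(p_values = pvals, rates = rates, method = method,
         scenario = scenario$name, scale = scenario$scale,
         effects = effects$name, n_replicates = n_replicates,
         n_permutations = n_permutations, n_trees = n_trees, seed = seed),
    class = "pathway_experiment"
  )
}

#' @export
print.pathway_experiment <- function(x, ...) {
  cat(sprintf("<pathway_experiment> %s / %s / %s: %d replicates, K = %d\n",
              x$scenario, x$effects, x$method, x$n_replicates,
              x$n_permutations))
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `pathway_experiment` object.
#' @param ... Unused.
#' @method tidy pathway_experiment
#' @export
tidy.pathway_experiment <- function(x, ...) {
  dplyr::mutate(x$rates, scenario = x$scenario, effects = x$effects,
                method = x$method, .before = 1)
}

#' @rdname run_experiment
#' @method glance pathway_experiment
#' @export
glance.pathway_experiment <- function(x, ...) {
  tibble(scenario = x$scenario, effects = x$effects, method = x$method,
         n_replicates = x$n_replicates, n_permutations = x$n_permutations,
         rate = x$rates$rate[1], level = x$rates$level[1], seed = x$seed)
}
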