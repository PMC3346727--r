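# Fixtures are generated in code; sizes are kept small so a full test run
# stays within desk-scale budgets.

# balanced case-control data with SNPs unrelated to the phenotype
make_noise_gm <- function(n = 200, p = 20, seed = 1, maf = 0.3) {
  set.seed(seed)
  d <- matrix(rbinom(n * p, 2, maf), n, p)
  colnames(d) <- sprintf("rs%03d", seq_len(p))
  genotype_matrix(d, rep(c(0L, 1L), length.out = n))
}

# noise SNPs plus one SNP that separates cases (dosage 2) from controls (0)
make_separator_gm <- function(n = 200, p_noise = 10, seed = 1) {
  gm <- make_noise_gm(n, p_noise, seed)
  sep <- ifelse(gm$phenotype == 1L, 2L, 0L)
  d <- cbind(gm$dosages, sep = sep)
  colnames(d)[p_noise + 1] <- "rs_sep"
  genotype_matrix(d, gm$phenotype)
}

# write a PLINK --recodeA style file and return its path
write_raw_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.raw")
  writeLines(lines, path)
  path
}

# exact binomial 95% CI contains the nominal level?
ci_contains <- function(n_reject, n, level) {
  ci <- stats::binom.test(n_reject, n)$conf.int
  ci[1] <= level && level <= ci[2]
}
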