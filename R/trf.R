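#' Configuration for the two-stage random-forest pathway test
#'
#' @param importance_threshold Stage-1 importance Z cutoff (strictly greater
#'   than).  The default 1.64 corresponds to a one-tailed standard-normal
#'   p-value of 0.05.  `NULL` disables the second stage entirely, giving the
#'   single-stage RF-pathway test.
#' @param n_permutations Number of phenotype permutations K (default 2000).
#' @param forest A [forest_config()] used by both stages.
#' @param window_kb SNP-to-gene mapping window in kilobases, used by
#'   [run_pathway_collection()] (default 20).
#' @param fallback_policy What stage 2 fits when no SNP exceeds the
#'   threshold: `"all_snps"` (default; the fit falls back to the full stage-1
#'   set, i.e. the single-stage score) or `"top_one"` (the single highest-Z
#'   SNP).
#' @return An object of class `trf_config`.
#' @export
trf_config <- function(importance_threshold = 1.64, n_permutations = 2000,
                       forest = forest_config(), window_kb = 20,
                       fallback_policy = c("all_snps", "top_one")) {
  fallback_policy <- match.arg(fallback_policy)
  if (!is.null(importance_threshold)) {
    stopifnot(is.numeric(importance_threshold),
              length(importance_threshold) == 1,
              is.finite(importance_threshold) || importance_threshold == -Inf)
  }
  if (!is_count(n_permutations)) abort("`n_permutations` must be >= 1")
  stopifnot(inherits(forest, "forest_config"),
            is.numeric(window_kb), window_kb >= 0)
  structure(
    list(importance_threshold = importance_threshold,
         n_permutations = as.integer(n_permutations),
         forest = forest, window_kb = window_kb,
         fallback_policy = fallback_policy),
    class = "trf_config"
  )
}

#' @export
print.trf_config <- function(x, ...) {
  cat(sprintf("<trf_config> threshold %s, K = %d, fallback %s\n",
              if (is.null(x$importance_threshold)) "none (single-stage RF)"
              else format(x$importance_threshold),
              x$n_permutations, x$fallback_policy))
  print(x$forest)
  invisible(x)
}

#' Permutation p-value with the add-one estimator
#'
#' `(1 + \#\{i : R_i <= R\}) / (K + 1)`, counting ties as extreme.  Strictly
#' positive, never below `1/(K+1)`, and a valid p-value for any exchangeable
#' permutation scheme.
#'
#' @param R Observed score (for the forest tests, smaller = more extreme).
#' @param R_perm Vector of permuted scores.
#' @return The p-value in `[1/(K+1), 1]`.
#' @examples
#' permutation_pvalue(0.30, c(0.5, 0.5, 0.5))  # 0.25
#' permutation_pvalue(0.30, c(0.2, 0.5, 0.5))  # 0.5
#' @export
permutation_pvalue <- function(R, R_perm) {
  stopifnot(is.numeric(R), length(R) == 1, is.finite(R),
            is.numeric(R_perm), length(R_perm) >= 1, all(is.finite(R_perm)))
  (1 + sum(R_perm <= R)) / (length(R_perm) + 1)
}

#' Two-stage random-forest pathway association test
#'
#' Tests whether the SNPs mapped to a pathway jointly predict case-control
#' status.  Stage 1 fits a random forest on all pathway SNPs and computes
#' each SNP's standardized permutation importance Z; stage 2 refits the
#' forest on the SNPs with `Z >` the threshold, and the out-of-bag prediction
#' error of that second forest is the pathway score `R`.  Significance comes
#' from `K` phenotype permutations, each of which re-runs *both* stages (so
#' the stage-1 selection is part of the null pipeline and introduces no
#' selection bias), with p-value `(1 + #\{R_i <= R\}) / (K + 1)`.
#'
#' With `importance_threshold = NULL` the test reduces to the single-stage
#' RF-pathway test: one forest on all pathway SNPs per (permuted) phenotype.
#'
#' @param x A [genotype_matrix()] without missing values.
#' @param snps SNP selection as in [fit_forest()].
#' @param config A [trf_config()].
#' @param pathway_id Optional label stored in the result.
#' @return An object of class `pathway_test` with elements `pathway_id`,
#'   `method` (`"trf"` or `"rf"`), `statistic` (the observed OOB error `R`),
#'   `perm_statistics` (length-K vector), `p_value`, `n_snps_stage1`,
#'   `n_snps_stage2`, `importance_z` (stage-1 Z scores, named; `NULL` for the
#'   single-stage test), `selected` (stage-2 SNP ids), `direction`
#'   (`"less"`), `n_permutations`, `seed`.
#' @examples
#' gm <- simulate_case_control(scenario_spec("S1", scale = 0.05),
#'                             effect_model_spec("M4"), seed = 7)
#' cfg <- trf_config(n_permutations = 49, forest = forest_config(n_trees = 50))
#' trf_pathway_test(gm, config = cfg)
#' @export
trf_pathway_test <- function(x, snps = NULL, config = trf_config(),
                             pathway_id = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "trf_config"))
  idx <- resolve_snp_subset(x, snps)
  check_testable(x, idx)
  if (inherits(snps, "pathway_snp_set") && is.null(pathway_id)) {
    pathway_id <- snps$pathway_id
  }
  ids <- x$snp_ids[idx]
  ord <- canonical_order(ids)
  use_threshold <- !is.null(config$importance_threshold)
  res <- cpp_trf_test(
    x$dosages[, idx[ord], drop = FALSE], x$phenotype,
    config$forest$n_trees, mtry_code(config$forest$mtry),
    config$forest$min_node_size,
    if (use_threshold) config$importance_threshold else 0,
    use_threshold,
    if (config$fallback_policy == "top_one") 1L else 0L,
    config$n_permutations, config$forest$seed
  )
  z <- NULL
  if (use_threshold) {
    z <- numeric(length(idx))
    z[ord] <- res$importance_z
    names(z) <- ids
  }
  canon_ids <- ids[ord]
  structure(
    list(pathway_id = pathway_id %||% "pathway",
         method = if (use_threshold) "trf" else "rf",
         statistic = res$R,
         perm_statistics = res$R_perm,
         p_value = permutation_pvalue(res$R, res$R_perm),
         n_snps_stage1 = res$n_snps_stage1,
         n_snps_stage2 = res$n_snps_stage2,
         importance_z = z,
         selected = canon_ids[res$selected],
         direction = "less",
         n_permutations = config$n_permutations,
         seed = config$forest$seed,
         config = config),
    class = "pathway_test"
  )
}

#' @export
print.pathway_test <- function(x, ...) {
  lab <- switch(x$method, trf = "TRF-pathway", rf = "RF-pathway",
                setbased = "set-based (PLINK-style)")
  cat(sprintf("<pathway_test> %s, %s\n", x$pathway_id, lab))
  if (x$method == "setbased") {
    cat(sprintf("  statistic S = %.4f (mean chi-square of significant tag SNPs)\n",
                x$statistic))
    cat(sprintf("  tag SNPs: %d of %d\n", length(x$selected), x$n_snps_stage1))
  } else {
    cat(sprintf("  score R (OOB error) = %.4f;  SNPs stage 1/2: %d/%d\n",
                x$statistic, x$n_snps_stage1, x$n_snps_stage2))
  }
  cat(sprintf("  p = %.4g  (K = %d permutations)\n", x$p_value,
              x$n_permutations))
  invisible(x)
}

#' @rdname trf_pathway_test
#' @param x A `pathway_test` object.
#' @param ... Unused.
#' @method tidy pathway_test
#' @export
tidy.pathway_test <- function(x, ...) {
  if (is.null(x$importance_z)) {
    return(tibble(snp_id = character(), importance_z = numeric(),
                  selected = logical()))
  }
  tibble(snp_id = names(x$importance_z),
         importance_z = unname(x$importance_z),
         selected = names(x$importance_z) %in% x$selected) |>
    dplyr::arrange(dplyr::desc(.data$importance_z))
}

#' @rdname trf_pathway_test
#' @method glance pathway_test
#' @export
glance.pathway_test <- function(x, ...) {
  tibble(pathway_id = x$pathway_id, method = x$method,
         statistic = x$statistic, p_value = x$p_value,
         n_snps_stage1 = x$n_snps_stage1, n_snps_stage2 = x$n_snps_stage2,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' Test every pathway of a collection
#'
#' Maps each pathway's genes to SNPs ([map_snps_to_pathway()]), runs the
#' requested tests on each mappable pathway, and returns one tidy row per
#' pathway sorted by the primary p-value.  Pathways mapping to zero SNPs are
#' retained as skipped rows.  A Bonferroni-adjusted column for the primary
#' method is included; because pathways share genes the tests are not
#' independent and this adjustment is conservative.
#'
#' @param x A [genotype_matrix()] whose SNP ids match the `snps` annotation.
#' @param pathways Tibble from [read_gmt()].
#' @param genes Gene annotation ([read_gene_annotations()]).
#' @param snps SNP annotation ([read_snp_map()]).
#' @param config A [trf_config()]; its `window_kb` drives the mapping and its
#'   forest seed the per-pathway seeds.
#' @param methods Subset of `c("trf", "rf", "setbased")`; the first is the
#'   primary method used for sorting and adjustment.
#' @param set_config A [set_test_config()] for the set-based comparator.
#' @param verbose Print per-pathway progress.
#' @return A tibble with columns `pathway_id`, `name`, `n_genes`,
#'   `n_genes_matched`, `n_snps`, per-method p-value columns (`trf_p`,
#'   `rf_p`, `plink_p`), `n_snps_stage2` and `R` for the TRF test when run,
#'   `p_bonferroni`, and `skipped`.
#' @export
run_pathway_collection <- function(x, pathways, genes, snps,
                                   config = trf_config(),
                                   methods = c("trf"),
                                   set_config = set_test_config(
                                     n_permutations = config$n_permutations,
                                     seed = config$forest$seed),
                                   verbose = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"), is.data.frame(pathways))
  methods <- match.arg(methods, c("trf", "rf", "setbased"), several.ok = TRUE)
  pcol <- c(trf = "trf_p", rf = "rf_p", setbased = "plink_p")

  rows <- purrr::map(seq_len(nrow(pathways)), function(i) {
    pw <- pathways[i, ]
    ss <- map_snps_to_pathway(pw, genes, snps, window_kb = config$window_kb)
    present <- ss$snp_ids[ss$snp_ids %in% x$snp_ids]
    out <- tibble(pathway_id = pw$pathway_id, name = pw$name,
                  n_genes = pw$n_genes, n_genes_matched = ss$n_genes_matched,
                  n_snps = length(present), n_snps_stage2 = NA_integer_,
                  R = NA_real_, trf_p = NA_real_, rf_p = NA_real_,
                  plink_p = NA_real_, skipped = length(present) == 0)
    if (length(present) == 0) return(out)
    # the per-pathway seed hashes the SNP set, so pathways with identical SNP
    # sets get identical p-values regardless of their position in the table
    seed_i <- derive_seed(config$forest$seed, snpset_hash(present))
    for (m in methods) {
      if (m == "setbased") {
        cfg <- set_config
        cfg$seed <- seed_i
        fit <- set_based_test(x, present, cfg, pathway_id = pw$pathway_id)
      } else {
        cfg <- config
        cfg$forest$seed <- seed_i
        if (m == "rf") cfg$importance_threshold <- NULL
        fit <- trf_pathway_test(x, present, cfg, pathway_id = pw$pathway_id)
        if (m == "trf") {
          out$n_snps_stage2 <- fit$n_snps_stage2
          out$R <- fit$statistic
        }
      }
      out[[pcol[m]]] <- fit$p_value
    }
    if (verbose) {
      message(sprintf("pathway %s: %d SNPs, %s = %.4g", pw$pathway_id,
                      length(present), pcol[methods[1]],
                      out[[pcol[methods[1]]]]))
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  primary <- pcol[methods[1]]
  n_tested <- sum(!res$skipped)
  res$p_bonferroni <- ifelse(res$skipped, NA_real_,
                             pmin(1, res[[primary]] * n_tested))
  keep <- c("pathway_id", "name", "n_genes", "n_genes_matched", "n_snps",
            if ("trf" %in% methods) c("n_snps_stage2", "R"),
            unname(pcol[methods]), "p_bonferroni", "skipped")
  res <- res[, keep]
  res[order(res$skipped, res[[primary]]), ]
}
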