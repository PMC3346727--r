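#' Random-forest configuration
#'
#' Settings for the classification forests used by the pathway tests.
#' Defaults follow the common random-forest conventions for classification:
#' 500 trees, `mtry = floor(sqrt(p))` candidate SNPs per split, terminal
#' nodes grown to size 1 (purity), Gini splitting, and n-sample bootstraps
#' drawn with replacement.
#'
#' @param n_trees Number of trees (>= 1).
#' @param mtry `"sqrt"` (default) for `floor(sqrt(p))`, or a fixed integer
#'   number of candidate SNPs per split (capped at the number of SNPs).
#' @param min_node_size Minimum terminal-node size (default 1).
#' @param seed Integer seed; together with the data it fully determines the
#'   fit.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, mtry = "sqrt", min_node_size = 1,
                          seed = 1) {
  if (!is_count(n_trees)) abort("`n_trees` must be a positive integer")
  if (!(identical(mtry, "sqrt") || is_count(mtry))) {
    abort('`mtry` must be "sqrt" or a positive integer')
  }
  if (!is_count(min_node_size)) abort("`min_node_size` must be a positive integer")
  if (!is_count(seed, min = 0)) abort("`seed` must be a non-negative integer")
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         min_node_size = as.integer(min_node_size), seed = as.integer(seed)),
    class = "forest_config"
  )
}

#' @export
print.forest_config <- function(x, ...) {
  cat(sprintf("<forest_config> %d trees, mtry = %s, min node size %d, seed %d\n",
              x$n_trees, as.character(x$mtry), x$min_node_size, x$seed))
  invisible(x)
}

# mtry as the integer the C++ engine expects (0 = recompute floor(sqrt(p))
# per forest stage)
mtry_code <- function(mtry) {
  if (identical(mtry, "sqrt")) 0L else as.integer(mtry)
}

# Columns are handed to the engine ordered by SNP id, and the importance
# permutation streams are keyed by that canonical position, so a fit is
# invariant to the column order of the input matrix.
canonical_order <- function(snp_ids) order(snp_ids, method = "radix")

check_testable <- function(x, idx) {
  if (anyNA(x$dosages[, idx])) {
    abort("genotypes contain missing values; run impute_missing() first")
  }
  if (length(unique(x$phenotype)) < 2) {
    abort("phenotype must contain both cases and controls")
  }
}

#' Fit a random-forest classifier and score SNP importance
#'
#' Grows a forest of classification trees on bootstrap samples (drawn with
#' replacement, same size as the data), predicts each sample by the majority
#' vote of the trees for which it is out of bag (OOB), and reports the OOB
#' prediction error together with the standardized permutation importance of
#' every SNP.
#'
#' The importance of SNP *j* is computed per tree as the decrease in OOB
#' accuracy after permuting the SNP's genotypes within that tree's OOB set;
#' the per-tree decreases are averaged over trees and divided by their
#' standard error, giving a Z score (0 when the decreases have zero
#' variance).  Vote ties classify a sample as control.
#'
#' @param x A [genotype_matrix()] without missing values.
#' @param snps SNP selection: `NULL` (all), integer column indices, SNP ids,
#'   or a [map_snps_to_pathway()] result.
#' @param config A [forest_config()].
#' @param importance Compute importance Z scores (default `TRUE`).
#' @return An object of class `forest_fit`: `oob_error`, `importance_z`
#'   (named vector, `NULL` if not requested), `oob_votes` (per-sample case
#'   vote fraction, `NA` for samples never out of bag), `n_oob_samples`,
#'   `n_trees_used`, `snp_ids`, `config`.
#' @examples
#' gm <- simulate_case_control(scenario_spec("S1", scale = 0.05),
#'                             effect_model_spec("null"), seed = 1)
#' fit <- fit_forest(gm, config = forest_config(n_trees = 50, seed = 1))
#' glance(fit)
#' @export
fit_forest <- function(x, snps = NULL, config = forest_config(),
                       importance = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "forest_config"))
  idx <- resolve_snp_subset(x, snps)
  check_testable(x, idx)
  ids <- x$snp_ids[idx]
  ord <- canonical_order(ids)
  fit <- cpp_fit_forest(x$dosages[, idx[ord], drop = FALSE], x$phenotype,
                        config$n_trees,
                        if (identical(config$mtry, "sqrt"))
                          max(1L, as.integer(floor(sqrt(length(idx)))))
                        else min(as.integer(config$mtry), length(idx)),
                        config$min_node_size, config$seed, importance)
  z <- NULL
  if (importance) {
    z <- numeric(length(idx))
    z[ord] <- fit$importance_z
    names(z) <- ids
  }
  votes <- ifelse(fit$tot_votes > 0, fit$case_votes / fit$tot_votes, NA_real_)
  structure(
    list(oob_error = fit$oob_error,
         importance_z = z,
         oob_votes = stats::setNames(votes, x$sample_ids),
         n_oob_samples = fit$n_oob_samples,
         n_trees_used = fit$n_trees_used,
         snp_ids = ids,
         config = config),
    class = "forest_fit"
  )
}

#' @export
print.forest_fit <- function(x, ...) {
  cat(sprintf("<forest_fit> %d SNPs, %d trees; OOB error %.4f (%d samples voted)\n",
              length(x$snp_ids), x$n_trees_used, x$oob_error, x$n_oob_samples))
  if (!is.null(x$importance_z)) {
    top <- sort(x$importance_z, decreasing = TRUE)
    top <- top[seq_len(min(3, length(top)))]
    cat("  top importance Z:",
        paste(sprintf("%s = %.2f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_forest
#' @param x A `forest_fit` object.
#' @param ... Unused.
#' @method tidy forest_fit
#' @export
tidy.forest_fit <- function(x, ...) {
  if (is.null(x$importance_z)) {
    return(tibble(snp_id = x$snp_ids))
  }
  tibble(snp_id = x$snp_ids, importance_z = unname(x$importance_z))
}

#' @rdname fit_forest
#' @method glance forest_fit
#' @export
glance.forest_fit <- function(x, ...) {
  tibble(oob_error = x$oob_error, n_snps = length(x$snp_ids),
         n_trees = x$n_trees_used, n_oob_samples = x$n_oob_samples)
}
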