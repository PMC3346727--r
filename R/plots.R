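#' Plot a pathway test against its permutation null
#'
#' Histogram of the permuted pathway scores with the observed score marked;
#' for the forest tests smaller scores (OOB error) are more extreme, for the
#' set-based test larger statistics are.
#'
#' @param object A `pathway_test` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_test
#' @export
autoplot.pathway_test <- function(object, bins = 30, ...) {
  df <- tibble(statistic = object$perm_statistics)
  lab <- if (object$method == "setbased") "pathway statistic S (mean chi-square)"
         else "pathway score R (OOB error)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s (%s)", object$pathway_id, object$method),
      subtitle = sprintf("observed = %.4f, p = %.4g (K = %d)",
                         object$statistic, object$p_value,
                         object$n_permutations),
      x = lab, y = "permutations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot stage-1 importance scores of a forest fit
#'
#' @param object A `forest_fit` with importance scores.
#' @param threshold Reference line (default 1.64, the one-tailed 5% normal
#'   quantile used for stage-2 selection).
#' @param top Show at most this many top SNPs.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot forest_fit
#' @export
autoplot.forest_fit <- function(object, threshold = 1.64, top = 30, ...) {
  if (is.null(object$importance_z)) {
    abort("fit has no importance scores")
  }
  df <- tidy(object) |>
    dplyr::arrange(dplyr::desc(.data$importance_z)) |>
    utils::head(top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance_z,
    y = stats::reorder(.data$snp_id, .data$importance_z))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "standardized importance Z", y = NULL,
                  title = sprintf("Top %d SNPs by importance", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates of a Monte-Carlo experiment
#'
#' @param object A `pathway_experiment`.
#' @param ... Unused.
#' @return A ggplot object showing the rejection rate and its exact binomial
#'   95% CI at each nominal level, with the nominal level as reference.
#' @method autoplot pathway_experiment
#' @export
autoplot.pathway_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$rates, level_f = factor(.data$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level_f, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$level), shape = 4, size = 3,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "nominal level", y = "rejection rate",
      title = sprintf("%s / %s / %s", object$scenario, object$effects,
                      object$method),
      subtitle = sprintf("%d replicates, K = %d (x = nominal)",
                         object$n_replicates, object$n_permutations)
    ) +
    ggplot2::theme_minimal()
}
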