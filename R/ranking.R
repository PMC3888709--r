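#' Differential-expression percentage per gene
#'
#' The vote-counting statistic: for each gene, the number of groups in which
#' its gene-level p-value is at or below `p_threshold` (the boundary counts),
#' divided by the number of groups in which the gene is measured at all (not
#' the total number of groups), times 100.
#'
#' @param gene_results Tibble of per-(group, gene) results as produced by
#'   [test_groups()]: columns `group_id`, `gene_id`, `p_value`.
#' @param p_threshold Significance threshold per group (default 0.05,
#'   inclusive).
#' @return Tibble with one row per gene: `gene_id`, `n_measured`,
#'   `n_significant`, `percentage`.
#' @export
de_percentages <- function(gene_results, p_threshold = 0.05) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  gene_results %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_measured = n_distinct(.data$group_id),
      n_significant = sum(.data$p_value <= p_threshold),
      .groups = "drop"
    ) %>%
    mutate(percentage = 100 * .data$n_significant / .data$n_measured)
}

#' Rank genes by differential-expression percentage
#'
#' Descending percentage; ties broken by larger `n_measured` (more evidence
#' first), then lexicographic gene id. Ranks are dense 1..N over the sorted
#' order, so the output is invariant to input row order.
#'
#' @param records Output of [de_percentages()].
#' @return The records, sorted, with a `rank` column.
#' @export
rank_genes <- function(records) {
  records %>%
    arrange(desc(.data$percentage), desc(.data$n_measured), .data$gene_id) %>%
    mutate(rank = row_number())
}

#' Select candidate genes from a ranking
#'
#' Applies the minimum-evidence filter (`n_measured >= min_groups`; the
#' obesity arm of the original design used 10) and the percentage threshold.
#' `threshold_mode` distinguishes the genome-wide selection convention
#' (at least, e.g. >= 50) from the SNP-screen convention (strictly greater,
#' e.g. > 40).
#'
#' @param ranked Output of [rank_genes()].
#' @param candidate_threshold_pct Percentage threshold in [0, 100].
#' @param threshold_mode `"at_least"` or `"strictly_greater"`.
#' @param min_groups Minimum number of groups measuring the gene (default 0).
#' @return The candidate subset of `ranked`, order preserved.
#' @export
select_candidates <- function(ranked, candidate_threshold_pct,
                              threshold_mode = c("at_least", "strictly_greater"),
                              min_groups = 0) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(candidate_threshold_pct >= 0, candidate_threshold_pct <= 100)
  pass <- if (threshold_mode == "at_least") {
    ranked$percentage >= candidate_threshold_pct
  } else {
    ranked$percentage > candidate_threshold_pct
  }
  ranked[pass & ranked$n_measured >= min_groups, , drop = FALSE]
}

#' Mean differential-expression percentage
#'
#' Unweighted mean of the per-gene percentages (the study-level summary such
#' as "the average percentage of all genes").
#'
#' @param records Output of [de_percentages()].
#' @return A single number in [0, 100].
#' @export
mean_percentage <- function(records) {
  if (nrow(records) == 0) abort("mean_percentage: empty record set")
  mean(records$percentage)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up FDR, input
#' order preserved. Used for the reporting comparison of adjustment methods;
#' candidate selection itself always uses raw per-group p <= 0.05.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("adjust_pvalues: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = switch(method, bonferroni = "bonferroni", bh_fdr = "BH"))
}

#' Compare raw, FDR and Bonferroni significant counts per group
#'
#' For each group, counts genes significant at `alpha` under the raw
#' p-values, BH-FDR-adjusted values and Bonferroni-adjusted values. By
#' construction raw >= fdr >= bonferroni in every group.
#'
#' @param gene_results Per-(group, gene) results with `group_id`, `p_value`.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble per group: `group_id`, `n_genes`, `raw_significant`,
#'   `fdr_significant`, `bonferroni_significant`.
#' @export
compare_adjustment <- function(gene_results, alpha = 0.05) {
  gene_results %>%
    group_by(.data$group_id) %>%
    summarise(
      n_genes = n(),
      raw_significant = sum(.data$p_value <= alpha),
      fdr_significant = sum(adjust_pvalues(.data$p_value, "bh_fdr") <= alpha),
      bonferroni_significant = sum(adjust_pvalues(.data$p_value, "bonferroni") <= alpha),
      .groups = "drop"
    )
}

#' Vote-count and rank genes across groups
#'
#' Convenience wrapper tying the ranking stage together: computes per-gene
#' differential-expression percentages, ranks them, and flags candidates.
#' Returns a `tv_vote` object with [tidy()], [glance()] and [autoplot()]
#' methods.
#'
#' @inheritParams de_percentages
#' @inheritParams select_candidates
#' @return A `tv_vote` object; `tidy()` yields the ranked records with a
#'   logical `candidate` column.
#' @export
vote_count <- function(gene_results, p_threshold = 0.05,
                       candidate_threshold_pct = 50,
                       threshold_mode = c("at_least", "strictly_greater"),
                       min_groups = 0) {
  threshold_mode <- match.arg(threshold_mode)
  ranked <- rank_genes(de_percentages(gene_results, p_threshold))
  cand <- select_candidates(ranked, candidate_threshold_pct, threshold_mode,
                            min_groups)
  ranked$candidate <- ranked$gene_id %in% cand$gene_id
  structure(
    list(
      records = ranked,
      config = list(
        p_threshold = p_threshold,
        candidate_threshold_pct = candidate_threshold_pct,
        threshold_mode = threshold_mode,
        min_groups = min_groups
      )
    ),
    class = "tv_vote"
  )
}

#' @export
print.tv_vote <- function(x, ...) {
  cat(sprintf(
    "<tv_vote> %d genes ranked; %d candidate(s) at %s %g%% (min %d groups)\n",
    nrow(x$records), sum(x$records$candidate),
    if (x$config$threshold_mode == "at_least") ">=" else ">",
    x$config$candidate_threshold_pct, x$config$min_groups
  ))
  print(head(x$records, 10))
  invisible(x)
}

#' @rdname vote_count
#' @param x A `tv_vote` object.
#' @param ... Unused.
#' @export
tidy.tv_vote <- function(x, ...) {
  x$records
}

#' @rdname vote_count
#' @method glance tv_vote
#' @export
glance.tv_vote <- function(x, ...) {
  tibble(
    n_genes = nrow(x$records),
    n_candidates = sum(x$records$candidate),
    mean_percentage = mean_percentage(x$records),
    p_threshold = x$config$p_threshold,
    candidate_threshold_pct = x$config$candidate_threshold_pct,
    threshold_mode = x$config$threshold_mode,
    min_groups = x$config$min_groups
  )
}

#' @rdname vote_count
#' @param object A `tv_vote` object.
#' @method autoplot tv_vote
#' @export
autoplot.tv_vote <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$percentage, fill = .data$candidate)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$config$candidate_threshold_pct,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "differential expression percentage",
      y = "genes",
      fill = "candidate",
      title = "Vote-counting across groups"
    ) +
    ggplot2::theme_minimal()
}
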