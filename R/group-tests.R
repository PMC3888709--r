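#' Two-sided variance-ratio (F) pretest
#'
#' Computes the F statistic as the larger sample variance over the smaller
#' (so F >= 1) with the corresponding (numerator, denominator) degrees of
#' freedom, and the two-sided tail probability capped at 1. Used to decide
#' between the pooled and Welch t-test for each probe.
#'
#' @param case_values,control_values Numeric vectors, each of length >= 2.
#' @return A list with `f_statistic`, `f_p`, `df1`, `df2`.
#' @export
variance_ratio_test <- function(case_values, control_values) {
  check_two_samples(case_values, control_values)
  v1 <- var(case_values)
  v2 <- var(control_values)
  if (v1 == 0 && v2 == 0) {
    abort("variance_ratio_test: both sample variances are zero (degenerate)")
  }
  if (v1 >= v2) {
    f <- v1 / v2
    df1 <- length(case_values) - 1L
    df2 <- length(control_values) - 1L
  } else {
    f <- v2 / v1
    df1 <- length(control_values) - 1L
    df2 <- length(case_values) - 1L
  }
  upper <- pf(f, df1, df2, lower.tail = FALSE)
  list(
    f_statistic = f,
    f_p = min(1, 2 * min(upper, 1 - upper)),
    df1 = df1, df2 = df2
  )
}

#' Pooled-variance two-sample t-test
#'
#' Standard two-sided equal-variance t-test with df = n1 + n2 - 2. The sign
#' convention is case minus control.
#'
#' @inheritParams variance_ratio_test
#' @return A list with `t_statistic`, `df`, `p_value`.
#' @export
t_test_pooled <- function(case_values, control_values) {
  check_two_samples(case_values, control_values)
  n1 <- length(case_values); n2 <- length(control_values)
  sp2 <- ((n1 - 1) * var(case_values) + (n2 - 1) * var(control_values)) /
    (n1 + n2 - 2)
  t <- (mean(case_values) - mean(control_values)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t_statistic = t, df = df, p_value = two_sided_t_p(t, df))
}

#' Welch unequal-variance two-sample t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom
#' (generally fractional). Sign convention is case minus control.
#'
#' @inheritParams variance_ratio_test
#' @return A list with `t_statistic`, `df`, `p_value`.
#' @export
t_test_welch <- function(case_values, control_values) {
  check_two_samples(case_values, control_values)
  n1 <- length(case_values); n2 <- length(control_values)
  v1 <- var(case_values); v2 <- var(control_values)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(case_values) - mean(control_values)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t_statistic = t, df = df, p_value = two_sided_t_p(t, df))
}

#' F-gated probe test
#'
#' Runs the variance-ratio pretest and then either the pooled t-test (when
#' the two-sided F p-value is >= `f_alpha`, including exact equality) or the
#' Welch t-test (when it is below `f_alpha`). When both sample variances are
#' zero the probe is flagged degenerate: p = 1 if the means are equal, p = 0
#' otherwise, with a warning.
#'
#' @inheritParams variance_ratio_test
#' @param f_alpha Significance level of the variance-ratio pretest
#'   (default 0.05).
#' @return One-row tibble: `f_statistic`, `f_p`, `variance_equal`, `branch`
#'   (`pooled`/`welch`/`degenerate`), `t_statistic`, `t_df`, `p_value`,
#'   `mean_case`, `mean_control`.
#' @export
select_and_test <- function(case_values, control_values, f_alpha = 0.05) {
  check_two_samples(case_values, control_values)
  m1 <- mean(case_values); m2 <- mean(control_values)
  v1 <- var(case_values); v2 <- var(control_values)
  if (v1 == 0 && v2 == 0) {
    warn("select_and_test: both sample variances are zero; degenerate rule applied")
    return(tibble(
      f_statistic = NA_real_, f_p = NA_real_, variance_equal = NA,
      branch = "degenerate", t_statistic = NA_real_, t_df = NA_real_,
      p_value = if (m1 == m2) 1 else 0, mean_case = m1, mean_control = m2
    ))
  }
  f <- variance_ratio_test(case_values, control_values)
  eq <- f$f_p >= f_alpha
  tt <- if (eq) t_test_pooled(case_values, control_values)
        else t_test_welch(case_values, control_values)
  tibble(
    f_statistic = f$f_statistic, f_p = f$f_p, variance_equal = eq,
    branch = if (eq) "pooled" else "welch",
    t_statistic = tt$t_statistic, t_df = tt$df, p_value = tt$p_value,
    mean_case = m1, mean_control = m2
  )
}

#' Resolve probes to unique genes
#'
#' Probes annotated to zero genes or to more than one gene are excluded;
#' only single-gene probes survive. Drop counts are reported per reason.
#'
#' @param annotation Tibble `platform_id`, `probe_id`, `gene_id` (NA for
#'   unannotated probes), one row per (probe, gene) pair.
#' @return Tibble `platform_id`, `probe_id`, `gene_id` with one row per
#'   retained probe.
#' @export
resolve_probes <- function(annotation) {
  ann <- distinct(annotation, .data$platform_id, .data$probe_id, .data$gene_id)
  nn <- ann %>% filter(!is.na(.data$gene_id))
  cnt <- nn %>% count(.data$platform_id, .data$probe_id, name = "n_genes")
  n_multi <- sum(cnt$n_genes >= 2)
  n_none <- nrow(distinct(ann, .data$platform_id, .data$probe_id)) - nrow(cnt)
  if (n_multi + n_none > 0) {
    inform(sprintf(
      "resolve_probes: excluded %d multi-gene and %d unannotated probe(s)",
      n_multi, n_none
    ))
  }
  kept <- nn %>%
    semi_join(cnt %>% filter(.data$n_genes == 1),
              by = c("platform_id", "probe_id")) %>%
    arrange(.data$platform_id, .data$probe_id)
  if (nrow(kept) == 0) warn("resolve_probes: no probes retained")
  kept
}

#' Per-gene differential expression test for one group
#'
#' Applies the F-gated t-test to every retained (single-gene) probe of the
#' group, then aggregates to gene level: the gene p-value is the minimum
#' across its probes and the direction (up = case above control) is taken
#' from the probe attaining that minimum (ties broken by probe id).
#'
#' @param group A [expression_group()].
#' @param annotation Probe annotation tibble covering the group's platform.
#' @param f_alpha Variance-ratio pretest level (default 0.05).
#' @return Tibble with one row per gene: `group_id`, `gene_id`, `p_value`,
#'   `direction` (`up`/`down`/`flat`), `n_probes_used`, `branch` (test branch
#'   of the minimum-P probe).
#' @export
test_group <- function(group, annotation, f_alpha = 0.05) {
  validate_expression_group(group)
  ann <- annotation %>% filter(.data$platform_id == group$platform_id)
  kept <- suppressMessages(resolve_probes(ann)) %>%
    filter(.data$probe_id %in% rownames(group$values))
  if (nrow(kept) == 0) {
    warn(sprintf("test_group: group '%s' has no retained probes", group$group_id))
    return(tibble(group_id = character(), gene_id = character(),
                  p_value = double(), direction = character(),
                  n_probes_used = integer(), branch = character()))
  }
  pt <- probe_tests(group, probe_ids = kept$probe_id, f_alpha = f_alpha)
  j <- inner_join(pt, kept, by = "probe_id")
  # min-P probe per gene: sort by (gene, p, probe) and keep the first row
  j <- j[order(j$gene_id, j$p_value, j$probe_id), ]
  top <- j[!duplicated(j$gene_id), ]
  n_probes <- as.integer(table(j$gene_id))  # table is sorted by gene_id
  delta <- top$mean_case - top$mean_control
  tibble(
    group_id = group$group_id,
    gene_id = top$gene_id,
    p_value = top$p_value,
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "flat")),
    n_probes_used = n_probes,
    branch = top$branch
  )
}

#' Per-gene tests across many groups
#'
#' @param groups List of expression groups.
#' @param annotation Probe annotation tibble covering all platforms.
#' @inheritParams test_group
#' @return Row-bound [test_group()] results for all groups.
#' @export
test_groups <- function(groups, annotation, f_alpha = 0.05) {
  purrr::map_dfr(groups, test_group, annotation = annotation, f_alpha = f_alpha)
}

#' Vectorized F-gated probe tests for a whole expression matrix
#'
#' The row-wise engine behind [test_group()]: computes for every requested
#' probe the variance-ratio pretest and the selected t-test in one pass over
#' the matrix. Scalar results agree with [select_and_test()] exactly.
#'
#' @param group A [expression_group()].
#' @param probe_ids Probes to test (default: all rows).
#' @inheritParams test_group
#' @return Tibble with one row per probe: `probe_id`, `mean_case`,
#'   `mean_control`, `f_statistic`, `f_p`, `variance_equal`, `branch`,
#'   `t_statistic`, `t_df`, `p_value`.
#' @export
probe_tests <- function(group, probe_ids = rownames(group$values),
                        f_alpha = 0.05) {
  x <- group$values[probe_ids, group$case_samples, drop = FALSE]
  y <- group$values[probe_ids, group$control_samples, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- unname(rowMeans(x)); m2 <- unname(rowMeans(y))
  v1 <- unname(rowSums((x - m1)^2)) / (n1 - 1)
  v2 <- unname(rowSums((y - m2)^2)) / (n2 - 1)

  degen <- v1 == 0 & v2 == 0
  if (any(degen)) {
    warn(sprintf("probe_tests: %d probe(s) with zero variance on both sides; degenerate rule applied",
                 sum(degen)))
  }

  case_larger <- v1 >= v2
  f <- ifelse(case_larger, v1 / pmax(v2, .Machine$double.xmin),
              v2 / pmax(v1, .Machine$double.xmin))
  df1 <- ifelse(case_larger, n1 - 1, n2 - 1)
  df2 <- ifelse(case_larger, n2 - 1, n1 - 1)
  f_upper <- pf(f, df1, df2, lower.tail = FALSE)
  f_p <- pmin(1, 2 * pmin(f_upper, 1 - f_upper))

  eq <- f_p >= f_alpha

  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_pool <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_pool <- rep(n1 + n2 - 2, length(m1))

  se2 <- v1 / n1 + v2 / n2
  t_welch <- (m1 - m2) / sqrt(se2)
  df_welch <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))

  t_stat <- ifelse(eq, t_pool, t_welch)
  t_df <- ifelse(eq, df_pool, df_welch)
  p <- 2 * pt(-abs(t_stat), t_df)

  tibble(
    probe_id = probe_ids,
    mean_case = unname(m1), mean_control = unname(m2),
    f_statistic = ifelse(degen, NA_real_, unname(f)),
    f_p = ifelse(degen, NA_real_, unname(f_p)),
    variance_equal = ifelse(degen, NA, unname(eq)),
    branch = ifelse(degen, "degenerate", ifelse(eq, "pooled", "welch")),
    t_statistic = ifelse(degen, NA_real_, unname(t_stat)),
    t_df = ifelse(degen, NA_real_, unname(t_df)),
    p_value = ifelse(degen, ifelse(m1 == m2, 1, 0), unname(p))
  )
}

check_two_samples <- function(case_values, control_values) {
  if (length(case_values) < 2 || length(control_values) < 2) {
    abort("each subgroup needs at least 2 values")
  }
  if (!all(is.finite(case_values)) || !all(is.finite(control_values))) {
    abort("expression values must be finite")
  }
  invisible(TRUE)
}

two_sided_t_p <- function(t, df) {
  2 * pt(-abs(t), df)
}
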