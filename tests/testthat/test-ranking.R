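make_results <- function(p_by_gene) {
  # p_by_gene: named list gene -> vector of per-group p values
  purrr::imap_dfr(p_by_gene, function(p, g) {
    tibble::tibble(group_id = sprintf("grp%02d", seq_along(p)),
                   gene_id = g, p_value = p)
  })
}

test_that("the percentage counts significant groups over measured groups, boundary inclusive", {
  rec <- de_percentages(make_results(list(A = c(0.01, 0.05, 0.20))))
  expect_identical(rec$n_significant, 2L)
  expect_identical(rec$n_measured, 3L)
  expect_equal(rec$percentage, 100 * 2 / 3)

  rec0 <- de_percentages(make_results(list(A = c(0.2, 0.9, 0.06))))
  expect_equal(rec0$percentage, 0)

  # k = 11 of n = 18 renders as the printed convention "61.1"
  rec2 <- de_percentages(make_results(list(A = c(rep(0.01, 11), rep(0.5, 7)))))
  expect_identical(tissuevote:::format_percentage(rec2$percentage), "61.1")

  # the denominator is groups measuring the gene, not all groups
  mixed <- dplyr::bind_rows(
    tibble::tibble(group_id = sprintf("grp%02d", 1:10), gene_id = "A",
                   p_value = rep(c(0.01, 0.5), 5)),
    tibble::tibble(group_id = sprintf("grp%02d", 1:4), gene_id = "B",
                   p_value = c(0.01, 0.01, 0.01, 0.5))
  )
  rec3 <- de_percentages(mixed)
  expect_equal(rec3$percentage[rec3$gene_id == "B"], 75)
  expect_identical(rec3$n_measured[rec3$gene_id == "B"], 4L)
})

test_that("raising the p threshold never decreases any percentage", {
  set.seed(5)
  res <- make_results(purrr::map(setNames(1:30, sprintf("G%02d", 1:30)),
                                 ~ runif(12)))
  for (thr in c(0.01, 0.05, 0.1, 0.5)) {
    lo <- de_percentages(res, p_threshold = thr)
    hi <- de_percentages(res, p_threshold = min(thr * 2, 0.99))
    j <- dplyr::inner_join(lo, hi, by = "gene_id")
    expect_true(all(j$percentage.y >= j$percentage.x))
  }
})

test_that("ranking is by percentage then evidence then gene id, invariant to input order", {
  recs <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    n_measured = c(20L, 6L, 18L, 6L),
    n_significant = c(10L, 3L, 12L, 3L),
    percentage = c(50, 50, 100 * 12 / 18, 50)
  )
  ranked <- rank_genes(recs)
  expect_identical(ranked$gene_id, c("C", "A", "B", "D"))
  expect_identical(ranked$rank, 1:4)

  # brute-force sort oracle under random permutations
  set.seed(9)
  for (i in 1:10) {
    perm <- rank_genes(recs[sample(nrow(recs)), ])
    expect_identical(perm$gene_id, ranked$gene_id)
    o <- order(-recs$percentage, -recs$n_measured, recs$gene_id)
    expect_identical(perm$gene_id, recs$gene_id[o])
  }
})

test_that("candidate selection honours threshold mode and the minimum-groups filter", {
  ranked <- rank_genes(tibble::tibble(
    gene_id = c("A", "B", "C"), n_measured = c(12L, 12L, 12L),
    n_significant = c(7L, 6L, 5L), percentage = c(55, 50, 49)
  ))
  expect_identical(select_candidates(ranked, 50, "at_least")$gene_id,
                   c("A", "B"))
  expect_identical(select_candidates(ranked, 50, "strictly_greater")$gene_id,
                   "A")

  few <- rank_genes(tibble::tibble(gene_id = "Z", n_measured = 9L,
                                   n_significant = 9L, percentage = 100))
  expect_identical(nrow(select_candidates(few, 60, "at_least", min_groups = 10)), 0L)
})

test_that("mean percentage behaves on edge cases and under the null", {
  two <- tibble::tibble(percentage = c(0, 100))
  expect_equal(mean_percentage(two), 50)
  expect_equal(mean_percentage(two[1, ]), 0)
  expect_error(mean_percentage(two[0, ]), "empty")

  # null simulation: percentages average near the per-group false positive rate
  sim <- simulate_studies(sim_config(
    n_groups = 20, n_genes = 2000, n_planted = 0, probes_per_gene = c(1, 1),
    multi_gene_probe_fraction = 0, platform_gene_dropout = 0, seed = 83
  ))
  recs <- de_percentages(test_groups(sim$groups, sim$annotation))
  se <- 100 * sqrt(0.05 * 0.95 / (20 * 2000))
  expect_lt(abs(mean_percentage(recs) - 5), 3 * se)
})

test_that("null per-gene significant counts are binomial (chi-square GOF)", {
  sim <- simulate_studies(sim_config(
    n_groups = 21, n_genes = 500, n_planted = 0, probes_per_gene = c(1, 1),
    multi_gene_probe_fraction = 0, platform_gene_dropout = 0, seed = 97
  ))
  recs <- de_percentages(test_groups(sim$groups, sim$annotation))
  # bin counts k = 0, 1, 2, >= 3 against Binomial(21, 0.05)
  k <- pmin(recs$n_significant, 3)
  obs <- tabulate(k + 1, nbins = 4)
  probs <- c(dbinom(0:2, 21, 0.05), 1 - pbinom(2, 21, 0.05))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("p-value adjustment matches hand-computed oracles and BH dominance", {
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bh_fdr"), 0.03)

  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bonferroni"),
               c(0.04, 0.08, 0.12, 0.16))

  # BH step-up oracle on a fixed vector, computed independently
  p <- c(0.005, 0.011, 0.02, 0.04, 0.3)
  m <- length(p)
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(adjust_pvalues(p, "bh_fdr"), stepup)

  set.seed(17)
  for (i in 1:100) {
    q <- runif(sample(2:30, 1))
    expect_true(all(adjust_pvalues(q, "bh_fdr") <=
                      adjust_pvalues(q, "bonferroni") + 1e-12))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjustment comparison counts are ordered raw >= fdr >= bonferroni", {
  set.seed(23)
  res <- purrr::map_dfr(1:5, function(g) {
    tibble::tibble(group_id = sprintf("grp%02d", g), gene_id = sprintf("G%03d", 1:200),
                   p_value = runif(200))
  })
  cmp <- compare_adjustment(res)
  expect_true(all(cmp$raw_significant >= cmp$fdr_significant))
  expect_true(all(cmp$fdr_significant >= cmp$bonferroni_significant))

  # ten planted near-zero p values are found by every method
  strong <- tibble::tibble(group_id = "grpS", gene_id = sprintf("S%03d", 1:200),
                           p_value = c(rep(1e-8, 10), runif(190, 0.2, 1)))
  cmp2 <- compare_adjustment(strong)
  expect_identical(cmp2$raw_significant, 10L)
  expect_identical(cmp2$fdr_significant, 10L)
  expect_identical(cmp2$bonferroni_significant, 10L)

  empty <- compare_adjustment(strong[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("vote_count ties the stage together with tidy, glance and plot methods", {
  res <- make_results(list(A = c(0.01, 0.02, 0.6), B = c(0.5, 0.6, 0.7)))
  v <- vote_count(res, candidate_threshold_pct = 60)
  td <- tidy(v)
  expect_identical(td$gene_id[td$candidate], "A")
  expect_identical(td$rank, 1:2)
  gl <- glance(v)
  expect_identical(gl$n_candidates, 1L)
  expect_equal(gl$mean_percentage, mean(td$percentage))
  expect_s3_class(autoplot(v), "ggplot")

  # percentage bounds and count consistency on every record
  expect_true(all(td$percentage >= 0 & td$percentage <= 100))
  expect_equal(td$percentage, 100 * td$n_significant / td$n_measured)
})
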