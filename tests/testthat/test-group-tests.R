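test_that("variance-ratio pretest follows the larger-over-smaller convention", {
  r <- variance_ratio_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$f_statistic, 1)
  expect_equal(r$f_p, 1)

  # frozen value from the F tail: var ratio 20/3, df (3, 2)
  r2 <- variance_ratio_test(c(1, 2, 3), c(2, 4, 6, 8))
  expect_equal(r2$f_statistic, 20 / 3 / 1, tolerance = 1e-12)
  expect_identical(c(r2$df1, r2$df2), c(3L, 2L))
  expect_equal(r2$f_p, 0.266431655917105, tolerance = 1e-12)

  # swapping sides changes nothing
  r3 <- variance_ratio_test(c(2, 4, 6, 8), c(1, 2, 3))
  expect_equal(r3[c("f_statistic", "f_p")], r2[c("f_statistic", "f_p")])

  expect_error(variance_ratio_test(c(5, 5, 5), c(5, 5, 5)), "degenerate")
})

test_that("pooled t-test matches the closed form and identical samples give p = 1", {
  r <- t_test_pooled(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(r$df, 4)
  expect_equal(r$p_value, 0.0213116411287567, tolerance = 1e-12)

  r0 <- t_test_pooled(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Welch test matches its frozen oracle values and is scale invariant", {
  r <- t_test_welch(c(0, 0, 1), c(10, 20, 30))
  expect_equal(r$t_statistic, -3.40070346445499, tolerance = 1e-10)
  expect_equal(r$df, 2.01333318518683, tolerance = 1e-10)
  expect_equal(r$p_value, 0.0759516976529189, tolerance = 1e-10)

  # equal sizes and equal sample variances: t identical to pooled
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(t_test_welch(x, y)$t_statistic, t_test_pooled(x, y)$t_statistic)

  r1 <- t_test_welch(x, y)
  r2 <- t_test_welch(10 * x, 10 * y)
  expect_equal(r1$t_statistic, r2$t_statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("t and F p-values agree with stats oracles on random small samples", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3))
    y <- rnorm(n2, sd = runif(1, 0.5, 3))
    expect_equal(t_test_pooled(x, y)$p_value,
                 stats::t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(t_test_welch(x, y)$p_value,
                 stats::t.test(x, y)$p.value,
                 tolerance = 1e-10)
    expect_equal(variance_ratio_test(x, y)$f_p,
                 min(1, stats::var.test(x, y)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("the F gate selects pooled at the boundary and Welch below it", {
  # equal variances: f_p = 1 >= alpha, boundary assigned to pooled
  r <- select_and_test(c(1, 2, 3), c(2, 3, 4), f_alpha = 1)
  expect_identical(r$branch, "pooled")
  expect_true(r$variance_equal)

  # strongly unequal variances
  set.seed(7)
  r2 <- select_and_test(rnorm(6, sd = 0.01), rnorm(6, sd = 10))
  expect_identical(r2$branch, "welch")
  expect_false(r2$variance_equal)

  # degenerate: both sides constant
  expect_warning(r3 <- select_and_test(c(5, 5, 5), c(5, 5, 5)), "degenerate")
  expect_identical(r3$branch, "degenerate")
  expect_equal(r3$p_value, 1)
  expect_warning(r4 <- select_and_test(c(5, 5, 5), c(6, 6, 6)), "degenerate")
  expect_equal(r4$p_value, 0)
})

test_that("branch choice over random inputs mirrors the two-sided F test", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(5, sd = runif(1, 0.3, 4)); y <- rnorm(5, sd = runif(1, 0.3, 4))
    r <- select_and_test(x, y, f_alpha = 0.05)
    f_p <- variance_ratio_test(x, y)$f_p
    expect_identical(r$branch, if (f_p < 0.05) "welch" else "pooled")
  }
})

test_that("probes resolve to unique genes and drops match a brute-force scan", {
  ann <- tibble::tibble(
    platform_id = "GPLX",
    probe_id = c("p1", "p2", "p2", "p3"),
    gene_id = c("A", "A", "B", NA)
  )
  expect_message(kept <- resolve_probes(ann), "1 multi-gene and 1 unannotated")
  expect_identical(kept$probe_id, "p1")
  expect_identical(kept$gene_id, "A")

  # all single-gene: identity pass-through
  ann2 <- tibble::tibble(platform_id = "GPLX", probe_id = c("q1", "q2"),
                         gene_id = c("A", "B"))
  expect_identical(resolve_probes(ann2)$probe_id, c("q1", "q2"))

  # random annotations: retained set equals probes with exactly one gene
  set.seed(21)
  probes <- sprintf("r%04d", 1:1000)
  sizes <- sample(0:3, 1000, replace = TRUE, prob = c(0.15, 0.6, 0.2, 0.05))
  rows <- purrr::map2_dfr(probes, sizes, function(p, k) {
    if (k == 0) tibble::tibble(probe_id = p, gene_id = NA_character_)
    else tibble::tibble(probe_id = p, gene_id = sample(LETTERS, k))
  })
  rows$platform_id <- "GPLR"
  got <- sort(suppressMessages(resolve_probes(rows))$probe_id)
  want <- sort(probes[sizes == 1])
  expect_identical(got, want)
})

test_that("gene-level p is the minimum over probes and carries its probe's direction", {
  g <- make_group(list(
    a1 = c(5.0, 5.2, 5.1, 5.1, 5.0, 5.2),   # gene A, weak probe
    a2 = c(6.5, 6.6, 6.4, 5.0, 5.1, 4.9),   # gene A, strong up probe
    b1 = c(4.0, 4.1, 3.9, 5.0, 5.1, 4.9)    # gene B, single down probe
  ))
  ann <- tibble::tibble(platform_id = "GPLX",
                        probe_id = c("a1", "a2", "b1"),
                        gene_id = c("A", "A", "B"))
  res <- test_group(g, ann)
  pt <- probe_tests(g)

  a <- res[res$gene_id == "A", ]
  expect_equal(a$p_value, min(pt$p_value[pt$probe_id %in% c("a1", "a2")]))
  expect_identical(a$n_probes_used, 2L)
  expect_identical(a$direction, "up")

  b <- res[res$gene_id == "B", ]
  expect_equal(b$p_value, pt$p_value[pt$probe_id == "b1"])
  expect_identical(b$direction, "down")
  expect_identical(b$n_probes_used, 1L)

  # gene-level p never exceeds any contributing probe p
  expect_true(all(a$p_value <= pt$p_value[pt$probe_id %in% c("a1", "a2")]))
})

test_that("row-wise probe tests agree exactly with the scalar gated test", {
  set.seed(31)
  vals <- purrr::map(1:40, ~ rnorm(10, 7, runif(1, 0.5, 2)))
  names(vals) <- sprintf("p%02d", 1:40)
  g <- make_group(vals, n_case = 5, n_control = 5)
  pt <- probe_tests(g)
  for (i in seq_len(nrow(pt))) {
    x <- g$values[pt$probe_id[i], g$case_samples]
    y <- g$values[pt$probe_id[i], g$control_samples]
    s <- select_and_test(x, y)
    expect_equal(pt$p_value[i], s$p_value, tolerance = 1e-12)
    expect_identical(pt$branch[i], s$branch)
    expect_equal(pt$f_p[i], s$f_p, tolerance = 1e-12)
  }
})

test_that("swapping case and control flips direction and preserves p exactly", {
  set.seed(41)
  vals <- purrr::map(1:30, ~ rnorm(8, 7, 1))
  names(vals) <- sprintf("p%02d", 1:30)
  g <- make_group(vals, n_case = 4, n_control = 4)
  ann <- tibble::tibble(platform_id = "GPLX", probe_id = names(vals),
                        gene_id = sprintf("G%02d", 1:30))
  swapped <- expression_group(g$group_id, g$disease, g$tissue, g$platform_id,
                              g$values, case_samples = g$control_samples,
                              control_samples = g$case_samples)
  r1 <- test_group(g, ann)
  r2 <- test_group(swapped, ann)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", flat = "flat")
  expect_identical(unname(flip[r1$direction]), r2$direction)
})

test_that("with no planted effect the per-group significant fraction is calibrated", {
  sim <- simulate_studies(sim_config(
    n_groups = 1, n_genes = 4000, n_planted = 0, probes_per_gene = c(1, 1),
    multi_gene_probe_fraction = 0, platform_gene_dropout = 0, seed = 61
  ))
  res <- test_group(sim$groups[[1]], sim$annotation)
  frac <- mean(res$p_value <= 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(frac - 0.05), tol)
})

test_that("a strongly planted gene attains the smallest gene-level p in most replicates", {
  # one group, 5v5; planted gene has three probes shifted +2 sd, five null
  # genes one probe each; min-P aggregation makes the planted gene dominate
  wins <- 0L
  set.seed(71)
  for (rep in 1:100) {
    vals <- c(
      purrr::map(1:3, ~ c(rnorm(5, 9, 1), rnorm(5, 7, 1))),
      purrr::map(1:5, ~ rnorm(10, 7, 1))
    )
    names(vals) <- sprintf("p%d", 1:8)
    g <- make_group(vals, n_case = 5, n_control = 5)
    ann <- tibble::tibble(platform_id = "GPLX", probe_id = names(vals),
                          gene_id = c("PL", "PL", "PL", sprintf("N%d", 1:5)))
    res <- test_group(g, ann)
    if (res$gene_id[which.min(res$p_value)] == "PL") wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
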