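#' Simulation configuration
#'
#' Defaults describe the default synthetic study: 21 groups over 6 tissues
#' (the structure of a multi-tissue case-control compendium), 2000 genes,
#' 5 samples per subgroup, Gaussian noise with sd 1 on the log2 scale around
#' a baseline of 7, 1-3 probes per gene with 5% multi-gene probes, 10%
#' per-group gene dropout (genes absent from that group's platform), and 20
#' planted genes shifted by 2 noise-sd in 70% of the groups measuring them.
#'
#' @param n_groups Number of case-control groups.
#' @param n_genes Number of genes in the universe.
#' @param probes_per_gene Integer range `c(min, max)`; each (group, gene)
#'   draws its probe count uniformly from it.
#' @param multi_gene_probe_fraction Fraction of probes additionally annotated
#'   to a second random gene; such probes must be excluded downstream.
#' @param samples_per_subgroup Samples per case and per control subgroup
#'   (>= 3).
#' @param baseline_mean Baseline log2 expression.
#' @param noise_sd Noise standard deviation on the log2 scale.
#' @param n_planted Number of planted differentially expressed genes.
#' @param effect_sd_units Planted shift in units of `noise_sd`.
#' @param planted_group_fraction Fraction of the groups measuring a planted
#'   gene in which it is perturbed.
#' @param variance_inflation Factor (>= 1) multiplying the case-subgroup
#'   noise variance in designated groups, to exercise the Welch branch.
#' @param inflated_group_fraction Fraction of groups designated for variance
#'   inflation (only relevant when `variance_inflation > 1`).
#' @param platform_gene_dropout Per-group probability that a gene is absent
#'   from the platform.
#' @param n_tissues Number of distinct tissues, assigned to groups
#'   round-robin.
#' @param disease Disease arm label for all groups.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `tv_sim_config` list.
#' @export
sim_config <- function(n_groups = 21, n_genes = 2000,
                       probes_per_gene = c(1, 3),
                       multi_gene_probe_fraction = 0.05,
                       samples_per_subgroup = 5,
                       baseline_mean = 7, noise_sd = 1,
                       n_planted = 20, effect_sd_units = 2,
                       planted_group_fraction = 0.7,
                       variance_inflation = 1,
                       inflated_group_fraction = 0.5,
                       platform_gene_dropout = 0.1,
                       n_tissues = 6, disease = "T2DM", seed = 1) {
  cfg <- list(
    n_groups = as.integer(n_groups), n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    multi_gene_probe_fraction = multi_gene_probe_fraction,
    samples_per_subgroup = as.integer(samples_per_subgroup),
    baseline_mean = baseline_mean, noise_sd = noise_sd,
    n_planted = as.integer(n_planted), effect_sd_units = effect_sd_units,
    planted_group_fraction = planted_group_fraction,
    variance_inflation = variance_inflation,
    inflated_group_fraction = inflated_group_fraction,
    platform_gene_dropout = platform_gene_dropout,
    n_tissues = as.integer(n_tissues), disease = disease,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_groups >= 1, n_genes >= 1,
      length(probes_per_gene) == 2, probes_per_gene[1] >= 1,
      probes_per_gene[2] >= probes_per_gene[1],
      multi_gene_probe_fraction >= 0, multi_gene_probe_fraction < 1,
      samples_per_subgroup >= 3, noise_sd > 0,
      n_planted >= 0, n_planted <= n_genes, effect_sd_units > 0,
      planted_group_fraction > 0, planted_group_fraction <= 1,
      variance_inflation >= 1,
      inflated_group_fraction >= 0, inflated_group_fraction <= 1,
      platform_gene_dropout >= 0, platform_gene_dropout < 1,
      n_tissues >= 1
    )
  })
  structure(cfg, class = "tv_sim_config")
}

sim_tissue_names <- function(n_tissues) {
  pool <- c("skeletal muscle", "adipose", "islet", "liver", "blood", "arterial")
  if (n_tissues <= length(pool)) pool[seq_len(n_tissues)]
  else c(pool, sprintf("tissue%02d", seq_len(n_tissues - length(pool))))
}

#' Simulate a multi-group case-control expression study
#'
#' Generates, reproducibly from the seed, a complete synthetic study: one
#' expression group per simulated dataset (its own platform, probe set and
#' samples), a probe annotation table with deliberately injected multi-gene
#' probes, and a truth ledger binding every planted (gene, group) pair and
#' its signed effect to the emitted data. Expression is
#' `baseline + gene offset + Gaussian noise`; planted genes are shifted by
#' `±effect_sd_units * noise_sd` in the case samples of a
#' `planted_group_fraction` share of the groups measuring them, with the
#' sign fixed per (gene, tissue) so direction summaries have recoverable
#' truth.
#'
#' @param config A [sim_config()].
#' @return A `tv_simulation`: list with `groups` (list of
#'   [expression_group()]), `annotation` (tibble `platform_id`, `probe_id`,
#'   `gene_id`), and `truth` (list: `planted_gene_ids`, `planted` tibble of
#'   (gene, group, tissue, sign, effect), `platform_genes`,
#'   `multi_gene_probes`, `inflated_groups`, `config`).
#' @export
simulate_studies <- function(config = sim_config()) {
  stopifnot(inherits(config, "tv_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  gene_offset <- setNames(rnorm(config$n_genes, 0, 0.5), genes)
  tissues <- rep_len(sim_tissue_names(config$n_tissues), config$n_groups)
  group_ids <- sprintf("grp%02d", seq_len(config$n_groups))

  n_inflated <- if (config$variance_inflation > 1)
    round(config$inflated_group_fraction * config$n_groups) else 0L
  inflated <- group_ids[seq_len(n_inflated)]

  # per-group gene presence (platform content)
  present <- matrix(
    runif(config$n_groups * config$n_genes) >= config$platform_gene_dropout,
    nrow = config$n_groups, dimnames = list(group_ids, genes)
  )

  planted_gene_ids <- if (config$n_planted > 0)
    sort(sample(genes, config$n_planted)) else character()
  tissue_names <- unique(tissues)
  sign_tab <- if (config$n_planted > 0) {
    matrix(sample(c(-1, 1), config$n_planted * length(tissue_names), TRUE),
           nrow = config$n_planted,
           dimnames = list(planted_gene_ids, tissue_names))
  } else NULL

  planted_rows <- list()
  for (g in planted_gene_ids) {
    meas <- group_ids[present[, g]]
    k <- round(config$planted_group_fraction * length(meas))
    if (k == 0 && length(meas) > 0) k <- 1
    pg <- sort(sample(meas, k))
    tis <- tissues[match(pg, group_ids)]
    planted_rows[[g]] <- tibble(
      gene_id = g, group_id = pg, tissue = tis,
      sign = unname(sign_tab[g, tis]),
      effect = unname(sign_tab[g, tis]) * config$effect_sd_units * config$noise_sd
    )
  }
  planted <- bind_rows(planted_rows)
  if (nrow(planted) == 0) {
    planted <- tibble(gene_id = character(), group_id = character(),
                      tissue = character(), sign = double(), effect = double())
  }

  groups <- vector("list", config$n_groups)
  ann_list <- vector("list", config$n_groups)
  multi_list <- vector("list", config$n_groups)
  ns <- config$samples_per_subgroup

  for (i in seq_len(config$n_groups)) {
    gid <- group_ids[i]
    platform <- sprintf("GPLSIM%02d", i)
    g_here <- genes[present[i, ]]
    n_probes_per <- sample(seq(config$probes_per_gene[1],
                               config$probes_per_gene[2]),
                           length(g_here), replace = TRUE)
    probe_gene <- rep(g_here, n_probes_per)
    probe_ids <- sprintf("%s_p%05d", platform, seq_along(probe_gene))

    ann <- tibble(platform_id = platform, probe_id = probe_ids,
                  gene_id = probe_gene)
    n_multi <- round(config$multi_gene_probe_fraction * length(probe_ids))
    if (n_multi > 0) {
      idx <- sample(seq_along(probe_ids), n_multi)
      second <- purrr::map_chr(probe_gene[idx], function(g0)
        sample(setdiff(genes, g0), 1))
      ann <- bind_rows(ann, tibble(platform_id = platform,
                                   probe_id = probe_ids[idx],
                                   gene_id = second))
      multi_list[[i]] <- tibble(platform_id = platform,
                                probe_id = probe_ids[idx])
    }
    ann_list[[i]] <- ann

    case_ids <- sprintf("%s_case%02d", gid, seq_len(ns))
    ctrl_ids <- sprintf("%s_ctrl%02d", gid, seq_len(ns))
    np <- length(probe_ids)
    base <- config$baseline_mean + gene_offset[probe_gene]
    case_sd <- config$noise_sd *
      if (gid %in% inflated) sqrt(config$variance_inflation) else 1
    m_case <- matrix(rnorm(np * ns, 0, case_sd), nrow = np)
    m_ctrl <- matrix(rnorm(np * ns, 0, config$noise_sd), nrow = np)

    shift <- setNames(rep(0, length(g_here)), g_here)
    pl_here <- planted[planted$group_id == gid, ]
    shift[pl_here$gene_id] <- pl_here$effect
    m <- cbind(base + shift[probe_gene] + m_case, base + m_ctrl)
    dimnames(m) <- list(probe_ids, c(case_ids, ctrl_ids))

    groups[[i]] <- expression_group(
      group_id = gid, disease = config$disease, tissue = tissues[i],
      platform_id = platform, values = m,
      case_samples = case_ids, control_samples = ctrl_ids
    )
  }

  structure(
    list(
      groups = groups,
      annotation = bind_rows(ann_list),
      truth = list(
        planted_gene_ids = planted_gene_ids,
        planted = planted,
        platform_genes = tibble(
          group_id = rep(group_ids, each = config$n_genes),
          gene_id = rep(genes, config$n_groups),
          present = as.vector(t(present))
        ) %>% filter(.data$present) %>% select(-"present"),
        multi_gene_probes = bind_rows(multi_list),
        inflated_groups = inflated,
        config = unclass(config)
      )
    ),
    class = "tv_simulation"
  )
}

#' @export
print.tv_simulation <- function(x, ...) {
  cat(sprintf(
    "<tv_simulation> %d groups, %d genes, %d planted gene(s), seed %d\n",
    length(x$groups), x$truth$config$n_genes,
    length(x$truth$planted_gene_ids), x$truth$config$seed
  ))
  invisible(x)
}

#' Simulate non-overlapping gene intervals
#'
#' Places genes round-robin on `n_chromosomes` chromosomes, each of length
#' `chrom_length`, with lengths drawn uniformly from `gene_length_range` and
#' uniformly scattered non-overlapping positions (1-based inclusive).
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Chromosome length in bases.
#' @param gene_length_range `c(min, max)` gene length.
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` with attributes
#'   `chrom_length` and `chromosomes`.
#' @export
simulate_gene_intervals <- function(n_genes, n_chromosomes = 3,
                                    chrom_length = 5e7,
                                    gene_length_range = c(2000, 20000),
                                    seed = 1) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, chrom_length >= 1,
            gene_length_range[1] >= 1,
            gene_length_range[2] >= gene_length_range[1])
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  chroms <- sprintf("chr%d", rep_len(seq_len(n_chromosomes), n_genes))
  out <- vector("list", n_chromosomes)
  for (ci in seq_len(n_chromosomes)) {
    ids <- genes[chroms == sprintf("chr%d", ci)]
    k <- length(ids)
    if (k == 0) next
    lens <- floor(runif(k, gene_length_range[1], gene_length_range[2] + 1))
    free <- chrom_length - sum(lens) - (k - 1)
    if (free < 0) {
      abort(sprintf("simulate_gene_intervals: %d genes cannot fit on a chromosome of length %g",
                    k, chrom_length))
    }
    gaps <- floor(diff(c(0, sort(runif(k, 0, free + 1)))))
    start <- 1 + cumsum(gaps) + c(0, cumsum(lens[-k] + 1))
    out[[ci]] <- tibble(gene_id = ids, chrom = sprintf("chr%d", ci),
                        start = as.integer(start),
                        end = as.integer(start + lens - 1))
  }
  res <- bind_rows(out) %>% arrange(.data$gene_id)
  attr(res, "chrom_length") <- chrom_length
  attr(res, "chromosomes") <- sprintf("chr%d", seq_len(n_chromosomes))
  res
}

#' Simulate a susceptibility-SNP panel
#'
#' A `near_fraction` share of SNPs is placed uniformly within `radius` of a
#' random planted gene (so it is guaranteed to pass the window screen for
#' that gene); the remainder is placed uniformly over the chromosome space.
#'
#' @param truth Either a `tv_simulation` object, its `truth` element, or a
#'   character vector of planted gene ids.
#' @param gene_intervals Intervals from [simulate_gene_intervals()] covering
#'   the planted genes (attribute `chrom_length` required).
#' @param n_snps Panel size.
#' @param near_fraction Fraction of SNPs forced near planted genes.
#' @param radius Window radius (default 1e6).
#' @param seed Integer seed.
#' @return Tibble of SNP records `rsid`, `chrom`, `pos`, `assoc_p`,
#'   `allele_freq_note`.
#' @export
simulate_snp_panel <- function(truth, gene_intervals, n_snps,
                               near_fraction = 0.5, radius = 1e6, seed = 1) {
  planted <- if (is.character(truth)) truth
  else if (inherits(truth, "tv_simulation")) truth$truth$planted_gene_ids
  else truth$planted_gene_ids
  chrom_length <- attr(gene_intervals, "chrom_length") %||%
    max(gene_intervals$end)
  chroms <- attr(gene_intervals, "chromosomes") %||%
    unique(gene_intervals$chrom)
  stopifnot(n_snps >= 1, near_fraction >= 0, near_fraction <= 1, radius >= 0)
  if (radius > chrom_length) {
    abort("simulate_snp_panel: radius larger than chromosome length")
  }
  set.seed(seed)
  n_near <- round(near_fraction * n_snps)
  if (n_near > 0 && length(planted) == 0) {
    abort("simulate_snp_panel: near_fraction > 0 but no planted genes")
  }
  target <- gene_intervals %>% filter(.data$gene_id %in% planted)
  if (n_near > 0 && nrow(target) == 0) {
    abort("simulate_snp_panel: planted genes absent from gene_intervals")
  }
  pos <- integer(n_snps); chrom <- character(n_snps)
  for (i in seq_len(n_snps)) {
    if (i <= n_near) {
      row <- target[sample(nrow(target), 1), ]
      lo <- max(1, row$start - radius)
      hi <- min(chrom_length, row$end + radius)
      pos[i] <- as.integer(floor(runif(1, lo, hi + 1)))
      chrom[i] <- row$chrom
    } else {
      chrom[i] <- sample(chroms, 1)
      pos[i] <- as.integer(floor(runif(1, 1, chrom_length + 1)))
    }
  }
  tibble(
    rsid = sprintf("rssim%04d", seq_len(n_snps)),
    chrom = chrom, pos = pos,
    assoc_p = 10^runif(n_snps, -12, log10(5e-8)),
    allele_freq_note = NA_character_
  )
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Materializes `matrix_<group>.tsv` per group, a combined `design.tsv`, an
#' `annotation.tsv` and a `truth.json` ledger under `dir`.
#'
#' @param sim A `tv_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "tv_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sim$groups) {
    mat <- as_tibble(g$values, rownames = "probe_id")
    readr::write_tsv(mat, file.path(dir, sprintf("matrix_%s.tsv", g$group_id)),
                     progress = FALSE)
  }
  readr::write_tsv(group_design(sim$groups), file.path(dir, "design.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(
      planted_gene_ids = truth$planted_gene_ids,
      planted = truth$planted,
      inflated_groups = truth$inflated_groups,
      multi_gene_probes = truth$multi_gene_probes,
      config = truth$config
    ),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory with `matrix_*.tsv`, `design.tsv` and
#'   `annotation.tsv`.
#' @return List with `groups` (list of [expression_group()]) and
#'   `annotation`.
#' @export
read_study <- function(dir) {
  mats <- sort(list.files(dir, pattern = "^matrix_.*\\.tsv$", full.names = TRUE))
  if (length(mats) == 0) abort(sprintf("read_study: no matrix files in '%s'", dir))
  design_path <- file.path(dir, "design.tsv")
  if (!file.exists(design_path)) abort(sprintf("read_study: missing '%s'", design_path))
  groups <- purrr::map(mats, read_expression_group, design_path = design_path)
  ann_path <- file.path(dir, "annotation.tsv")
  if (!file.exists(ann_path)) abort(sprintf("read_study: missing '%s'", ann_path))
  list(groups = groups, annotation = read_probe_annotation(ann_path))
}
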