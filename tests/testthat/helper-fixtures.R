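# Small builders and independent oracles shared across test files.

# A minimal valid expression group built from explicit per-probe values.
# `probe_values` is a named list: probe_id -> numeric vector of length
# n_case + n_control (cases first).
make_group <- function(probe_values, n_case = 3, n_control = 3,
                       group_id = "g1", disease = "T2DM",
                       tissue = "skeletal muscle", platform_id = "GPLX") {
  m <- do.call(rbind, probe_values)
  rownames(m) <- names(probe_values)
  case_ids <- sprintf("case%d", seq_len(n_case))
  ctrl_ids <- sprintf("ctrl%d", seq_len(n_control))
  colnames(m) <- c(case_ids, ctrl_ids)
  expression_group(group_id, disease, tissue, platform_id, m,
                   case_samples = case_ids, control_samples = ctrl_ids)
}

# Write a matrix + design pair to a temp dir and return the two paths.
write_group_files <- function(values, design, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  dp <- file.path(dir, "design.tsv")
  readr::write_tsv(values, mp, progress = FALSE)
  readr::write_tsv(design, dp, progress = FALSE)
  list(matrix = mp, design = dp)
}

simple_matrix_tbl <- function(n_probes = 4, samples = c("s1", "s2", "s3", "s4", "s5", "s6"),
                              seed = 42) {
  set.seed(seed)
  out <- tibble::tibble(probe_id = sprintf("p%d", seq_len(n_probes)))
  for (s in samples) out[[s]] <- round(rnorm(n_probes, 7, 1), 4)
  out
}

simple_design_tbl <- function(samples = c("s1", "s2", "s3", "s4", "s5", "s6"),
                              roles = c("case", "case", "case", "control", "control", "control"),
                              group_id = "g1") {
  tibble::tibble(sample_id = samples, role = roles, group_id = group_id,
                 disease = "T2DM", tissue = "islet", platform_id = "GPLX")
}

# Brute-force oracle for the SNP window: per (gene, SNP) pair, scalar rule.
brute_force_near <- function(genes, snps, radius) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    hits <- character(0); dists <- numeric(0)
    for (j in seq_len(nrow(snps))) {
      if (tissuevote:::norm_chrom(genes$chrom[i]) != tissuevote:::norm_chrom(snps$chrom[j])) next
      p <- snps$pos[j]
      d <- if (p >= genes$start[i] && p <= genes$end[i]) 0
           else min(abs(p - genes$start[i]), abs(p - genes$end[i]))
      if (d <= radius) { hits <- c(hits, snps$rsid[j]); dists <- c(dists, d) }
    }
    if (length(hits) > 0) {
      rows[[genes$gene_id[i]]] <- tibble::tibble(
        gene_id = genes$gene_id[i],
        rsids = list(sort(unique(hits))),
        n_snps = length(unique(hits)),
        min_distance = min(dists)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(), rsids = list(),
                          n_snps = integer(), min_distance = double()))
  }
  dplyr::arrange(out, gene_id)
}

random_interval_instance <- function(seed, n_genes = 8, n_snps = 6,
                                     chrom_pool = c("chr1", "2", "chr3")) {
  set.seed(seed)
  genes <- tibble::tibble(
    gene_id = sprintf("G%02d", seq_len(n_genes)),
    chrom = sample(chrom_pool, n_genes, TRUE),
    start = sample.int(5e6, n_genes)
  )
  genes$end <- genes$start + sample.int(2e5, n_genes)
  snps <- tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(n_snps)),
    chrom = sample(chrom_pool, n_snps, TRUE),
    pos = sample.int(6e6, n_snps)
  )
  list(genes = genes, snps = snps)
}
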