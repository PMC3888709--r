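#' Read an expression group from a matrix file and a design file
#'
#' The matrix file is tab-delimited with a `probe_id` column followed by one
#' column per sample; the design file is the authority for case/control
#' assignment (columns `sample_id`, `role`, `group_id`, `disease`, `tissue`,
#' `platform_id`). Column order of the matrix is preserved.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param design_path Path to the design TSV. If the design file describes
#'   several groups, only rows whose samples appear in the matrix are used;
#'   they must belong to exactly one group.
#' @return A validated [expression_group()].
#' @export
read_expression_group <- function(matrix_path, design_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (!"probe_id" %in% names(raw)) {
    abort(sprintf("'%s': expression matrix must have a 'probe_id' column", matrix_path))
  }
  sample_cols <- setdiff(names(raw), "probe_id")
  for (sc in sample_cols) {
    col <- raw[[sc]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | is.na(col) | col == "")
    if (length(bad) > 0) {
      abort(sprintf(
        "'%s': non-numeric or missing expression value at probe '%s', sample column '%s'",
        matrix_path, raw$probe_id[bad[1]], sc
      ))
    }
    raw[[sc]] <- num
  }
  if (anyDuplicated(raw$probe_id)) {
    abort(sprintf("'%s': duplicate probe id '%s'", matrix_path,
                  raw$probe_id[duplicated(raw$probe_id)][1]))
  }

  design <- readr::read_tsv(design_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  needed <- c("sample_id", "role", "group_id", "disease", "tissue", "platform_id")
  miss <- setdiff(needed, names(design))
  if (length(miss) > 0) {
    abort(sprintf("'%s': design file missing column(s) %s", design_path,
                  paste(miss, collapse = ", ")))
  }
  design <- design[design$sample_id %in% sample_cols, , drop = FALSE]
  unassigned <- setdiff(sample_cols, design$sample_id)
  if (length(unassigned) > 0) {
    abort(sprintf("'%s': sample '%s' missing from design", design_path, unassigned[1]))
  }
  if (n_distinct(design$group_id) != 1) {
    abort(sprintf("'%s': matrix samples span %d groups, expected 1",
                  design_path, n_distinct(design$group_id)))
  }
  if (!all(design$role %in% c("case", "control"))) {
    bad <- design$role[!design$role %in% c("case", "control")][1]
    abort(sprintf("'%s': unknown role '%s' (expected case/control)", design_path, bad))
  }

  m <- as.matrix(raw[, sample_cols, drop = FALSE])
  rownames(m) <- raw$probe_id
  expression_group(
    group_id = design$group_id[1],
    disease = design$disease[1],
    tissue = design$tissue[1],
    platform_id = design$platform_id[1],
    values = m,
    case_samples = design$sample_id[design$role == "case"],
    control_samples = design$sample_id[design$role == "control"]
  )
}

#' Read a probe-to-gene annotation table
#'
#' One row per (probe, gene) pair; a probe annotated to several genes has
#' several rows, a probe with no gene has an empty/NA `gene_id`. Such probes
#' are dropped later by [resolve_probes()].
#'
#' @param path Tab-delimited file with columns `platform_id`, `probe_id`,
#'   `gene_id`.
#' @return A tibble with those three columns (`gene_id` NA when unannotated).
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  miss <- setdiff(c("platform_id", "probe_id", "gene_id"), names(ann))
  if (length(miss) > 0) {
    abort(sprintf("'%s': annotation missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  ann %>%
    mutate(gene_id = ifelse(is.na(.data$gene_id) | .data$gene_id == "",
                            NA_character_, .data$gene_id)) %>%
    distinct(.data$platform_id, .data$probe_id, .data$gene_id)
}

#' Read a susceptibility-SNP table
#'
#' @param path Tab-delimited file with columns `rsid`, `chrom`, `pos` and
#'   optionally `assoc_p` (genome-wide association P value) and
#'   `allele_freq_note` (pass-through text).
#' @param max_assoc_p If given, rows with `assoc_p` above this bound are
#'   dropped (the genome-wide-significance filter, canonically `5e-8`);
#'   the number dropped is reported via a message.
#' @return A tibble of SNP records: `rsid`, `chrom`, `pos`, `assoc_p`,
#'   `allele_freq_note`.
#' @export
read_snp_table <- function(path, max_assoc_p = NULL) {
  snps <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  miss <- setdiff(c("rsid", "chrom", "pos"), names(snps))
  if (length(miss) > 0) {
    abort(sprintf("'%s': SNP table missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(snps$pos))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("'%s': non-integer or invalid position '%s' for %s",
                  path, snps$pos[bad[1]], snps$rsid[bad[1]]))
  }
  if (anyDuplicated(snps$rsid)) {
    abort(sprintf("'%s': duplicate rsid '%s'", path,
                  snps$rsid[duplicated(snps$rsid)][1]))
  }
  out <- tibble(
    rsid = snps$rsid,
    chrom = snps$chrom,
    pos = as.integer(pos),
    assoc_p = if ("assoc_p" %in% names(snps))
      suppressWarnings(as.numeric(snps$assoc_p)) else NA_real_,
    allele_freq_note = if ("allele_freq_note" %in% names(snps))
      snps$allele_freq_note else NA_character_
  )
  if (!is.null(max_assoc_p)) {
    keep <- !is.na(out$assoc_p) & out$assoc_p <= max_assoc_p
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      inform(sprintf("read_snp_table: dropped %d SNP(s) with assoc_p > %g",
                     n_drop, max_assoc_p))
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Read gene coordinate intervals
#'
#' Coordinates are stored 1-based and inclusive at both ends (the NCBI/CCDS
#' convention). BED input (0-based, half-open) is converted on read:
#' `start + 1`, `end` unchanged. Duplicate intervals for one gene on the same
#' chromosome are merged by union; on different chromosomes they are an error.
#'
#' @param path Tab-delimited table. For `dialect = "one_based_inclusive"`, a
#'   headered TSV with columns `gene_id`, `chrom`, `start`, `end`; for
#'   `dialect = "bed"`, a headerless 4-column BED (`chrom`, `start`, `end`,
#'   `name`).
#' @param dialect Coordinate dialect of the file.
#' @return A tibble `gene_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   one row per gene.
#' @export
read_gene_intervals <- function(path, dialect = c("one_based_inclusive", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                           col_types = "ciic", progress = FALSE)
    raw$start <- raw$start + 1L
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer()
    ), progress = FALSE)
    miss <- setdiff(c("gene_id", "chrom", "start", "end"), names(raw))
    if (length(miss) > 0) {
      abort(sprintf("'%s': interval table missing column(s) %s", path,
                    paste(miss, collapse = ", ")))
    }
  }
  bad <- which(raw$end < raw$start)
  if (length(bad) > 0) {
    abort(sprintf("'%s': interval for '%s' has end < start after conversion",
                  path, raw$gene_id[bad[1]]))
  }
  merged <- raw %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_chrom = n_distinct(norm_chrom(.data$chrom)),
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
  if (any(merged$n_chrom > 1)) {
    abort(sprintf("'%s': gene '%s' has intervals on different chromosomes",
                  path, merged$gene_id[merged$n_chrom > 1][1]))
  }
  merged %>% select("gene_id", "chrom", "start", "end")
}

#' Convert 1-based inclusive intervals back to BED rows
#'
#' The inverse of the BED conversion in [read_gene_intervals()].
#'
#' @param intervals Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return Tibble with BED columns `chrom`, `start` (0-based), `end`, `name`.
#' @export
intervals_to_bed <- function(intervals) {
  tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start - 1L),
    end = as.integer(intervals$end),
    name = intervals$gene_id
  )
}

#' Write a candidate report
#'
#' Rows are ordered by rank then gene id; percentages are rendered to one
#' decimal place (half away from zero), the convention of the published
#' candidate tables. An empty record set yields a header-only file with a
#' warning.
#'
#' @param records Tibble with at least `gene_id`, `percentage`,
#'   `n_significant`, `n_measured`, `rank`; an optional `rsids` list-column
#'   (from the SNP-window screen) is written semicolon-joined.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_candidate_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (nrow(records) == 0) {
    warn(sprintf("write_candidate_report: empty record list written to '%s'", path))
  }
  out <- records %>%
    arrange(.data$rank, .data$gene_id) %>%
    mutate(percentage = format_percentage(.data$percentage))
  if ("rsids" %in% names(out) && is.list(out$rsids)) {
    out$rsids <- purrr::map_chr(out$rsids, paste, collapse = ";")
  }
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Worked-example coordinate fixtures
#'
#' Returns the published gene intervals, SNP positions and differential
#' expression percentages of the SNP-proximal candidate tables for one
#' disease arm, transcribed from the printed tables and shipped as
#' plain-text files with the package.
#'
#' @param arm `"T2DM"` or `"obesity"`.
#' @return A list with tibbles `genes` (gene_id, chrom, start, end,
#'   percentage) and `snps` (rsid, chrom, pos, allele_freq_note).
#' @export
worked_example <- function(arm = c("T2DM", "obesity")) {
  arm <- match.arg(arm)
  stem <- if (arm == "T2DM") "t2dm" else "obesity"
  gene_path <- system.file("extdata", paste0(stem, "_snp_window_genes.tsv"),
                           package = "tissuevote", mustWork = TRUE)
  snp_path <- system.file("extdata", paste0(stem, "_snps.tsv"),
                          package = "tissuevote", mustWork = TRUE)
  genes <- readr::read_tsv(gene_path, col_types = "cciid", progress = FALSE)
  snps <- read_snp_table(snp_path)
  list(genes = genes, snps = snps)
}
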