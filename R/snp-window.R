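#' Is a gene within the window around a SNP?
#'
#' A gene qualifies when it lies on the same (normalized) chromosome and its
#' closed interval [start, end] intersects the closed window
#' [pos - radius, pos + radius]. Boundaries are inclusive: a gene ending
#' exactly `radius` bases from the SNP qualifies. The distance is 0 when the
#' SNP falls inside the gene, otherwise the gap to the nearer gene end.
#'
#' @param gene One-row tibble or list with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param snp One-row tibble or list with `rsid`, `chrom`, `pos`.
#' @param radius Window radius in bases (default 1e6, i.e. +/- 1 Mb).
#' @param anchor What part of the gene must fall in the window: the whole
#'   interval (`"interval"`, any overlap, the default), the gene midpoint, or
#'   the start coordinate (`"tss"`).
#' @return A list with `member` (logical) and `distance` (bases; NA when the
#'   chromosomes differ).
#' @export
window_membership <- function(gene, snp, radius = 1e6,
                              anchor = c("interval", "midpoint", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(radius >= 0)
  if (norm_chrom(gene$chrom) != norm_chrom(snp$chrom)) {
    return(list(member = FALSE, distance = NA_real_))
  }
  lo <- switch(anchor,
    interval = gene$start,
    midpoint = floor((gene$start + gene$end) / 2),
    tss = gene$start
  )
  hi <- switch(anchor,
    interval = gene$end,
    midpoint = lo,
    tss = lo
  )
  d <- if (snp$pos >= lo && snp$pos <= hi) 0
       else min(abs(snp$pos - lo), abs(snp$pos - hi))
  list(member = d <= radius, distance = as.numeric(d))
}

#' Genes within the window of any SNP
#'
#' Intersects every gene interval with every SNP window on the same
#' chromosome and returns one row per qualifying gene with all qualifying
#' SNPs and the minimum distance.
#'
#' @param genes Tibble of gene intervals (`gene_id`, `chrom`, `start`, `end`).
#' @param snps Tibble of SNP records (`rsid`, `chrom`, `pos`).
#' @inheritParams window_membership
#' @return Tibble sorted by gene id: `gene_id`, `rsids` (list-column of
#'   qualifying rsids), `n_snps`, `min_distance`.
#' @export
genes_near_snps <- function(genes, snps, radius = 1e6,
                            anchor = c("interval", "midpoint", "tss")) {
  anchor <- match.arg(anchor)
  empty <- tibble(gene_id = character(), rsids = list(),
                  n_snps = integer(), min_distance = double())
  if (nrow(genes) == 0 || nrow(snps) == 0) return(empty)
  g <- genes %>% mutate(.chrom = norm_chrom(.data$chrom))
  if (anchor == "midpoint") {
    g <- g %>% mutate(start = floor((.data$start + .data$end) / 2),
                      end = .data$start)
  } else if (anchor == "tss") {
    g <- g %>% mutate(end = .data$start)
  }
  s <- snps %>%
    mutate(.chrom = norm_chrom(.data$chrom)) %>%
    select("rsid", "pos", ".chrom")
  pairs <- inner_join(g, s, by = ".chrom", relationship = "many-to-many") %>%
    mutate(distance = ifelse(
      .data$pos >= .data$start & .data$pos <= .data$end, 0,
      pmin(abs(.data$pos - .data$start), abs(.data$pos - .data$end))
    )) %>%
    filter(.data$distance <= radius)
  if (nrow(pairs) == 0) return(empty)
  pairs %>%
    group_by(.data$gene_id) %>%
    arrange(.data$distance, .data$rsid, .by_group = TRUE) %>%
    summarise(
      rsids = list(sort(unique(.data$rsid))),
      n_snps = length(unique(.data$rsid)),
      min_distance = min(.data$distance),
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id)
}

#' Screen SNP-proximal genes by differential-expression percentage
#'
#' Intersects the window assignments with the ranked percentage records and
#' keeps genes passing the screen threshold (strictly greater by default,
#' the published convention for this re-ranking step: > 40% for T2DM,
#' > 50% for obesity). Assigned genes with no percentage record cannot be
#' candidates; they are returned in the `unranked` attribute.
#'
#' @param assignments Output of [genes_near_snps()].
#' @param percentage_records Ranked records from [rank_genes()] (or
#'   `tidy()` of a [vote_count()] object).
#' @param candidate_threshold_pct Percentage threshold for the screen.
#' @param threshold_mode `"strictly_greater"` (default) or `"at_least"`.
#' @param min_groups Minimum `n_measured` (default 0).
#' @return Tibble of screened candidates sorted by rank: ranking columns
#'   plus `rsids` and `min_distance`; attribute `unranked` holds gene ids
#'   assigned to SNPs but absent from the ranking.
#' @export
screen_candidates <- function(assignments, percentage_records,
                              candidate_threshold_pct,
                              threshold_mode = c("strictly_greater", "at_least"),
                              min_groups = 0) {
  threshold_mode <- match.arg(threshold_mode)
  unranked <- setdiff(assignments$gene_id, percentage_records$gene_id)
  if (length(unranked) > 0) {
    inform(sprintf("screen_candidates: %d assigned gene(s) have no percentage record",
                   length(unranked)))
  }
  joined <- inner_join(percentage_records, assignments, by = "gene_id")
  out <- select_candidates(joined, candidate_threshold_pct,
                           threshold_mode = threshold_mode,
                           min_groups = min_groups)
  if ("rank" %in% names(out)) out <- out %>% arrange(.data$rank, .data$gene_id)
  attr(out, "unranked") <- sort(unranked)
  out
}
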