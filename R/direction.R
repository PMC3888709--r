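#' Summarize up/down regulation of candidate genes per tissue
#'
#' For each (candidate gene, tissue) with at least one measuring group,
#' counts groups calling the gene up, down or flat and makes a majority-vote
#' call: `up` when up-counts exceed down-counts (symmetrically `down`),
#' `mixed` on a non-zero tie, `flat` otherwise. By default every measured
#' group votes; `significant_only = TRUE` restricts the vote to groups where
#' the gene reached `p_threshold`.
#'
#' @param gene_results Per-(group, gene) results from [test_groups()]
#'   (columns `group_id`, `gene_id`, `p_value`, `direction`).
#' @param group_designs Design tibble from [group_design()] (maps `group_id`
#'   to `tissue`).
#' @param candidate_genes Character vector of candidate gene ids.
#' @param significant_only Restrict votes to significant groups
#'   (default FALSE).
#' @param p_threshold Threshold used when `significant_only` (default 0.05).
#' @return Tibble ordered by (gene, tissue): `gene_id`, `tissue`, `n_up`,
#'   `n_down`, `n_flat`, `call`.
#' @export
summarize_directions <- function(gene_results, group_designs, candidate_genes,
                                 significant_only = FALSE, p_threshold = 0.05) {
  if (length(candidate_genes) == 0) abort("summarize_directions: empty candidate list")
  tissues <- group_designs %>% distinct(.data$group_id, .data$tissue)
  res <- gene_results %>% filter(.data$gene_id %in% candidate_genes)
  absent <- setdiff(candidate_genes, res$gene_id)
  if (length(absent) > 0) {
    warn(sprintf("summarize_directions: candidate(s) absent from all groups: %s",
                 paste(absent, collapse = ", ")))
  }
  if (significant_only) res <- res %>% filter(.data$p_value <= p_threshold)
  res %>%
    inner_join(tissues, by = "group_id") %>%
    group_by(.data$gene_id, .data$tissue) %>%
    summarise(
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n_flat = sum(.data$direction == "flat"),
      .groups = "drop"
    ) %>%
    mutate(call = case_when(
      .data$n_up > .data$n_down ~ "up",
      .data$n_down > .data$n_up ~ "down",
      .data$n_up == .data$n_down & .data$n_up > 0 ~ "mixed",
      TRUE ~ "flat"
    )) %>%
    arrange(.data$gene_id, .data$tissue)
}
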