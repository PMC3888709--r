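#' Pipeline configuration
#'
#' The defaults reproduce the published analysis settings: per-group
#' significance at P <= 0.05 after an F-gated t-test at level 0.05;
#' genome-wide candidate thresholds of >= 50% (T2DM arm) and >= 60%
#' (obesity arm), with the obesity arm additionally requiring at least 10
#' measuring groups; SNP-screen thresholds of > 40% (T2DM) and > 50%
#' (obesity); a +/- 1 Mb window; and a genome-wide-significance SNP filter
#' at P <= 5e-8. Per-arm fields are named vectors keyed by disease label;
#' an unnamed scalar applies to every arm.
#'
#' @param p_threshold Per-group gene significance threshold.
#' @param f_alpha Variance-ratio pretest level.
#' @param min_groups Named per-arm minimum number of measuring groups.
#' @param candidate_threshold_pct Named per-arm genome-wide percentage
#'   threshold.
#' @param candidate_mode Threshold mode for genome-wide selection.
#' @param screen_threshold_pct Named per-arm SNP-screen percentage threshold.
#' @param screen_mode Threshold mode for the SNP screen.
#' @param window_radius SNP window radius in bases.
#' @param snp_assoc_p_max Maximum SNP association P value.
#' @param direction_significant_only Restrict direction votes to significant
#'   groups.
#' @param seed Integer seed echoed into the run manifest (the pipeline
#'   stages themselves are deterministic).
#' @return A `tv_pipeline_config` list.
#' @export
pipeline_config <- function(p_threshold = 0.05, f_alpha = 0.05,
                            min_groups = c(T2DM = 0, obesity = 10),
                            candidate_threshold_pct = c(T2DM = 50, obesity = 60),
                            candidate_mode = "at_least",
                            screen_threshold_pct = c(T2DM = 40, obesity = 50),
                            screen_mode = "strictly_greater",
                            window_radius = 1e6,
                            snp_assoc_p_max = 5e-8,
                            direction_significant_only = FALSE,
                            seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1, f_alpha > 0, f_alpha < 1,
            window_radius >= 0,
            candidate_mode %in% c("at_least", "strictly_greater"),
            screen_mode %in% c("at_least", "strictly_greater"))
  structure(
    list(
      p_threshold = p_threshold, f_alpha = f_alpha,
      min_groups = min_groups,
      candidate_threshold_pct = candidate_threshold_pct,
      candidate_mode = candidate_mode,
      screen_threshold_pct = screen_threshold_pct,
      screen_mode = screen_mode,
      window_radius = window_radius,
      snp_assoc_p_max = snp_assoc_p_max,
      direction_significant_only = direction_significant_only,
      seed = as.integer(seed)
    ),
    class = "tv_pipeline_config"
  )
}

arm_value <- function(x, arm) {
  if (!is.null(names(x)) && arm %in% names(x)) unname(x[[arm]])
  else unname(x[[1]])
}

#' Run the full candidate-gene pipeline on a study directory
#'
#' Executes per-group testing, vote-count ranking, the multiplicity
#' comparison, the optional SNP-window screen (when `snps[_<arm>].tsv` and
#' `gene_intervals.tsv` are present in `study_dir`) and per-tissue direction
#' summaries, per disease arm. All report TSVs plus a JSON run manifest are
#' written under `out_dir`; rerunning with identical inputs and config
#' yields byte-identical reports. Partial outputs are removed on failure.
#'
#' @param study_dir Directory with `matrix_*.tsv`, `design.tsv`,
#'   `annotation.tsv` and optionally `snps.tsv` / `snps_<arm>.tsv` and
#'   `gene_intervals.tsv`.
#' @param out_dir Output directory for reports (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results per stage:
#'   `gene_results`, per-arm `votes` ([vote_count()] objects),
#'   `adjustment`, per-arm `screen`, per-arm `directions`, and `manifest`.
#' @export
run_pipeline <- function(study_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "tv_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
    path
  }

  tryCatch({
    study <- read_study(study_dir)
    designs <- group_design(study$groups)
    arms <- unique(designs$disease)

    gene_results <- test_groups(study$groups, study$annotation,
                                f_alpha = config$f_alpha)
    emit(gene_results %>%
           mutate(p_value = signif(.data$p_value, 10)),
         "group_tests.tsv")

    adjustment <- compare_adjustment(gene_results, alpha = config$p_threshold)
    emit(adjustment, "adjustment_comparison.tsv")

    intervals_path <- file.path(study_dir, "gene_intervals.tsv")
    intervals <- if (file.exists(intervals_path))
      read_gene_intervals(intervals_path) else NULL

    votes <- list(); screens <- list(); directions <- list()
    counts <- list()
    for (arm in arms) {
      arm_groups <- designs$group_id[designs$disease == arm]
      arm_results <- gene_results %>% filter(.data$group_id %in% arm_groups)
      vote <- vote_count(
        arm_results,
        p_threshold = config$p_threshold,
        candidate_threshold_pct = arm_value(config$candidate_threshold_pct, arm),
        threshold_mode = config$candidate_mode,
        min_groups = arm_value(config$min_groups, arm)
      )
      votes[[arm]] <- vote
      ranked <- tidy(vote)
      emit(ranked %>%
             select("rank", "gene_id", "n_significant", "n_measured",
                    "percentage", "candidate") %>%
             mutate(percentage = format_percentage(.data$percentage)),
           sprintf("ranked_genes_%s.tsv", arm))

      snp_path <- file.path(study_dir, sprintf("snps_%s.tsv", arm))
      if (!file.exists(snp_path)) snp_path <- file.path(study_dir, "snps.tsv")
      if (file.exists(snp_path) && !is.null(intervals)) {
        snps <- suppressMessages(
          read_snp_table(snp_path, max_assoc_p = config$snp_assoc_p_max))
        assignments <- genes_near_snps(intervals, snps,
                                       radius = config$window_radius)
        screen <- suppressMessages(screen_candidates(
          assignments, ranked,
          candidate_threshold_pct = arm_value(config$screen_threshold_pct, arm),
          threshold_mode = config$screen_mode,
          min_groups = arm_value(config$min_groups, arm)
        ))
        screens[[arm]] <- screen
        emit(screen %>%
               mutate(rsids = purrr::map_chr(.data$rsids, paste, collapse = ";"),
                      percentage = format_percentage(.data$percentage)) %>%
               select("rank", "gene_id", "percentage", "rsids", "min_distance"),
             sprintf("snp_screen_%s.tsv", arm))
      } else {
        inform(sprintf("run_pipeline: no SNP table or gene intervals for arm '%s'; screen skipped", arm))
      }

      cand <- ranked$gene_id[ranked$candidate]
      if (length(cand) > 0) {
        dirsum <- suppressWarnings(summarize_directions(
          arm_results, designs[designs$disease == arm, ],
          candidate_genes = cand,
          significant_only = config$direction_significant_only,
          p_threshold = config$p_threshold
        ))
        directions[[arm]] <- dirsum
        emit(dirsum, sprintf("direction_summary_%s.tsv", arm))
      } else {
        inform(sprintf("run_pipeline: no candidates in arm '%s'; direction summary skipped", arm))
      }

      counts[[arm]] <- list(
        groups = length(unique(arm_results$group_id)),
        genes_ranked = nrow(ranked),
        candidates = sum(ranked$candidate),
        snp_screen_candidates = if (!is.null(screens[[arm]])) nrow(screens[[arm]]) else NA,
        direction_rows = if (!is.null(directions[[arm]])) nrow(directions[[arm]]) else NA
      )
    }

    manifest <- list(
      package = "tissuevote",
      version = as.character(utils::packageVersion("tissuevote")),
      seed = config$seed,
      config = unclass(config),
      stages = list(
        group_tests = list(rows = nrow(gene_results),
                           groups = length(study$groups)),
        adjustment_comparison = list(rows = nrow(adjustment)),
        per_arm = counts
      ),
      reports = basename(written)
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)

    invisible(list(gene_results = gene_results, votes = votes,
                   adjustment = adjustment, screen = screens,
                   directions = directions, manifest = manifest))
  }, error = function(e) {
    unlink(written)
    abort(sprintf("run_pipeline failed (partial outputs removed): %s",
                  conditionMessage(e)), parent = e)
  })
}
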