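#' Construct an expression group
#'
#' An expression group is one case-control comparison: a matrix of normalized
#' log2 expression values (probes in rows, samples in columns) together with
#' the sample design (which samples are cases, which are controls), the
#' disease arm, tissue and platform. It is the unit on which per-gene
#' differential expression is tested.
#'
#' @param group_id Group identifier (one case-control comparison).
#' @param disease Disease arm label, `"T2DM"` or `"obesity"`.
#' @param tissue Tissue of origin, e.g. `"skeletal muscle"`.
#' @param platform_id Platform (array design) tag, GPL-style.
#' @param values Numeric matrix of finite normalized log2 intensities with
#'   probe ids as row names and sample ids as column names.
#' @param case_samples,control_samples Character vectors of sample ids. They
#'   must be disjoint, each of size >= 3, and together cover every column of
#'   `values`.
#'
#' @return An object of class `tv_expression_group`.
#' @export
expression_group <- function(group_id, disease, tissue, platform_id,
                             values, case_samples, control_samples) {
  g <- structure(
    list(
      group_id = as.character(group_id),
      disease = as.character(disease),
      tissue = as.character(tissue),
      platform_id = as.character(platform_id),
      values = values,
      case_samples = as.character(case_samples),
      control_samples = as.character(control_samples)
    ),
    class = "tv_expression_group"
  )
  validate_expression_group(g)
}

#' Validate an expression group
#'
#' Checks the structural invariants: unique probe ids, finite numeric values,
#' disjoint case/control sets covering all sample columns, and at least three
#' samples per subgroup.
#'
#' @param g A `tv_expression_group`.
#' @return `g`, invisibly unchanged, or an error describing the violation.
#' @export
validate_expression_group <- function(g) {
  stopifnot(inherits(g, "tv_expression_group"))
  v <- g$values
  if (!is.matrix(v) || !is.numeric(v)) {
    abort(sprintf("group '%s': values must be a numeric matrix", g$group_id))
  }
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    abort(sprintf("group '%s': values must have probe row names and sample column names",
                  g$group_id))
  }
  if (anyDuplicated(rownames(v))) {
    dup <- rownames(v)[duplicated(rownames(v))][1]
    abort(sprintf("group '%s': duplicate probe id '%s'", g$group_id, dup))
  }
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "group '%s': non-finite or missing expression value at probe '%s', sample '%s'",
      g$group_id, rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]
    ))
  }
  if (length(intersect(g$case_samples, g$control_samples)) > 0) {
    abort(sprintf("group '%s': case and control sample sets overlap", g$group_id))
  }
  all_samples <- c(g$case_samples, g$control_samples)
  if (!setequal(all_samples, colnames(v)) || length(all_samples) != ncol(v)) {
    missing <- setdiff(colnames(v), all_samples)
    extra <- setdiff(all_samples, colnames(v))
    abort(sprintf(
      "group '%s': design does not match matrix columns (unassigned: %s; unknown: %s)",
      g$group_id,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"
    ))
  }
  for (role in c("case", "control")) {
    ids <- if (role == "case") g$case_samples else g$control_samples
    if (length(ids) < 3) {
      abort(sprintf("group '%s': %s subgroup below minimum size 3 (has %d)",
                    g$group_id, role, length(ids)))
    }
  }
  invisible(g)
}

#' @export
print.tv_expression_group <- function(x, ...) {
  cat(sprintf(
    "<expression group '%s'> %s / %s / %s\n  %d probes x %d samples (%d case, %d control)\n",
    x$group_id, x$disease, x$tissue, x$platform_id,
    nrow(x$values), ncol(x$values),
    length(x$case_samples), length(x$control_samples)
  ))
  invisible(x)
}

#' Sample design of one or many expression groups
#'
#' @param groups A `tv_expression_group` or a list of them.
#' @return A tibble with columns `sample_id`, `role`, `group_id`, `disease`,
#'   `tissue`, `platform_id` (the design-file layout).
#' @export
group_design <- function(groups) {
  if (inherits(groups, "tv_expression_group")) groups <- list(groups)
  purrr::map_dfr(groups, function(g) {
    tibble(
      sample_id = c(g$case_samples, g$control_samples),
      role = rep(c("case", "control"),
                 c(length(g$case_samples), length(g$control_samples))),
      group_id = g$group_id,
      disease = g$disease,
      tissue = g$tissue,
      platform_id = g$platform_id
    )
  })
}
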