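#' Cross-dataset protein overlap and weighted-protein integration
#'
#' Set algebra combining two analyzed datasets: the proteins present in
#' both, the proteins weighted (kME >= threshold in their module) in at
#' least one dataset, and the proteins weighted in both. The headline
#' percentage is `100 * |weighted in either| / |common|`, rounded to one
#' decimal.
#'
#' @param set_a,set_b Accessions analyzed in each dataset.
#' @param weighted_a,weighted_b Weighted-protein accessions of each dataset
#'   (each must be a subset of its parent set).
#' @return An object of class `"integration_result"`: a list with `common`,
#'   `weighted_either`, `weighted_both` (character vectors) and
#'   `pct_weighted_either` (percentage, 1 decimal; `NA` when the common set
#'   is empty).
#' @export
overlap_datasets <- function(set_a, set_b, weighted_a, weighted_b) {
  if (!all(weighted_a %in% set_a) || !all(weighted_b %in% set_b)) {
    abort("weighted sets must be subsets of their parent sets")
  }
  common <- intersect(unique(set_a), unique(set_b))
  weighted_either <- intersect(union(weighted_a, weighted_b), common)
  weighted_both <- intersect(intersect(weighted_a, weighted_b), common)
  pct <- if (length(common) == 0) NA_real_ else {
    round(100 * length(weighted_either) / length(common), 1)
  }
  structure(list(
    common = sort(common),
    weighted_either = sort(weighted_either),
    weighted_both = sort(weighted_both),
    pct_weighted_either = pct
  ), class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("%d proteins in both datasets\n", length(x$common)))
  if (is.na(x$pct_weighted_either)) {
    cat("weighted-in-either percentage not applicable (empty common set)\n")
  } else {
    cat(sprintf("%d (%.1f%%) weighted in at least one dataset\n",
                length(x$weighted_either), x$pct_weighted_either))
  }
  cat(sprintf("%d weighted in both datasets\n", length(x$weighted_both)))
  invisible(x)
}

#' @export
glance.integration_result <- function(x, ...) {
  tibble::tibble(
    n_common = length(x$common),
    n_weighted_either = length(x$weighted_either),
    n_weighted_both = length(x$weighted_both),
    pct_weighted_either = x$pct_weighted_either
  )
}

#' Log2 fold changes versus matched controls (time-course design)
#'
#' For each protein and each (compound, dose, timepoint) treatment group,
#' the log2 fold change is the mean over the group's replicates minus the
#' mean over the same-timepoint control replicates, ignoring missing cells.
#' A cell is undefined (missing) when either group has no present value.
#'
#' @param matrix Normalized protein x sample tibble of log2 intensities.
#' @param design Design tibble covering the samples.
#' @return Tibble: `accession` plus one column per condition, named
#'   `<compound>_<dose>_<timepoint>h`.
#' @export
log2fc_invitro <- function(matrix, design) {
  m <- pm_to_matrix(matrix)
  design <- design[match(colnames(m), design$sample_id), ]
  treated <- design[design$compound != "none", ]
  groups <- dplyr::distinct(treated, .data$compound, .data$dose,
                            .data$timepoint_h)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  cols <- lapply(seq_len(nrow(groups)), function(g) {
    gi <- groups[g, ]
    g_ids <- treated$sample_id[treated$compound == gi$compound &
                                 treated$dose == gi$dose &
                                 treated$timepoint_h == gi$timepoint_h]
    c_ids <- design$sample_id[design$compound == "none" &
                                design$timepoint_h == gi$timepoint_h]
    if (length(c_ids) == 0) {
      abort(sprintf("no control samples at timepoint %g h", gi$timepoint_h))
    }
    unname(apply(m[, g_ids, drop = FALSE], 1, mean_na) -
             apply(m[, c_ids, drop = FALSE], 1, mean_na))
  })
  names(cols) <- sprintf("%s_%s_%gh", groups$compound, groups$dose,
                         groups$timepoint_h)
  dplyr::bind_cols(tibble::tibble(accession = rownames(m)),
                   tibble::as_tibble(cols))
}

#' Log2 fold changes across patient groups (biopsy design)
#'
#' Per protein: mean of the anthracycline-treated patients minus mean of the
#' no-cancer control patients, and likewise for the non-anthracycline
#' cancer-treated patients.
#'
#' @param matrix Normalized protein x sample tibble.
#' @param design Biopsy design tibble with `patient_group`.
#' @return Tibble: `accession`, `ant_treated_vs_control`,
#'   `nonant_treated_vs_control`.
#' @export
log2fc_biopsy <- function(matrix, design) {
  m <- pm_to_matrix(matrix)
  design <- design[match(colnames(m), design$sample_id), ]
  ids <- function(g) design$sample_id[design$patient_group %in% g]
  if (length(ids("control")) == 0) abort("empty control patient group")
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  gmean <- function(g) unname(apply(m[, ids(g), drop = FALSE], 1, mean_na))
  ctrl <- gmean("control")
  tibble::tibble(
    accession = rownames(m),
    ant_treated_vs_control = gmean("ant_treated") - ctrl,
    nonant_treated_vs_control = gmean("nonant_treated") - ctrl
  )
}

#' Select consistently high-expression proteins
#'
#' Returns the proteins whose log2 intensity is strictly above `floor` in
#' every sample, with no missing values — the "high expression in all
#' samples" filter used to pick robustly quantified marker candidates.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @param floor Log2 expression floor (default 10).
#' @return Character vector of accessions.
#' @export
high_expression_filter <- function(matrix, floor = 10) {
  m <- pm_to_matrix(matrix)
  keep <- !apply(is.na(m), 1, any) & apply(m > floor, 1, all)
  rownames(m)[keep]
}
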