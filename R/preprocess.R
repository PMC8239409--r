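#' Remove proteins matching multiple UniProt identifiers
#'
#' Accession-to-identifier mapping is sometimes ambiguous (one accession
#' matching several UniProt IDs); such proteins are removed before network
#' analysis.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @param id_map Tibble with columns `accession` and `n_ids` (number of
#'   UniProt IDs the accession maps to). Must cover every accession.
#' @return The matrix restricted to single-ID proteins.
#' @export
drop_ambiguous_ids <- function(matrix, id_map) {
  stopifnot(all(c("accession", "n_ids") %in% names(id_map)))
  missing_acc <- setdiff(matrix$accession, id_map$accession)
  if (length(missing_acc)) {
    abort(sprintf("id_map does not cover %d accession(s), e.g. %s",
                  length(missing_acc), missing_acc[1]))
  }
  keep <- id_map$accession[id_map$n_ids == 1]
  out <- dplyr::filter(matrix, .data$accession %in% keep)
  if (nrow(out) == 0) warn("all proteins matched multiple UniProt IDs")
  out
}

#' Filter proteins by missingness and variance
#'
#' Removes proteins missing in strictly more than `max_missing_fraction` of
#' samples, and proteins with zero variance over their present values (a
#' constant profile carries no co-expression information and breaks
#' correlation computations); proteins with fewer than two present values
#' count as zero-variance.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @param max_missing_fraction Maximum tolerated missing fraction
#'   (default 0.5; a protein missing in exactly half the samples is kept).
#' @return Filtered tibble.
#' @export
filter_missing <- function(matrix, max_missing_fraction = 0.5) {
  if (nrow(matrix) == 0) abort("empty matrix")
  m <- pm_to_matrix(matrix)
  miss_frac <- rowMeans(is.na(m))
  n_present <- rowSums(!is.na(m))
  v <- apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else var(r)
  })
  keep <- miss_frac <= max_missing_fraction & n_present >= 2 & v > 0
  matrix[keep, , drop = FALSE]
}

shift_samples <- function(m, shifts) {
  sweep(m, 2, shifts, `+`)
}

#' Median normalization for the treated-versus-control time-course design
#'
#' Two-stage additive (log2) median shifting. First, control samples are put
#' on a common scale: using the reference set of proteins observed in every
#' control sample, each control is shifted so its reference-set median equals
#' the median of the control samples' medians. Second, for every
#' (compound, dose, timepoint) treatment group, the common protein set
#' between the group's samples and the same-timepoint normalized controls is
#' determined; each treated sample is shifted so its median over that common
#' set equals the median of the normalized controls' medians over the same
#' set.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @param design Design tibble covering the matrix's samples (see
#'   [generate_invitro_design()]); controls are rows with `compound ==
#'   "none"`.
#' @return A list with `matrix` (normalized tibble) and `report`, a tibble
#'   of per-sample shifts, set sizes and targets.
#' @export
normalize_invitro <- function(matrix, design) {
  m <- pm_to_matrix(matrix)
  design <- design[match(colnames(m), design$sample_id), ]
  if (anyNA(design$sample_id)) abort("design does not cover all samples")
  ctrl_ids <- design$sample_id[design$compound == "none"]
  if (length(ctrl_ids) == 0) abort("no control samples in design")

  ref_set <- rownames(m)[rowSums(is.na(m[, ctrl_ids, drop = FALSE])) == 0]
  if (length(ref_set) == 0) abort("empty reference set across control samples")
  ctrl_med <- apply(m[ref_set, ctrl_ids, drop = FALSE], 2, median)
  ctrl_target <- median(ctrl_med)
  shifts <- setNames(numeric(ncol(m)), colnames(m))
  shifts[ctrl_ids] <- ctrl_target - ctrl_med
  m <- shift_samples(m, shifts)

  report <- tibble::tibble(
    sample_id = ctrl_ids, scheme = "invitro", group = "control",
    set_size = length(ref_set), target = ctrl_target,
    shift = unname(shifts[ctrl_ids])
  )

  treated <- design[design$compound != "none", ]
  groups <- dplyr::distinct(treated, .data$compound, .data$dose,
                            .data$timepoint_h)
  for (g in seq_len(nrow(groups))) {
    gi <- groups[g, ]
    g_ids <- treated$sample_id[
      treated$compound == gi$compound & treated$dose == gi$dose &
        treated$timepoint_h == gi$timepoint_h]
    tp_ctrl <- design$sample_id[design$compound == "none" &
                                  design$timepoint_h == gi$timepoint_h]
    label <- sprintf("%s/%s/%gh", gi$compound, gi$dose, gi$timepoint_h)
    if (length(tp_ctrl) == 0) {
      abort(sprintf("no control samples at the timepoint of group %s", label))
    }
    cols <- c(g_ids, tp_ctrl)
    common <- rownames(m)[rowSums(is.na(m[, cols, drop = FALSE])) == 0]
    if (length(common) == 0) {
      abort(sprintf("empty common protein set for group %s", label))
    }
    target <- median(apply(m[common, tp_ctrl, drop = FALSE], 2, median))
    g_med <- apply(m[common, g_ids, drop = FALSE], 2, median)
    g_shift <- target - g_med
    m[, g_ids] <- shift_samples(m[, g_ids, drop = FALSE], g_shift)
    report <- dplyr::bind_rows(report, tibble::tibble(
      sample_id = g_ids, scheme = "invitro", group = label,
      set_size = length(common), target = target, shift = unname(g_shift)
    ))
  }
  list(matrix = matrix_to_pm(m), report = report)
}

#' Median normalization for the biopsy design
#'
#' Using the core set of proteins present in every sample, each sample is
#' shifted (additively, log2) so that its core-set median equals the common
#' median — the median of the per-sample medians over the core set.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @return A list with `matrix` and `report` as in [normalize_invitro()].
#' @export
normalize_biopsy <- function(matrix) {
  m <- pm_to_matrix(matrix)
  core <- rownames(m)[rowSums(is.na(m)) == 0]
  if (length(core) == 0) abort("empty core set: no protein present in all samples")
  med <- apply(m[core, , drop = FALSE], 2, median)
  target <- median(med)
  shifts <- target - med
  m <- shift_samples(m, shifts)
  list(
    matrix = matrix_to_pm(m),
    report = tibble::tibble(
      sample_id = colnames(m), scheme = "biopsy", group = "all",
      set_size = length(core), target = target, shift = unname(shifts)
    )
  )
}

#' Standardize intensities to a fixed number of decimal digits
#'
#' Rounds every present value half-to-even to `digits` decimals so that
#' downstream results are bit-stable across platforms.
#'
#' @param matrix Protein x sample tibble.
#' @param digits Decimal digits (default 6).
#' @return Rounded tibble; missing cells stay missing.
#' @export
standardize_decimals <- function(matrix, digits = 6) {
  vc <- sample_cols(matrix)
  matrix[vc] <- lapply(matrix[vc], round_even, digits = digits)
  matrix
}
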