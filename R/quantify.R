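#' Consolidate charge and modification variants into single peptide rows
#'
#' A peptide observed in several charge states (2+ to 7+) or modification
#' states (carbamidomethylation, deamidation, oxidation, ...) appears as
#' multiple rows of the peptide table. Consolidation sums the variant
#' intensities per sample — total-ion-current logic on the linear scale — so
#' each (peptide, protein) pair contributes one row. A consolidated cell is
#' missing only when every variant is missing in that sample.
#'
#' @param peptides Peptide tibble: `peptide`, `protein`, `charge`,
#'   `modification`, then one linear-intensity column per sample.
#' @return Consolidated tibble: `peptide`, `protein`, plus sample columns.
#' @export
consolidate_peptides <- function(peptides) {
  if (nrow(peptides) == 0) abort("empty peptide table")
  val_cols <- setdiff(names(peptides),
                      c("peptide", "protein", "charge", "modification"))
  sum_keep_na <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  peptides |>
    dplyr::group_by(.data$peptide, .data$protein) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(val_cols), sum_keep_na),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein, .data$peptide)
}

#' Protein inference: Occam's razor, shared-peptide removal, two-peptide rule
#'
#' Applies the identification rules of label-free protein inference to a
#' consolidated peptide table: (1) proteins whose peptide set is a subset of
#' another protein's peptide set are redundant and removed (ties between
#' identical sets keep the lexicographically smaller accession); (2) peptides
#' still mapping to more than one retained protein are shared and dropped;
#' (3) proteins left with fewer than two peptides fail positive
#' identification and are removed.
#'
#' @param peptides Consolidated peptide tibble (from
#'   [consolidate_peptides()]).
#' @return Filtered peptide tibble with unambiguous, >= 2-peptide proteins.
#' @export
infer_proteins <- function(peptides) {
  if (nrow(peptides) == 0) abort("empty peptide table")
  pepsets <- split(peptides$peptide, peptides$protein)
  pepsets <- lapply(pepsets, unique)
  acc <- names(pepsets)
  # Occam's razor: remove proteins whose evidence is subsumed by another's.
  # Process in decreasing set size so supersets are settled first.
  ord <- order(-lengths(pepsets), acc)
  retained <- character(0)
  retained_sets <- list()
  for (i in ord) {
    s <- pepsets[[i]]
    subsumed <- any(vapply(retained_sets,
                           function(r) all(s %in% r), logical(1)))
    if (!subsumed) {
      retained <- c(retained, acc[i])
      retained_sets <- c(retained_sets, list(s))
    }
  }
  out <- dplyr::filter(peptides, .data$protein %in% retained)
  # shared peptides among retained proteins are ignored
  n_prot <- out |>
    dplyr::distinct(.data$peptide, .data$protein) |>
    dplyr::count(.data$peptide, name = "n_proteins")
  shared <- n_prot$peptide[n_prot$n_proteins > 1]
  out <- dplyr::filter(out, !.data$peptide %in% shared)
  # at least 2 peptides for positive identification
  keep <- out |>
    dplyr::count(.data$protein) |>
    dplyr::filter(.data$n >= 2)
  dplyr::filter(out, .data$protein %in% keep$protein) |>
    dplyr::arrange(.data$protein, .data$peptide)
}

#' Hi3 (top-3 peptide) protein quantification
#'
#' For each protein, the up-to-three most intense peptides are selected by
#' their average intensity across the samples in which they were observed
#' (ties broken lexicographically by peptide key). The protein's linear
#' intensity in a sample is the mean (optionally the sum) of the selected
#' peptides' present values, then log2-transformed; it is missing when none
#' of the selected peptides was observed in that sample.
#'
#' @param peptides Consolidated, inferred peptide tibble (see
#'   [infer_proteins()]).
#' @param n_top Number of top peptides used (default 3).
#' @param aggregate `"mean"` (standard Hi3/Top3) or `"sum"`.
#' @return Protein x sample tibble of log2 intensities, with an
#'   `n_peptides_used` attribute (tibble: accession, n_peptides_used).
#' @export
hi3_quantify <- function(peptides, n_top = 3, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(peptides) == 0) abort("empty peptide table")
  val_cols <- setdiff(names(peptides), c("peptide", "protein"))
  v <- as.matrix(peptides[val_cols])
  pep_mean <- rowMeans(v, na.rm = TRUE)
  agg_fun <- if (aggregate == "mean") {
    function(m) colMeans(m, na.rm = TRUE)
  } else {
    function(m) colSums(m, na.rm = TRUE)
  }
  by_prot <- split(seq_len(nrow(peptides)), peptides$protein)
  prot_acc <- names(by_prot)
  out <- matrix(NA_real_, nrow = length(by_prot), ncol = length(val_cols),
                dimnames = list(prot_acc, val_cols))
  n_used <- integer(length(by_prot))
  for (i in seq_along(by_prot)) {
    idx <- by_prot[[i]]
    ord <- idx[order(-pep_mean[idx], peptides$peptide[idx])]
    top <- ord[seq_len(min(n_top, length(ord)))]
    n_used[i] <- length(top)
    sub <- v[top, , drop = FALSE]
    lin <- agg_fun(sub)
    lin[colSums(!is.na(sub)) == 0] <- NA_real_
    out[i, ] <- log2(lin)
  }
  res <- matrix_to_pm(out)
  attr(res, "n_peptides_used") <-
    tibble::tibble(accession = prot_acc, n_peptides_used = n_used)
  res
}
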