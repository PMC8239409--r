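#' Convert a protein intensity tibble to a numeric matrix
#'
#' Throughout the package, protein (and peptide) intensity data travel as
#' tibbles whose first column identifies the feature (`accession`) and whose
#' remaining columns are samples. This helper converts to a base matrix
#' (proteins in rows, samples in columns) for numerical work.
#'
#' @param x A tibble with an `accession` column and one numeric column per
#'   sample. Missing intensities are `NA`.
#' @return A numeric matrix with `accession` values as rownames.
#' @export
pm_to_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"accession" %in% names(x)) {
    abort("expected an `accession` column identifying proteins")
  }
  if (anyDuplicated(x$accession)) {
    abort("duplicate accessions in protein table")
  }
  m <- as.matrix(x[setdiff(names(x), "accession")])
  storage.mode(m) <- "double"
  rownames(m) <- x$accession
  m
}

#' Convert a protein matrix back to the package's tibble layout
#'
#' @param m A numeric matrix with proteins in rows (rownames = accessions)
#'   and samples in columns.
#' @return A tibble with `accession` plus one column per sample.
#' @export
matrix_to_pm <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(
    tibble::tibble(accession = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

sample_cols <- function(x) setdiff(names(x), "accession")

# Seed scoping: every stochastic generator takes an integer seed and runs
# under a locally-scoped RNG so global state is never touched.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_ok = TRUE, hi_ok = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (x > lo || (lo_ok && x == lo)) && (x < hi || (hi_ok && x == hi))
  if (!ok) abort(sprintf("`%s` must be a fraction in the expected range", name))
  invisible(x)
}

#' @noRd
round_even <- function(x, digits = 6) round(x, digits)
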