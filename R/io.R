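#' Read and write package tables as TSV
#'
#' Intensity matrices are written feature rows x sample columns with an
#' empty cell for missing values; designs use the fixed column set
#' `sample_id, dataset_kind, compound, dose, timepoint_h, replicate,
#' patient_group`.
#'
#' @param path File path.
#' @return `read_protein_tsv()` and `read_design_tsv()` return tibbles.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @param x Table to write.
#' @export
write_protein_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_protein_tsv <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname io_tsv
#' @export
write_design_tsv <- function(x, path) {
  cols <- c("sample_id", "dataset_kind", "compound", "dose", "timepoint_h",
            "replicate", "patient_group")
  readr::write_tsv(x[cols], path, na = "")
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", dataset_kind = "c", compound = "c",
                    dose = "c", timepoint_h = "d", replicate = "i",
                    patient_group = "c"))
}

#' Read a GMT gene-set file (or a two-column TSV)
#'
#' GMT lines are `set_id <tab> description <tab> member1 <tab> member2 ...`.
#' A two-column TSV (`set_id`, `member`, with or without a header) is also
#' accepted.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (all(n_fields == 2)) {
    ids <- vapply(fields, `[`, character(1), 1)
    members <- vapply(fields, `[`, character(1), 2)
    if (identical(tolower(ids[1]), "set_id") ||
        identical(tolower(members[1]), "member")) {
      ids <- ids[-1]; members <- members[-1]
    }
    return(split(members, factor(ids, levels = unique(ids))))
  }
  bad <- which(n_fields < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  }
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[`, character(1), 1)
  out
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, id, sets[[id]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read interaction edge lists (SIF or two-column TSV)
#'
#' `read_sif()` parses the simple interaction format (`A <tab> pp <tab> B`,
#' possibly with several targets per line); `read_edge_tsv()` reads a
#' two-column table. Malformed lines raise an error naming the line number.
#'
#' @param path File path.
#' @return Edge tibble (`from`, `to`).
#' @export
read_sif <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- nzchar(trimws(lines))
  rows <- purrr::imap(lines, function(l, i) {
    if (!keep[i]) return(NULL)
    f <- strsplit(trimws(l), "[\t ]+")[[1]]
    if (length(f) == 1) return(NULL)  # isolated node line
    if (length(f) < 3) {
      abort(sprintf("malformed SIF line %d: '%s'", i, l))
    }
    tibble::tibble(from = f[1], to = f[-(1:2)])
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_sif
#' @export
read_edge_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("edge TSV must have two columns")
  tibble::tibble(from = as.character(x[[1]]), to = as.character(x[[2]]))
}

#' Write a PPI edge list as SIF
#'
#' @param edges Edge tibble (`from`, `to`).
#' @param path File path.
#' @param interaction Interaction type tag (default `"pp"`).
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  readr::write_lines(paste(edges$from, interaction, edges$to, sep = "\t"),
                     path)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Writes the protein clustering tree with merge heights as branch lengths,
#' for inspection in standard tree viewers.
#'
#' @param dendrogram An [stats::hclust] object.
#' @param path File path.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
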