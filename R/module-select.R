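#' Treated-versus-control eigengene contrasts per module
#'
#' For each module eigengene, computes the standardized mean difference
#' (treated minus control, divided by the pooled standard deviation) and a
#' PCA-separation score: the mean silhouette width of the treated/control
#' labels on the first two principal components of the module's protein
#' submatrix (per-protein mean imputation, samples as observations). Both
#' scores quantify what eigengene bar plots and module PCA plots show
#' visually.
#'
#' @param eigengenes Eigengene tibble (see [module_eigengenes()]).
#' @param design Design tibble; treated/control groups are derived with
#'   [treatment_groups()].
#' @param matrix Optional protein x sample tibble; required (together with
#'   `partition`) for the PCA-separation score.
#' @param partition Optional partition tibble matching the eigengenes.
#' @return Tibble with `module`, `effect`, `pca_separation`, `pooled_sd_ok`.
#' @export
eigengene_contrast <- function(eigengenes, design, matrix = NULL,
                               partition = NULL) {
  grp <- treatment_groups(design)
  memat <- me_matrix(eigengenes)
  samples <- rownames(memat)
  treated <- intersect(samples, grp$treated)
  control <- intersect(samples, grp$control)
  if (length(treated) == 0 || length(control) == 0) {
    abort("design must provide both treated and control samples")
  }
  purrr::map_dfr(colnames(memat), function(mod) {
    xt <- memat[treated, mod]
    xc <- memat[control, mod]
    n1 <- length(xt); n2 <- length(xc)
    ok <- n1 >= 2 && n2 >= 2
    sp <- if (ok) {
      sqrt(((n1 - 1) * var(xt) + (n2 - 1) * var(xc)) / (n1 + n2 - 2))
    } else {
      NA_real_
    }
    eff <- if (ok && sp > 0) (mean(xt) - mean(xc)) / sp else {
      if (isTRUE(all.equal(mean(xt), mean(xc)))) 0 else NA_real_
    }
    if (ok && sp == 0 && mean(xt) == mean(xc)) eff <- 0
    sep <- NA_real_
    if (!is.null(matrix) && !is.null(partition)) {
      sep <- pca_separation(matrix, partition, mod, treated, control)
    }
    tibble::tibble(module = mod, effect = eff, pca_separation = sep,
                   pooled_sd_ok = ok)
  })
}

pca_separation <- function(matrix, partition, module, treated, control) {
  acc <- partition$accession[partition$module == module]
  m <- pm_to_matrix(matrix)[acc, c(treated, control), drop = FALSE]
  m <- t(apply(m, 1, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  keep <- apply(m, 1, sd) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) return(NA_real_)
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  labels <- c(rep(1L, length(treated)), rep(2L, length(control)))
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Select treatment-affected modules
#'
#' A module is called treatment-affected when its standardized eigengene
#' contrast reaches `effect_threshold` in absolute value, or when the
#' treated/control groups separate on the module's first two principal
#' components (`pca_separation >= pca_threshold`). This makes the visual
#' module-selection step deterministic and testable.
#'
#' @param contrasts Tibble from [eigengene_contrast()].
#' @param effect_threshold Standardized effect cutoff (default 1.0).
#' @param pca_threshold Silhouette-score cutoff (default 0.25).
#' @return Character vector of selected module labels.
#' @export
select_affected <- function(contrasts, effect_threshold = 1.0,
                            pca_threshold = 0.25) {
  eff_ok <- !is.na(contrasts$effect) & abs(contrasts$effect) >= effect_threshold
  pca_ok <- !is.na(contrasts$pca_separation) &
    contrasts$pca_separation >= pca_threshold
  contrasts$module[(eff_ok | pca_ok) & contrasts$module != "grey"]
}

#' Per-module disease annotation counts
#'
#' The per-module summary reported for disease-association catalogues:
#' protein count, disease-overlap count, weighted-protein count, and
#' weighted-and-disease count.
#'
#' @param partition Partition tibble.
#' @param weighted Character vector of weighted-protein accessions.
#' @param disease_set Character vector of disease-associated accessions
#'   (nonempty).
#' @return Tibble with one row per module (grey last):
#'   `module`, `n_proteins`, `n_disease`, `n_weighted`,
#'   `n_weighted_disease`.
#' @export
annotate_disease <- function(partition, weighted, disease_set) {
  if (length(disease_set) == 0) abort("`disease_set` must be nonempty")
  partition |>
    dplyr::mutate(
      disease = .data$accession %in% disease_set,
      wt = .data$accession %in% weighted
    ) |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_disease = sum(.data$disease),
      n_weighted = sum(.data$wt),
      n_weighted_disease = sum(.data$disease & .data$wt),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$module == "grey", dplyr::desc(.data$n_proteins))
}

#' Over-representation analysis (hypergeometric test)
#'
#' Tests each pathway for over-representation of the query set within the
#' background universe using the hypergeometric upper tail: the probability
#' of observing at least the realized overlap when drawing `|query|`
#' proteins from the background with `|pathway ∩ background|` successes.
#' P-values are Benjamini-Hochberg adjusted across the tested pathways;
#' a pathway passes when both p and q fall below their cutoffs.
#'
#' @param query Character vector, the protein set of interest (must be a
#'   subset of `background`).
#' @param background Character vector, the protein universe (typically the
#'   post-filter proteins of the analyzed dataset).
#' @param pathways Named list of character vectors (e.g. from
#'   [read_gmt()]); each pathway is intersected with the background.
#' @param p_cut,q_cut Significance cutoffs (default 0.01 each).
#' @param min_overlap Pathways with smaller overlap are still reported; set
#'   to drop tiny overlaps from testing (default 0 keeps all).
#' @return Tibble with `pathway_id`, `size` (in background), `overlap`,
#'   `p_value`, `q_value`, `passes`.
#' @export
ora <- function(query, background, pathways, p_cut = 0.01, q_cut = 0.01,
                min_overlap = 0) {
  if (!all(query %in% background)) {
    abort("`query` must be a subset of `background`")
  }
  query <- unique(query)
  background <- unique(background)
  n_bg <- length(background)
  n_q <- length(query)
  res <- purrr::imap_dfr(pathways, function(genes, id) {
    pw <- intersect(unique(genes), background)
    ov <- length(intersect(pw, query))
    p <- if (length(pw) == 0) 1 else {
      phyper(ov - 1, m = length(pw), n = n_bg - length(pw), k = n_q,
             lower.tail = FALSE)
    }
    tibble::tibble(pathway_id = id, size = length(pw), overlap = ov,
                   p_value = p)
  })
  res <- dplyr::filter(res, .data$overlap >= min_overlap)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$passes <- res$p_value < p_cut & res$q_value < q_cut
  dplyr::arrange(res, .data$p_value)
}
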