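me_matrix <- function(eigengenes) {
  m <- as.matrix(eigengenes[setdiff(names(eigengenes), "sample_id")])
  rownames(m) <- eigengenes$sample_id
  m
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized protein x sample submatrix: each member protein is
#' mean-imputed (per protein) and z-scored across samples, and the first
#' right singular vector of the resulting matrix is taken as the per-sample
#' module summary. The eigengene has unit norm and is oriented so that it
#' correlates non-negatively with the module's average standardized profile.
#' Proteins that are entirely missing or constant are excluded from the
#' decomposition with a warning.
#'
#' @param matrix Protein x sample tibble of log2 intensities.
#' @param partition Partition tibble (`accession`, `module`); grey proteins
#'   are skipped.
#' @return Tibble with `sample_id` plus one eigengene column per non-grey
#'   module, carrying a `variance_explained` attribute (named numeric, the
#'   fraction of standardized module variance captured).
#' @export
module_eigengenes <- function(matrix, partition) {
  m <- pm_to_matrix(matrix)
  mods <- setdiff(unique(partition$module), "grey")
  if (length(mods) == 0) abort("no non-grey modules in partition")
  me <- matrix(NA_real_, nrow = ncol(m), ncol = length(mods),
               dimnames = list(colnames(m), mods))
  var_exp <- setNames(numeric(length(mods)), mods)
  for (j in seq_along(mods)) {
    acc <- partition$accession[partition$module == mods[j]]
    x <- m[acc, , drop = FALSE]
    all_miss <- rowSums(!is.na(x)) == 0
    if (any(all_miss)) {
      warn(sprintf("module %s: %d all-missing protein(s) excluded from the eigengene",
                   mods[j], sum(all_miss)))
      x <- x[!all_miss, , drop = FALSE]
    }
    x <- t(apply(x, 1, function(r) {
      r[is.na(r)] <- mean(r, na.rm = TRUE)
      r
    }))
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      warn(sprintf("module %s: %d constant protein(s) excluded from the eigengene",
                   mods[j], sum(sds == 0)))
      x <- x[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (nrow(x) == 0) abort(sprintf("module %s has no usable proteins", mods[j]))
    z <- (x - rowMeans(x)) / sds
    sv <- svd(z)
    eig <- sv$v[, 1]
    avg <- colMeans(z)
    if (sum(eig * avg) < 0) eig <- -eig
    me[, j] <- eig
    var_exp[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(m)),
    tibble::as_tibble(me, .name_repair = "minimal")
  )
  attr(out, "variance_explained") <- var_exp
  out
}

#' Merge modules with similar eigengene profiles
#'
#' Modules whose eigengenes are nearly parallel describe the same underlying
#' co-expression signal. Eigengenes are clustered by the dissimilarity
#' `1 - cor`, groups of modules joined below `merge_cut_height` are merged
#' (the merged module keeps the label of its largest constituent), and
#' eigengenes are recomputed; this repeats until every remaining pair of
#' eigengenes is at least `merge_cut_height` apart. Final labels are
#' re-assigned in color order by decreasing size.
#'
#' @param matrix Protein x sample tibble.
#' @param partition Partition tibble from [dynamic_cut()].
#' @param eigengenes Optional eigengene tibble for `partition` (recomputed if
#'   absent).
#' @param merge_cut_height Eigengene dissimilarity threshold (default 0.25).
#' @return List with elements `partition` and `eigengenes` (with
#'   `variance_explained` attribute), plus `n_iterations`.
#' @export
merge_modules <- function(matrix, partition, eigengenes = NULL,
                          merge_cut_height = 0.25) {
  stopifnot(merge_cut_height > 0, merge_cut_height < 1)
  part <- partition
  mods <- setdiff(unique(part$module), "grey")
  if (length(mods) < 2) {
    eig <- eigengenes %||%
      (if (length(mods)) module_eigengenes(matrix, part) else NULL)
    return(list(partition = part, eigengenes = eig, n_iterations = 0L))
  }
  eig <- eigengenes %||% module_eigengenes(matrix, part)
  max_iter <- length(mods)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    memat <- me_matrix(eig)
    mods <- colnames(memat)
    if (length(mods) < 2) break
    diss <- 1 - cor(memat)
    hc <- hclust(as.dist(diss), method = "average")
    grp <- cutree(hc, h = merge_cut_height)
    if (max(grp) == length(mods)) break  # nothing below the threshold
    sizes <- table(part$module)
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1) {
        keep <- members[which.max(sizes[members])]
        part$module[part$module %in% members] <- keep
      }
    }
    eig <- module_eigengenes(matrix, part)
    if (iter >= max_iter) break
  }
  # re-assign colors by decreasing size
  ids <- rep(0L, nrow(part))
  nz <- part$module != "grey"
  ids[nz] <- as.integer(factor(part$module[nz],
                               levels = unique(part$module[nz])))
  part <- label_partition(ids, part$accession)
  eig <- if (any(nz)) module_eigengenes(matrix, part) else NULL
  list(partition = part, eigengenes = eig, n_iterations = iter)
}

#' Module membership (kME) and weighted proteins
#'
#' kME of a protein for a module is the Pearson correlation between the
#' protein's profile and the module eigengene, over pairwise-complete
#' samples. Proteins whose kME for their own module reaches the threshold
#' (default 0.8, inclusive) are the module's "weighted" proteins — the
#' proteins that carry the module signal. Grey proteins have no own module
#' and are never weighted; proteins with fewer than three paired
#' observations get an undefined (missing) kME.
#'
#' @param matrix Protein x sample tibble.
#' @param eigengenes Eigengene tibble (post-merge).
#' @param partition Partition tibble matching the eigengenes.
#' @param kme_threshold Weighted-protein cutoff (default 0.8).
#' @return List with `kme` (tibble: accession, own module, one kME column
#'   per module, `kme_own`) and `weighted` (character vector of accessions).
#' @export
module_membership <- function(matrix, eigengenes, partition,
                              kme_threshold = 0.8) {
  m <- pm_to_matrix(matrix)
  memat <- me_matrix(eigengenes)
  stopifnot(identical(rownames(memat), colnames(m)))
  kme <- suppressWarnings(cor(t(m), memat, use = "pairwise.complete.obs"))
  obs <- !is.na(m)
  n_paired <- obs %*% matrix(1, ncol(m), ncol(memat))
  kme[n_paired < 3] <- NA_real_
  own <- partition$module[match(rownames(kme), partition$accession)]
  kme_own <- vapply(seq_len(nrow(kme)), function(i) {
    if (is.na(own[i]) || own[i] == "grey" || !own[i] %in% colnames(kme)) {
      NA_real_
    } else {
      kme[i, own[i]]
    }
  }, numeric(1))
  weighted <- rownames(kme)[!is.na(kme_own) & kme_own >= kme_threshold]
  kme_tbl <- dplyr::bind_cols(
    tibble::tibble(accession = rownames(kme), module = own),
    tibble::as_tibble(kme, .name_repair = "minimal"),
    tibble::tibble(kme_own = kme_own)
  )
  list(kme = kme_tbl, weighted = weighted)
}

#' Fit the full co-expression module model
#'
#' One-call wrapper for the network stage: signed adjacency at the chosen
#' power, topological overlap, average-linkage dendrogram, hybrid dynamic
#' tree cut, eigengene computation, eigengene-based module merging, and
#' module membership scoring.
#'
#' @param matrix Protein x sample tibble of (filtered, normalized) log2
#'   intensities.
#' @param params A [network_params()] object.
#' @return An object of class `"coex_fit"` with components `partition`,
#'   `eigengenes`, `kme`, `weighted`, `dendrogram`, `soft_threshold`,
#'   `params`.
#' @export
fit_coexpression_modules <- function(matrix, params = network_params()) {
  adj <- signed_adjacency(matrix, params$power)
  diss <- tom_dissimilarity(adj)
  hc <- cluster_tree(diss)
  part0 <- dynamic_cut(hc, diss, params)
  merged <- if (any(part0$module != "grey")) {
    eig0 <- module_eigengenes(matrix, part0)
    merge_modules(matrix, part0, eig0, params$merge_cut_height)
  } else {
    list(partition = part0, eigengenes = NULL, n_iterations = 0L)
  }
  mm <- if (!is.null(merged$eigengenes)) {
    module_membership(matrix, merged$eigengenes, merged$partition,
                      params$kme_threshold)
  } else {
    list(kme = NULL, weighted = character())
  }
  k <- rowSums(adj) - 1
  sf <- scale_free_fit(k)
  structure(list(
    partition = merged$partition,
    eigengenes = merged$eigengenes,
    kme = mm$kme,
    weighted = mm$weighted,
    dendrogram = hc,
    soft_threshold = tibble::tibble(
      power = params$power, scale_free_r2 = sf$r2, slope = sf$slope,
      mean_connectivity = mean(k)
    ),
    params = params,
    n_samples = length(sample_cols(matrix))
  ), class = "coex_fit")
}

#' @export
print.coex_fit <- function(x, ...) {
  sizes <- module_sizes(x$partition)
  cat("Signed co-expression module fit\n")
  cat(sprintf("  %d proteins, %d samples, power = %g\n",
              nrow(x$partition), x$n_samples, x$params$power))
  cat(sprintf("  scale-free R2 = %.2f, mean connectivity = %.1f\n",
              x$soft_threshold$scale_free_r2,
              x$soft_threshold$mean_connectivity))
  cat(sprintf("  %d modules (%d weighted proteins):\n",
              sum(sizes$module != "grey"), length(x$weighted)))
  print(sizes, n = Inf)
  invisible(x)
}

#' Module sizes of a partition
#'
#' @param partition Partition tibble (`accession`, `module`).
#' @return Tibble (`module`, `n_proteins`) sorted by decreasing size with
#'   grey last.
#' @export
module_sizes <- function(partition) {
  partition |>
    dplyr::count(.data$module, name = "n_proteins") |>
    dplyr::arrange(.data$module == "grey", dplyr::desc(.data$n_proteins))
}

#' @describeIn fit_coexpression_modules Per-protein tidy summary: module
#'   assignment, own-module kME and weighted flag.
#' @param x A `coex_fit` object.
#' @param ... Unused.
#' @export
tidy.coex_fit <- function(x, ...) {
  out <- x$partition
  if (!is.null(x$kme)) {
    out <- dplyr::left_join(out,
      dplyr::select(x$kme, "accession", "kme_own"), by = "accession")
  } else {
    out$kme_own <- NA_real_
  }
  out$weighted <- out$accession %in% x$weighted
  out
}

#' @describeIn fit_coexpression_modules One-row model summary.
#' @export
glance.coex_fit <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$partition),
    n_samples = x$n_samples,
    n_modules = sum(unique(x$partition$module) != "grey"),
    n_grey = sum(x$partition$module == "grey"),
    n_weighted = length(x$weighted),
    power = x$params$power,
    scale_free_r2 = x$soft_threshold$scale_free_r2,
    mean_connectivity = x$soft_threshold$mean_connectivity
  )
}
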