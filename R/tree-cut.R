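#' Network and module-detection parameters
#'
#' Bundles the tunable parameters of the co-expression analysis. The
#' `deep_split` level (0-4) controls how aggressively dendrogram branches are
#' split into candidate modules; it maps to a maximum core scatter of
#' 0.64/0.73/0.82/0.91/0.95 and a minimum branch gap of three quarters of the
#' remaining headroom, both on the normalized dendrogram height scale.
#' Explicit `max_core_scatter`/`min_gap` values override the mapping.
#'
#' @param power Soft-thresholding power for the signed adjacency.
#' @param min_cluster_size Smallest allowed module (default 30).
#' @param deep_split Split aggressiveness, integer 0-4 (default 3).
#' @param pam_respects_dendro Only `FALSE` is supported: the
#'   medoid-assignment stage ignores dendrogram position.
#' @param merge_cut_height Eigengene dissimilarity (1 - correlation) below
#'   which modules are merged (default 0.25).
#' @param kme_threshold Module-membership cutoff defining weighted proteins
#'   (default 0.8, inclusive).
#' @param cut_height Maximum merge height considered part of any branch;
#'   default 0.99 of the dendrogram height.
#' @param max_core_scatter,min_gap Optional explicit branch criteria on the
#'   normalized height scale.
#' @param pam_stage Run the medoid-style assignment of leftover proteins
#'   (default `TRUE`).
#' @param pam_gate Gate for the assignment stage. `NULL` (default) uses the
#'   cluster-relative rule: a leftover protein joins its nearest module only
#'   if its average dissimilarity to it does not exceed the loosest current
#'   member's average dissimilarity. A numeric value instead imposes an
#'   absolute bound on the normalized height scale.
#' @return A list of class `"network_params"`.
#' @export
network_params <- function(power = 2, min_cluster_size = 30, deep_split = 3,
                           pam_respects_dendro = FALSE,
                           merge_cut_height = 0.25, kme_threshold = 0.8,
                           cut_height = NULL, max_core_scatter = NULL,
                           min_gap = NULL, pam_stage = TRUE, pam_gate = NULL) {
  stopifnot(power > 0, min_cluster_size >= 1,
            deep_split %in% 0:4,
            merge_cut_height > 0, merge_cut_height < 1,
            kme_threshold > 0, kme_threshold <= 1)
  if (isTRUE(pam_respects_dendro)) {
    abort("only pam_respects_dendro = FALSE is supported")
  }
  mcs_map <- c(0.64, 0.73, 0.82, 0.91, 0.95)
  mcs <- max_core_scatter %||% mcs_map[deep_split + 1]
  structure(list(
    power = power,
    min_cluster_size = as.integer(min_cluster_size),
    deep_split = as.integer(deep_split),
    pam_respects_dendro = FALSE,
    merge_cut_height = merge_cut_height,
    kme_threshold = kme_threshold,
    cut_height = cut_height,
    max_core_scatter = mcs,
    min_gap = min_gap %||% ((1 - mcs) * 3 / 4),
    pam_stage = pam_stage,
    pam_gate = pam_gate
  ), class = "network_params")
}

#' Standard module color sequence
#'
#' Module labels follow the conventional color order, assigned by decreasing
#' module size; `grey` is reserved for unassigned proteins.
#'
#' @param n Number of colors requested.
#' @return Character vector of color names.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "skyblue",
            "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta")
  if (n > length(base)) base <- c(base, paste0("module", seq_len(n - length(base))))
  base[seq_len(n)]
}

# Relabel integer cluster ids (0 = unassigned) with colors by decreasing
# size; ties broken by first occurrence.
label_partition <- function(cluster_ids, accessions) {
  module <- rep("grey", length(cluster_ids))
  ids <- setdiff(unique(cluster_ids), 0)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(cluster_ids == i), integer(1))
    first <- vapply(ids, function(i) which(cluster_ids == i)[1], integer(1))
    ord <- ids[order(-sizes, first)]
    cols <- module_colors(length(ord))
    for (j in seq_along(ord)) module[cluster_ids == ord[j]] <- cols[j]
  }
  tibble::tibble(accession = accessions, module = module)
}

#' Hybrid dynamic tree cut
#'
#' Detects modules as coherent dendrogram branches rather than by cutting at
#' a fixed height. Working on the normalized height scale (5th percentile of
#' merge heights to `cut_height`), a branch is a candidate module when it
#' (i) holds at least `min_cluster_size` proteins, (ii) has a tight core —
#' the mean of its lowest internal merge heights stays below
#' `max_core_scatter` — and (iii) hangs clearly below its attachment point
#' (gap of at least `min_gap`). Candidate branches are reported at the
#' highest level at which they remain coherent; branch points joining two
#' candidate lineages split them. Proteins not covered by any candidate
#' branch are then assigned, ignoring dendrogram position, to the module
#' with the smallest average dissimilarity, provided that distance passes the
#' `pam_gate`; leftovers are labeled grey.
#'
#' @param dendrogram An [stats::hclust] tree built from `dissimilarity`.
#' @param dissimilarity The dissimilarity matrix the tree was built from
#'   (typically [tom_dissimilarity()]).
#' @param params A [network_params()] object.
#' @return Partition tibble (`accession`, `module`), color-labeled by
#'   decreasing module size, with a `"params"` attribute.
#' @export
dynamic_cut <- function(dendrogram, dissimilarity, params = network_params()) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  acc <- dendrogram$labels %||% rownames(dissimilarity) %||% as.character(seq_len(n))
  if (params$min_cluster_size > n) {
    warn("min_cluster_size exceeds the number of proteins; all grey")
    return(structure(label_partition(rep(0L, n), acc), params = params))
  }
  merge <- dendrogram$merge
  height <- dendrogram$height
  cut_height <- params$cut_height %||% (0.99 * max(height))
  href <- quantile(height, 0.05, names = FALSE)
  scale_h <- max(cut_height - href, .Machine$double.eps)
  normh <- function(h) (h - href) / scale_h

  n_nodes <- n - 1L
  members <- vector("list", n_nodes)
  int_heights <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    mem <- list(); hts <- list()
    for (ch in merge[i, ]) {
      if (ch < 0) {
        mem <- c(mem, list(-ch))
      } else {
        mem <- c(mem, list(members[[ch]]))
        hts <- c(hts, list(int_heights[[ch]]))
      }
    }
    members[[i]] <- unlist(mem)
    int_heights[[i]] <- c(unlist(hts), height[i])
  }
  attach_h <- rep(Inf, n_nodes)
  for (i in seq_len(n_nodes)) {
    for (ch in merge[i, ]) if (ch > 0) attach_h[ch] <- height[i]
  }

  n_core <- max(1L, ceiling(params$min_cluster_size / 2))
  qualifies <- function(i) {
    sz <- length(members[[i]])
    if (sz < params$min_cluster_size) return(FALSE)
    hts <- sort(int_heights[[i]])
    core_scatter <- normh(mean(hts[seq_len(min(length(hts), n_core))]))
    if (core_scatter > params$max_core_scatter) return(FALSE)
    gap <- normh(attach_h[i]) - normh(max(hts))
    gap >= params$min_gap
  }

  res <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    kids <- merge[i, ]
    r <- lapply(kids, function(ch) if (ch > 0) res[[ch]] else list())
    if (length(r[[1]]) && length(r[[2]])) {
      res[[i]] <- c(r[[1]], r[[2]])
    } else if (length(r[[1]]) || length(r[[2]])) {
      res[[i]] <- c(r[[1]], r[[2]])
    } else {
      res[[i]] <- if (qualifies(i)) list(members[[i]]) else list()
    }
  }
  clusters <- res[[n_nodes]]

  cluster_ids <- rep(0L, n)
  for (j in seq_along(clusters)) cluster_ids[clusters[[j]]] <- j

  if (params$pam_stage && length(clusters)) {
    # loosest-member average dissimilarity per cluster (the fit gate)
    maxd <- vapply(clusters, function(mem) {
      if (length(mem) < 2) return(0)
      max(vapply(mem, function(j) mean(dissimilarity[j, setdiff(mem, j)]),
                 numeric(1)))
    }, numeric(1))
    unassigned <- which(cluster_ids == 0L)
    for (i in unassigned) {
      d <- vapply(clusters, function(mem) mean(dissimilarity[i, mem]),
                  numeric(1))
      best <- which.min(d)
      fits <- if (is.null(params$pam_gate)) d[best] <= maxd[best]
              else normh(d[best]) <= params$pam_gate
      if (fits) cluster_ids[i] <- best
    }
  }
  structure(label_partition(cluster_ids, acc), params = params)
}
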