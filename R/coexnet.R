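as_protein_matrix <- function(x) {
  if (is.matrix(x)) x else pm_to_matrix(x)
}

#' Signed weighted co-expression adjacency
#'
#' Computes `a_ij = ((1 + cor(x_i, x_j)) / 2) ^ power` with Pearson
#' correlation over pairwise-complete samples. In a signed network strongly
#' anti-correlated proteins get adjacency near zero instead of near one.
#' Protein pairs with fewer than three shared observations are treated as
#' uncorrelated (`cor = 0`, adjacency `0.5^power`).
#'
#' @param matrix Protein x sample tibble (or numeric matrix, proteins in
#'   rows) of log2 intensities; at least 3 samples.
#' @param power Soft-thresholding power (beta > 0).
#' @return Symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(matrix, power = 2) {
  stopifnot(power > 0)
  m <- as_protein_matrix(matrix)
  if (ncol(m) < 3) abort("need at least 3 samples for correlation networks")
  cc <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  obs <- !is.na(m)
  shared <- obs %*% t(obs)
  cc[shared < 3] <- 0
  cc[is.na(cc)] <- 0
  a <- ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Soft-threshold (scale-free topology) diagnostics
#'
#' For each candidate power, builds the signed adjacency and reports the mean
#' connectivity (`k_i` = sum of off-diagonal adjacencies) plus a scale-free
#' topology fit: connectivities are binned into `n_bins` equal-width bins,
#' and `log10(frequency)` is regressed on `log10(mean connectivity)` over the
#' nonempty bins. The (unsigned) regression R-squared and the slope are
#' reported separately — an approximately scale-free network shows a high
#' R-squared with negative slope.
#'
#' @param matrix Protein x sample tibble or matrix.
#' @param powers Candidate powers (nonempty numeric vector).
#' @param n_bins Number of connectivity bins (default 10).
#' @return Tibble with columns `power`, `scale_free_r2`, `slope`,
#'   `mean_connectivity`.
#' @export
soft_threshold_report <- function(matrix, powers = c(1:10, 12, 14, 16),
                                  n_bins = 10) {
  if (length(powers) == 0) abort("`powers` must be nonempty")
  m <- as_protein_matrix(matrix)
  if (nrow(m) < 2) abort("need at least 2 proteins")
  purrr::map_dfr(powers, function(p) {
    a <- signed_adjacency(m, p)
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_bins = n_bins)
    tibble::tibble(power = p, scale_free_r2 = fit$r2, slope = fit$slope,
                   mean_connectivity = mean(k))
  })
}

scale_free_fit <- function(k, n_bins = 10) {
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    warn("degenerate connectivity distribution; scale-free R2 reported as 0")
    return(list(r2 = 0, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(ok) < 3) return(list(r2 = 0, slope = NA_real_))
  x <- log10(kmean[ok])
  y <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm(y ~ x)
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' The topological overlap of two proteins combines their direct adjacency
#' with the adjacency they share through common neighbours:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu` over
#' `u != i`. `1 - w` is the clustering dissimilarity used to build the
#' protein dendrogram.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]` with unit
#'   diagonal.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("adjacency must be symmetric")
  }
  if (any(adjacency < -1e-12) || any(adjacency > 1 + 1e-12)) {
    abort("adjacency values must lie in [0, 1]")
  }
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  w <- (l + a0) / (kmin + 1 - a0)
  diag(w) <- 1
  dimnames(w) <- dimnames(adjacency)
  w
}

#' Topological overlap dissimilarity
#'
#' @param adjacency Symmetric adjacency matrix (see [tom_similarity()]).
#' @return `1 - tom_similarity(adjacency)`.
#' @export
tom_dissimilarity <- function(adjacency) 1 - tom_similarity(adjacency)

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' @param dissimilarity Symmetric dissimilarity matrix with zero diagonal and
#'   no NaN values.
#' @return An [stats::hclust] object (average linkage).
#' @export
cluster_tree <- function(dissimilarity) {
  if (anyNA(dissimilarity)) abort("dissimilarity contains missing values")
  if (!isSymmetric(unname(dissimilarity), tol = 1e-10)) {
    abort("dissimilarity must be symmetric")
  }
  if (any(abs(diag(dissimilarity)) > 1e-12)) {
    abort("dissimilarity must have a zero diagonal")
  }
  hclust(as.dist(dissimilarity), method = "average")
}
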