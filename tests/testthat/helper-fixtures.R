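# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no binary fixtures.

# Adjusted Rand index between two label vectors (independent oracle used to
# score module recovery).
ari <- function(a, b) {
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- sr * sc / choose(n, 2)
  (s - e) / ((sr + sc) / 2 - e)
}

# Brute-force topological overlap by explicit triple loop (oracle).
tom_bruteforce <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  w
}

# Exact hypergeometric upper-tail by direct combinatorial summation (oracle).
hyper_tail_oracle <- function(overlap, pathway, background, query) {
  ks <- overlap:min(pathway, query)
  sum(vapply(ks, function(k) {
    exp(lchoose(pathway, k) + lchoose(background - pathway, query - k) -
          lchoose(background, query))
  }, numeric(1)))
}

# Random valid adjacency matrix (symmetric, [0,1], unit diagonal).
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Small in vitro design reused by the module-structure tests: replicate 1 of
# the full design plus one extra control (48 samples).
design_48 <- function() {
  d3 <- generate_invitro_design(3)
  dplyr::bind_rows(
    dplyr::filter(d3, replicate == 1),
    dplyr::filter(d3, compound == "none", timepoint_h == 2, replicate == 2)[1, ]
  )
}

# A tight planted-block matrix with essentially noise-free modules.
block_matrix <- function(sizes, n_samples = 30, seed = 1) {
  des <- generate_biopsy_design(n_samples, 0, 0)
  generate_protein_profiles(des, sizes, kme_target = 0.98, noise_sd = 0.1,
                            seed = seed)$matrix
}
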