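test_that("eigengene of a coherent module matches the shared profile", {
  profile <- c(1, 3, 2, 5, 4, 6)
  m <- matrix(rep(profile, each = 4), nrow = 4) + 0.01 * matrix(1:24, 4)
  dimnames(m) <- list(paste0("P", 1:4), paste0("s", 1:6))
  part <- tibble::tibble(accession = rownames(m), module = "turquoise")
  eig <- module_eigengenes(matrix_to_pm(m), part)
  e <- eig$turquoise
  expect_equal(sum(e^2), 1, tolerance = 1e-12)          # unit norm
  expect_gt(abs(cor(e, profile)), 0.999)
  expect_gte(cor(e, profile), 0)                         # orientation
  ve <- attr(eig, "variance_explained")
  expect_gt(ve[["turquoise"]], 0.999)
})

test_that("flipping all protein signs flips the eigengene", {
  withr::with_seed(61, {
    m <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("P", 1:5), paste0("s", 1:8)))
  })
  part <- tibble::tibble(accession = rownames(m), module = "blue")
  e1 <- module_eigengenes(matrix_to_pm(m), part)$blue
  e2 <- module_eigengenes(matrix_to_pm(-m), part)$blue
  expect_equal(e2, -e1, tolerance = 1e-9)
})

test_that("anti-correlated halves: high variance explained, near-zero mean kME", {
  profile <- c(2, -1, 3, -2, 1, -3, 2, -2)
  m <- rbind(matrix(rep(profile, each = 5), 5),
             matrix(rep(-profile, each = 5), 5))
  m <- m + withr::with_seed(62, matrix(rnorm(80, sd = 0.05), 10))
  dimnames(m) <- list(paste0("P", 1:10), paste0("s", 1:8))
  part <- tibble::tibble(accession = rownames(m), module = "brown")
  eig <- module_eigengenes(matrix_to_pm(m), part)
  expect_gt(attr(eig, "variance_explained")[["brown"]], 0.99)
  mm <- module_membership(matrix_to_pm(m), eig, part)
  expect_lt(abs(mean(mm$kme$kme_own)), 0.1)
})

test_that("all-missing proteins are excluded from eigengenes with a warning", {
  withr::with_seed(63, {
    m <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
  })
  m[4, ] <- NA
  part <- tibble::tibble(accession = rownames(m), module = "red")
  expect_warning(eig <- module_eigengenes(matrix_to_pm(m), part),
                 "all-missing")
  expect_false(anyNA(eig$red))
})

test_that("modules with near-parallel eigengenes merge; distant ones do not", {
  des <- generate_biopsy_design(30, 0, 0)
  # two planted modules sharing one template (split artificially), one apart
  sim <- generate_protein_profiles(des, c(40, 35), kme_target = 0.95,
                                   noise_sd = 0.2, seed = 64)
  part <- sim$truth$planted_partition
  # split M1 into two labels -> their eigengenes correlate near 1
  split_part <- part
  first_half <- part$accession[part$module == "M1"][1:20]
  split_part$module[split_part$accession %in% first_half] <- "M1b"
  eig <- module_eigengenes(sim$matrix, split_part)
  memat <- as.matrix(eig[-1])
  expect_gt(cor(memat[, "M1"], memat[, "M1b"]), 0.75)
  merged <- merge_modules(sim$matrix, split_part, eig)
  sizes <- module_sizes(merged$partition)
  expect_equal(sort(sizes$n_proteins), c(35, 40))   # M1 reunified, M2 apart
  expect_lte(merged$n_iterations,
             length(unique(split_part$module)))
  # final eigengene pairs all at least merge_cut_height apart
  final <- 1 - cor(as.matrix(merged$eigengenes[-1]))
  expect_true(all(final[upper.tri(final)] >= 0.25))
})

test_that("kME threshold is inclusive and grey proteins are never weighted", {
  e <- c(1, 3, 2, 5, 4)
  x <- c(1, 2, 3, 4, 5)  # cor(x, e) = 0.8
  m <- rbind(X = x, G = c(5, 1, 4, 2, 3))
  colnames(m) <- paste0("s", 1:5)
  eig <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                          tibble::tibble(turquoise = e))
  part <- tibble::tibble(accession = c("X", "G"),
                         module = c("turquoise", "grey"))
  mm <- module_membership(matrix_to_pm(m), eig, part)
  k <- mm$kme$kme_own[mm$kme$accession == "X"]
  expect_equal(k, 0.8, tolerance = 1e-12)
  # a protein sitting exactly at the threshold is weighted (>=, not >)
  mm_at <- module_membership(matrix_to_pm(m), eig, part, kme_threshold = k)
  expect_true("X" %in% mm_at$weighted)
  expect_false("G" %in% mm_at$weighted)
  expect_true(is.na(mm_at$kme$kme_own[mm_at$kme$accession == "G"]))
})

test_that("kME is undefined with fewer than 3 paired observations", {
  m <- rbind(X = c(1, 2, NA, NA, NA))
  colnames(m) <- paste0("s", 1:5)
  eig <- tibble::tibble(sample_id = colnames(m), blue = c(1, 2, 3, 4, 5))
  part <- tibble::tibble(accession = "X", module = "blue")
  mm <- module_membership(matrix_to_pm(m), eig, part)
  expect_true(is.na(mm$kme$kme_own))
  expect_length(mm$weighted, 0)
})

test_that("a protein identical to its eigengene has kME 1 and is weighted", {
  e <- withr::with_seed(65, rnorm(10))
  m <- rbind(X = e, Y = e + withr::with_seed(66, rnorm(10, sd = 2)))
  colnames(m) <- paste0("s", 1:10)
  eig <- tibble::tibble(sample_id = colnames(m), green = e)
  part <- tibble::tibble(accession = c("X", "Y"), module = "green")
  mm <- module_membership(matrix_to_pm(m), eig, part)
  expect_equal(mm$kme$kme_own[mm$kme$accession == "X"], 1, tolerance = 1e-12)
  expect_true("X" %in% mm$weighted)
})
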