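test_that("the in vitro design reproduces the 139-sample study layout", {
  d <- generate_invitro_design(3)
  expect_equal(nrow(d), 139)
  counts <- table(d$compound)
  expect_equal(unname(counts[c("none", "DOX", "EPI", "IDA")]),
               c(21, 42, 42, 34), ignore_attr = TRUE)
  # toxic idarubicin truncated at 168 h, reduced replicates at 2 and 24 h
  ida_tox <- dplyr::filter(d, compound == "IDA", dose == "toxic")
  expect_true(all(ida_tox$timepoint_h <= 168))
  expect_equal(sum(ida_tox$timepoint_h %in% c(2, 24)), 4)
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_true(all(is.na(d$patient_group)))
})

test_that("single-replicate design enumerates the factorial (47 rows)", {
  d <- generate_invitro_design(1)
  expect_equal(nrow(d), 47)
  counts <- table(d$compound)
  expect_equal(unname(counts[c("none", "DOX", "EPI", "IDA")]),
               c(7, 14, 14, 12), ignore_attr = TRUE)
  expect_error(generate_invitro_design(0), "positive integer")
})

test_that("design generation is deterministic and biopsy groups are right", {
  expect_identical(generate_invitro_design(3), generate_invitro_design(3))
  b <- generate_biopsy_design()
  expect_equal(nrow(b), 16)
  expect_equal(unname(table(b$patient_group)[c("control", "ant_treated",
                                               "nonant_treated")]),
               c(8, 6, 2), ignore_attr = TRUE)
  expect_true(all(b$compound == "none"))
  expect_true(all(is.na(b$timepoint_h)))
})

test_that("noise-free planted modules are exactly collinear", {
  des <- generate_biopsy_design(10, 0, 0)
  sim <- generate_protein_profiles(des, c(5, 4), kme_target = 1, noise_sd = 0,
                                   seed = 3)
  m <- pm_to_matrix(sim$matrix)
  part <- sim$truth$planted_partition
  for (mod in c("M1", "M2")) {
    sub <- m[part$accession[part$module == mod], ]
    cors <- cor(t(sub))
    expect_equal(max(abs(cors - 1)), 0, tolerance = 1e-12)
  }
  expect_error(generate_protein_profiles(des[0, ], c(5)), "empty design")
  expect_error(generate_protein_profiles(des, c(5, -1)), "positive")
})

test_that("a null treatment effect gives near-zero eigengene contrasts", {
  des <- generate_invitro_design(3)
  effects <- purrr::map_dbl(1:5, function(s) {
    sim <- generate_protein_profiles(des, c(40), effect_size = 0, seed = s)
    eig <- module_eigengenes(sim$matrix, sim$truth$planted_partition)
    ct <- eigengene_contrast(eig, des)
    abs(ct$effect)
  })
  expect_lt(mean(effects), 0.5)
})

test_that("same seed reproduces the simulated matrix byte for byte", {
  des <- design_48()
  s1 <- generate_protein_profiles(des, c(20, 10), seed = 11)
  s2 <- generate_protein_profiles(des, c(20, 10), seed = 11)
  expect_identical(s1, s2)
  s3 <- generate_protein_profiles(des, c(20, 10), seed = 12)
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("peptide expansion is lossless by construction", {
  des <- generate_biopsy_design(4, 0, 0)
  sim <- generate_protein_profiles(des, c(3), seed = 5)
  pep0 <- generate_peptides(sim$matrix, c(4, 4), variant_fraction = 0,
                            seed = 6)
  # no variants: one row per peptide, 4 peptides per protein
  expect_equal(nrow(pep0), 3 * 4)
  expect_false(anyDuplicated(pep0[c("peptide", "protein")]) > 0)
  # peptide intensities are factor * linear protein abundance: ratios across
  # samples equal the protein's linear profile ratios
  lin <- 2^pm_to_matrix(sim$matrix)
  v <- as.matrix(pep0[setdiff(names(pep0), c("peptide", "protein", "charge",
                                             "modification"))])
  for (r in seq_len(nrow(pep0))) {
    expect_equal(v[r, ] / v[r, 1],
                 lin[pep0$protein[r], ] / lin[pep0$protein[r], 1],
                 tolerance = 1e-12)
  }
})

test_that("charge/modification variants sum back to the peptide total", {
  des <- generate_biopsy_design(3, 0, 0)
  sim <- generate_protein_profiles(des, c(2), seed = 7)
  pep <- generate_peptides(sim$matrix, c(3, 3), variant_fraction = 1, seed = 8)
  expect_gt(nrow(pep), 6)                     # every peptide split in variants
  cons <- consolidate_peptides(pep)
  expect_equal(nrow(cons), 6)
  # after consolidation each peptide is factor * linear protein profile again
  lin <- 2^pm_to_matrix(sim$matrix)
  v <- as.matrix(cons[setdiff(names(cons), c("peptide", "protein"))])
  for (r in seq_len(nrow(cons))) {
    ratio <- v[r, ] / lin[cons$protein[r], ]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  }
})

test_that("missingness injection hits the target rate", {
  des <- design_48()
  sim <- generate_protein_profiles(des, c(40, 30), seed = 9)
  expect_identical(inject_missingness(sim$matrix, target_rate = 0), sim$matrix)
  mc <- inject_missingness(sim$matrix, "MCAR", 0.3, seed = 10)
  frac <- mean(is.na(pm_to_matrix(mc)))
  expect_gte(frac, 0.27); expect_lte(frac, 0.33)
  expect_error(inject_missingness(sim$matrix, target_rate = 1), "\\[0, 1\\)")
})

test_that("intensity-dependent censoring removes predominantly low values", {
  des <- design_48()
  sim <- generate_protein_profiles(des, c(40, 30), seed = 9)
  v0 <- pm_to_matrix(sim$matrix)
  mi <- inject_missingness(sim$matrix, "intensity_dependent", 0.25, seed = 11)
  v1 <- pm_to_matrix(mi)
  censored <- v0[is.na(v1)]
  retained <- v0[!is.na(v1)]
  expect_lt(mean(censored), mean(retained))
  expect_identical(mi, inject_missingness(sim$matrix, "intensity_dependent",
                                          0.25, seed = 11))
})

test_that("simulated PPI graphs are simple with hub degrees as planted", {
  prot <- sprintf("P%03d", 1:100)
  g <- generate_ppi(prot, hub_count = 3, hub_degree = 30,
                    background_degree_mean = 2, seed = 12)
  expect_true(all(g$edges$from != g$edges$to))
  key <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  expect_false(anyDuplicated(key) > 0)
  deg <- table(c(g$edges$from, g$edges$to))
  expect_true(all(deg[g$hubs] >= 30))
  # degenerate cases
  g0 <- generate_ppi(prot, hub_count = 0, background_degree_mean = 0)
  expect_equal(nrow(g0$edges), 0)
  expect_error(generate_ppi(prot[1:10], hub_count = 1, hub_degree = 30),
               "smaller than")
})

test_that("disease-set simulation draws from the requested modules", {
  des <- generate_biopsy_design(5, 0, 0)
  sim <- generate_protein_profiles(des, c(20, 20), n_background = 50,
                                   seed = 13)
  ds <- generate_disease_set(sim$truth$planted_partition,
                             module_fraction = 0.5, modules = "M1",
                             background_fraction = 0, seed = 14)
  part <- sim$truth$planted_partition
  expect_equal(length(ds), 10)
  expect_true(all(part$module[match(ds, part$accession)] == "M1"))
})
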