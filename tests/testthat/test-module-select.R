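test_that("a strongly shifted module shows a large standardized contrast", {
  des <- generate_invitro_design(3)
  sim <- generate_protein_profiles(des, c(40, 35), effect_modules = 1,
                                   seed = 71)
  eig <- module_eigengenes(sim$matrix, sim$truth$planted_partition)
  ct <- eigengene_contrast(eig, des, sim$matrix,
                           sim$truth$planted_partition)
  expect_gt(abs(ct$effect[ct$module == "M1"]), 1)
  expect_lt(abs(ct$effect[ct$module == "M2"]), 1)
  expect_gt(ct$pca_separation[ct$module == "M1"],
            ct$pca_separation[ct$module == "M2"])
})

test_that("identical treated and control groups give a zero contrast", {
  des <- tibble::tibble(
    sample_id = paste0("s", 1:6), dataset_kind = "invitro",
    compound = rep(c("none", "DOX"), each = 3), dose = "none",
    timepoint_h = 2, replicate = 1L, patient_group = NA_character_)
  eig <- tibble::tibble(sample_id = des$sample_id,
                        blue = rep(c(0.1, -0.2, 0.4), 2))
  ct <- eigengene_contrast(eig, des)
  expect_equal(ct$effect, 0)
  # a group with < 2 samples flags the pooled SD as undefined
  des1 <- des[c(1, 4:6), ]
  eig1 <- eig[c(1, 4:6), ]
  ct1 <- eigengene_contrast(eig1, des1)
  expect_false(ct1$pooled_sd_ok)
})

test_that("selection applies the effect/PCA thresholds as documented", {
  ct <- tibble::tibble(
    module = c("turquoise", "blue", "brown"),
    effect = c(1.8, 0.2, 1.1),
    pca_separation = c(0.1, 0.05, 0.02),
    pooled_sd_ok = TRUE)
  expect_equal(select_affected(ct), c("turquoise", "brown"))
  # all null -> empty
  ct0 <- dplyr::mutate(ct, effect = 0.1, pca_separation = 0)
  expect_length(select_affected(ct0), 0)
  # threshold 0 selects every non-grey module
  expect_equal(select_affected(ct, effect_threshold = 0), ct$module)
  # the PCA route alone can select
  ct2 <- dplyr::mutate(ct0, pca_separation = c(0.3, 0, 0))
  expect_equal(select_affected(ct2), "turquoise")
  # grey never selected
  ctg <- tibble::tibble(module = "grey", effect = 5, pca_separation = 0.9,
                        pooled_sd_ok = TRUE)
  expect_length(select_affected(ctg), 0)
})

test_that("disease annotation counts the four table rows per module", {
  part <- tibble::tibble(
    accession = sprintf("P%02d", 1:20),
    module = rep(c("turquoise", "blue", "grey"), c(10, 6, 4)))
  disease <- part$accession[part$module == "turquoise"]
  weighted <- part$accession[c(1:3, 11)]
  tab <- annotate_disease(part, weighted, disease)
  tq <- tab[tab$module == "turquoise", ]
  expect_equal(tq$n_proteins, 10)
  expect_equal(tq$n_disease, 10)        # disease set = whole module
  expect_equal(tq$n_weighted, 3)
  expect_equal(tq$n_weighted_disease, 3)
  expect_equal(tab$n_disease[tab$module == "blue"], 0)
  # column sums over modules equal whole-set counts
  expect_equal(sum(tab$n_proteins), nrow(part))
  expect_equal(sum(tab$n_disease), length(disease))
  expect_equal(sum(tab$n_weighted), length(weighted))
  # empty weighted set -> zero weighted rows
  tab0 <- annotate_disease(part, character(0), disease)
  expect_true(all(tab0$n_weighted == 0))
  expect_error(annotate_disease(part, weighted, character(0)), "nonempty")
})

test_that("hypergeometric p-values match the exact summation oracle", {
  bg <- sprintf("B%03d", 1:100)
  pw <- list(path1 = bg[1:10])
  query <- bg[c(1:5, 50:54)]           # overlap 5 of pathway size 10
  res <- ora(query, bg, pw)
  expect_equal(res$p_value, hyper_tail_oracle(5, 10, 100, 10),
               tolerance = 1e-14)
  # zero overlap has p = 1; single pathway means q = p
  res0 <- ora(bg[50:59], bg, pw)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$q_value, res0$p_value)
  expect_error(ora(c(bg[1], "OUT"), bg, pw), "subset")
})

test_that("ORA exactness holds across random instances and BH is monotone", {
  withr::with_seed(73, {
    for (rep in 1:20) {
      n_bg <- sample(30:500, 1)
      bg <- sprintf("G%04d", seq_len(n_bg))
      pws <- lapply(1:5, function(i) sample(bg, min(sample(5:30, 1), n_bg)))
      names(pws) <- paste0("pw", 1:5)
      query <- sample(bg, sample(10:30, 1))
      res <- ora(query, bg, pws)
      for (i in seq_len(nrow(res))) {
        id <- res$pathway_id[i]
        expect_equal(res$p_value[i],
                     hyper_tail_oracle(res$overlap[i], length(pws[[id]]),
                                       n_bg, length(query)),
                     tolerance = 1e-12)
      }
      ord <- order(res$p_value)
      expect_true(all(diff(res$q_value[ord]) >= -1e-15))  # monotone in p-order
      expect_true(all(res$q_value >= res$p_value - 1e-15))
    }
  })
})
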