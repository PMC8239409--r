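pep_row <- function(peptide, protein, charge, modification, ...) {
  tibble::tibble(peptide = peptide, protein = protein, charge = charge,
                 modification = modification, ...)
}

test_that("consolidation sums charge/modification variants per sample", {
  tbl <- dplyr::bind_rows(
    pep_row("AAA", "P1", 2L, "none", s1 = 100, s2 = NA),
    pep_row("AAA", "P1", 3L, "none", s1 = 40, s2 = NA),
    pep_row("BBB", "P1", 2L, "none", s1 = 7, s2 = 9)
  )
  out <- consolidate_peptides(tbl)
  expect_equal(nrow(out), 2)
  expect_equal(out$s1[out$peptide == "AAA"], 140)
  expect_true(is.na(out$s2[out$peptide == "AAA"]))  # all variants missing
  # single-variant peptide passes through unchanged
  expect_equal(out$s1[out$peptide == "BBB"], 7)
  expect_equal(out$s2[out$peptide == "BBB"], 9)
})

test_that("protein inference applies Occam's razor and the 2-peptide rule", {
  tbl <- dplyr::bind_rows(
    pep_row("a", "P", 2L, "none", s1 = 1),
    pep_row("b", "P", 2L, "none", s1 = 1),
    pep_row("a", "Q", 2L, "none", s1 = 1),
    pep_row("b", "Q", 2L, "none", s1 = 1),
    pep_row("c", "Q", 2L, "none", s1 = 1)
  )
  out <- infer_proteins(consolidate_peptides(tbl))
  # P's evidence {a,b} is a subset of Q's {a,b,c}: P removed, Q keeps all 3
  expect_equal(unique(out$protein), "Q")
  expect_setequal(out$peptide, c("a", "b", "c"))
})

test_that("identical peptide sets keep the lexicographically smaller accession", {
  tbl <- dplyr::bind_rows(
    pep_row("a", "Z9", 2L, "none", s1 = 1),
    pep_row("b", "Z9", 2L, "none", s1 = 1),
    pep_row("a", "A1", 2L, "none", s1 = 1),
    pep_row("b", "A1", 2L, "none", s1 = 1)
  )
  out <- infer_proteins(consolidate_peptides(tbl))
  expect_equal(unique(out$protein), "A1")
})

test_that("shared peptides are dropped and 1-peptide proteins removed", {
  tbl <- dplyr::bind_rows(
    pep_row("a", "P", 2L, "none", s1 = 1),   # shared with Q after inference
    pep_row("b", "P", 2L, "none", s1 = 1),
    pep_row("c", "P", 2L, "none", s1 = 1),
    pep_row("a", "Q", 2L, "none", s1 = 1),
    pep_row("d", "Q", 2L, "none", s1 = 1),
    pep_row("e", "R", 2L, "none", s1 = 1)    # single unique peptide
  )
  out <- infer_proteins(consolidate_peptides(tbl))
  # neither set subsumes the other; shared 'a' ignored; P keeps {b,c};
  # Q falls to {d} alone -> fails the 2-peptide rule; R has 1 peptide
  expect_setequal(unique(out$protein), "P")
  expect_setequal(out$peptide, c("b", "c"))
  # disjoint sets are both retained
  tbl2 <- dplyr::bind_rows(
    pep_row(c("a", "b"), "P", 2L, "none", s1 = 1),
    pep_row(c("c", "d"), "Q", 2L, "none", s1 = 1)
  )
  expect_setequal(unique(infer_proteins(consolidate_peptides(tbl2))$protein),
                  c("P", "Q"))
})

test_that("Hi3 selects top-3 peptides by cross-sample mean and averages them", {
  # peptide cross-sample means 10, 8, 6, 4 -> top three selected
  tbl <- dplyr::bind_rows(
    pep_row("p1", "P", 2L, "none", s1 = 12, s2 = 8),
    pep_row("p2", "P", 2L, "none", s1 = 6,  s2 = 10),
    pep_row("p3", "P", 2L, "none", s1 = 3,  s2 = 9),
    pep_row("p4", "P", 2L, "none", s1 = 4,  s2 = 4)
  )
  out <- hi3_quantify(consolidate_peptides(tbl))
  expect_equal(out$s1, log2((12 + 6 + 3) / 3), tolerance = 1e-12)
  expect_equal(round(out$s1, 6), 2.807355)
  expect_equal(out$s2, log2((8 + 10 + 9) / 3), tolerance = 1e-12)
  prov <- attr(out, "n_peptides_used")
  expect_equal(prov$n_peptides_used, 3)
})

test_that("Hi3 handles 2-peptide proteins, missing cells and equal values", {
  tbl <- dplyr::bind_rows(
    pep_row("p1", "P", 2L, "none", s1 = 8, s2 = NA),
    pep_row("p2", "P", 2L, "none", s1 = 4, s2 = NA)
  )
  out <- hi3_quantify(consolidate_peptides(tbl))
  expect_equal(out$s1, log2(6))
  expect_true(is.na(out$s2))  # no selected peptide present
  tbl2 <- dplyr::bind_rows(
    pep_row(c("p1", "p2", "p3"), "P", 2L, "none", s1 = 16)
  )
  expect_equal(hi3_quantify(consolidate_peptides(tbl2))$s1, 4)
})

test_that("quantification is invariant to input row order", {
  des <- generate_biopsy_design(5, 0, 0)
  sim <- generate_protein_profiles(des, c(4), n_background = 2, seed = 21)
  pep <- generate_peptides(sim$matrix, c(3, 6), variant_fraction = 0.5,
                          seed = 22)
  run <- function(p) {
    out <- hi3_quantify(infer_proteins(consolidate_peptides(p)))
    attr(out, "n_peptides_used") <- NULL
    out
  }
  shuffled <- pep[withr::with_seed(1, sample(nrow(pep))), ]
  expect_equal(run(pep), run(shuffled))
})

test_that("Hi3 on noise-free peptides recovers protein profiles up to a constant", {
  des <- generate_biopsy_design(6, 0, 0)
  sim <- generate_protein_profiles(des, c(5), n_background = 3, seed = 23)
  pep <- generate_peptides(sim$matrix, c(4, 7), variant_fraction = 0.4,
                          seed = 24)
  out <- hi3_quantify(infer_proteins(consolidate_peptides(pep)))
  mq <- pm_to_matrix(out)
  mo <- pm_to_matrix(sim$matrix)[rownames(mq), ]
  resid <- mq - mo
  expect_lt(max(abs(resid - rowMeans(resid))), 1e-9)
  # no protein with fewer than 2 contributing peptides
  expect_true(all(attr(out, "n_peptides_used")$n_peptides_used >= 2))
})
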