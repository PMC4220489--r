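des_ac11 <- make_named_library("scLib_AC11")
tmpl <- des_ac11$base
rnd <- des_ac11$positions$label

test_that("positivity scoring uses the strict 3x background rule", {
  expect_true(score_positive(0.9, 0.2))
  expect_false(score_positive(0.6, 0.2)) # boundary is strict
  expect_false(score_positive(0, 0))
  expect_equal(score_positive(c(0.9, 0.6), c(0.2, 0.2)), c(TRUE, FALSE))
  expect_error(score_positive(-1, 0.1))
})

test_that("competition indices are clamped fractions", {
  expect_equal(competition_index(0.05, 1.0), 0.95)
  expect_equal(competition_index(1.0, 1.0), 0)
  expect_equal(competition_index(1.2, 1.0), 0)
  expect_error(competition_index(0.5, 0), "positive")
})

test_that("architecture classification recognizes the deletion classes", {
  base <- scaffold_sequence(tmpl, FALSE)
  expect_equal(classify_architecture(base, tmpl, rnd), "intact")
  reg <- scaffold_registry(tmpl)
  idx_of <- function(seg) reg$residue_index[reg$segment == seg]
  aa <- strsplit(base, "")[[1]]
  no_b <- paste(aa[-c(idx_of("L1"), idx_of("B"))], collapse = "")
  expect_equal(classify_architecture(no_b, tmpl, rnd), "del_helix_B")
  # helix B excised but both linkers retained
  no_b2 <- paste(aa[-idx_of("B")], collapse = "")
  expect_equal(classify_architecture(no_b2, tmpl, rnd), "del_helix_B")
  only_c <- paste(aa[c(idx_of("L2"), idx_of("C"))], collapse = "")
  expect_equal(classify_architecture(only_c, tmpl, rnd), "only_helix_C")
  gap_b <- paste(aa[-idx_of("B")[8:21]], collapse = "")
  expect_equal(classify_architecture(gap_b, tmpl, rnd), "del_two_heptads")
  expect_equal(classify_architecture("", tmpl, rnd), "other")
  expect_equal(classify_architecture("GGSGGS", tmpl, rnd), "other")
})

test_that("classification is idempotent and stable under terminus tags", {
  cl <- sample_clones(des_ac11, 6, seed = 23)
  reg <- scaffold_registry(tmpl)
  idx_b <- reg$residue_index[reg$segment == "B"]
  for (i in seq_len(nrow(cl))) {
    s <- cl$aa_sequence[i]
    k1 <- classify_architecture(s, tmpl, rnd)
    expect_equal(k1, "intact")
    tagged <- paste0("MKYLLPTAAAGLLLLAAQPAMS", s, "AAAHHHHHHQ")
    expect_equal(classify_architecture(tagged, tmpl, rnd), k1)
    aa <- strsplit(s, "")[[1]]
    broken <- paste(aa[-idx_b], collapse = "")
    expect_equal(classify_architecture(broken, tmpl, rnd), "del_helix_B")
    expect_equal(
      classify_architecture(paste0("GSGS", broken, "HHHH"), tmpl, rnd),
      "del_helix_B"
    )
  }
})

test_that("panel summaries partition the panel and count destabilizers", {
  panel <- generate_clone_panel(
    c(intact = 12, del_helix_B = 5, del_two_heptads = 2, only_helix_C = 1),
    des_ac11, seed = 31
  )
  qc <- qc_panel(panel, tmpl, randomized = rnd)
  expect_equal(sum(qc$classes$n), qc$n)
  expect_equal(qc$n, 20L)
  expect_equal(qc$fraction_defective, 8 / 20)
  expect_equal(qc$fraction_defective,
               1 - qc$classes$n[qc$classes$class == "intact"] / qc$n)
  # identical clones collapse to one unique sequence
  mono <- tibble::tibble(id = c("a", "b", "c"),
                         aa_sequence = rep(scaffold_sequence(tmpl, FALSE), 3))
  qc1 <- qc_panel(mono, tmpl, randomized = rnd)
  expect_equal(qc1$fraction_defective, 0)
  expect_equal(qc1$n_unique, 1L)
  # three glycines planted at helix-A randomized positions are reported
  aa <- strsplit(scaffold_sequence(tmpl, FALSE), "")[[1]]
  gly_at <- c("A1c", "A2c", "A3c")
  aa[position_to_residue_index(gly_at, tmpl)] <- "G"
  qc2 <- qc_panel(tibble::tibble(id = "g3", aa_sequence = paste(aa, collapse = "")),
                  tmpl, randomized = rnd)
  expect_equal(sum(qc2$destabilizers$n_gly[qc2$destabilizers$helix == "A"]), 3L)
})

test_that("panel summaries score positivity when ODs are present", {
  panel <- tibble::tibble(
    id = c("p", "n"),
    aa_sequence = rep(scaffold_sequence(tmpl, FALSE), 2),
    od_target = c(1.2, 0.3), od_background = c(0.2, 0.2)
  )
  qc <- qc_panel(panel, tmpl, randomized = rnd)
  expect_equal(qc$clones$positive, c(TRUE, FALSE))
})

test_that("consensus motifs assign classes by quorum", {
  base <- scaffold_sequence(tmpl, FALSE)
  at <- function(s, lab, res) {
    aa <- strsplit(s, "")[[1]]
    aa[position_to_residue_index(lab, tmpl)] <- res
    paste(aa, collapse = "")
  }
  clones <- c(at(base, "A2g", "M"), at(base, "A2g", "I"), at(base, "A2g", "V"))
  m <- consensus_motif(clones, "A2g", tmpl)
  expect_equal(m$assignments$class, "aliphatic")
  # a single clone returns its own residues' classes exactly
  one <- consensus_motif(at(base, "C3e", "F"), c("C3e", "A3c"), tmpl)
  expect_equal(one$assignments$class, c("aromatic", "small")) # A3c is Ala
  # a 50/50 split stays unassigned at quorum 0.7
  split <- c(at(base, "A3g", "W"), at(base, "A3g", "V"))
  m2 <- consensus_motif(split, "A3g", tmpl)
  expect_true(is.na(m2$assignments$class))
  expect_error(consensus_motif(character(), "A2g", tmpl), "empty")
  expect_error(consensus_motif("SHORT", "A2g", tmpl), "aligned")
})

test_that("a consensus motif feeds straight into a maturation design", {
  base <- scaffold_sequence(tmpl, FALSE)
  aa <- strsplit(base, "")[[1]]
  aa[position_to_residue_index("A2g", tmpl)] <- "M"
  m <- consensus_motif(paste(aa, collapse = ""), "A2g", tmpl)
  mat <- matlib_from_consensus(base, m)
  cl <- sample_clones(mat, 50, seed = 2)
  expect_true(all(cl$A2g %in% c("M", "I", "L", "V")))
})
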