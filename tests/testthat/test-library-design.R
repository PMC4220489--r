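test_that("named library presets carry the designed position counts", {
  ac11 <- make_named_library("scLib_AC11")
  expect_equal(nrow(ac11$positions), 11L)
  expect_equal(sum(ac11$positions$helix == "A"), 6L)
  expect_equal(sum(ac11$positions$helix == "C"), 5L)
  expect_true(all(ac11$positions$letter[ac11$positions$helix == "A"] %in%
                    c("c", "g")))
  expect_true(all(ac11$positions$letter[ac11$positions$helix == "C"] %in%
                    c("b", "e")))
  ac7 <- make_named_library("scLib_AC7")
  expect_equal(nrow(ac7$positions), 7L)
  expect_equal(sum(ac7$positions$helix == "A"), 4L)
  expect_equal(sum(ac7$positions$helix == "C"), 3L)
  c9 <- make_named_library("scLib_C9")
  expect_equal(nrow(c9$positions), 9L)
  expect_true(all(c9$positions$helix == "C"))
  expect_true(all(c9$positions$letter %in% c("b", "c", "f")))
  expect_error(make_named_library("scLib_Z1"), "unknown")
})

test_that("groove census reproduces 11/14 (79%) for the AC groove library", {
  cs <- library_census(make_named_library("scLib_AC11"))
  expect_equal(cs$groove_total, 14L)
  expect_equal(cs$groove_randomized, 11L)
  expect_equal(cs$groove_percent, 79L)
  # an empty randomization scheme covers none of the groove
  des <- make_named_library("scLib_AC11")
  des$positions <- des$positions[0, ]
  cs0 <- library_census(des)
  expect_equal(cs0$groove_randomized, 0L)
  expect_equal(cs0$groove_percent, 0L)
})

test_that("NNK diversity statistics follow the closed forms", {
  ac11 <- make_named_library("scLib_AC11")
  st <- nnk_stats(ac11)
  expect_equal(st$dna_diversity, 32^11)
  expect_equal(st$stop_free_fraction, (31 / 32)^11, tolerance = 1e-12)
  expect_equal(st$stop_free_fraction, 0.7052, tolerance = 1e-3)
  des0 <- ac11
  des0$positions <- des0$positions[0, ]
  st0 <- nnk_stats(des0)
  expect_equal(st0$dna_diversity, 1)
  expect_equal(st0$stop_free_fraction, 1)
  expect_equal(st0$coverage_sample, 1)
  des1 <- ac11
  des1$positions <- des1$positions[1, ]
  st1 <- nnk_stats(des1)
  expect_equal(st1$dna_diversity, 32)
  # coverage bound frozen from ceil(log(0.05)/log(1 - 1/32))
  expect_equal(st1$coverage_sample, 95)
  # monotone decreasing stop-free fraction in k
  sf <- vapply(1:11, function(k) {
    d <- ac11
    d$positions <- d$positions[seq_len(k), ]
    nnk_stats(d)$stop_free_fraction
  }, numeric(1))
  expect_true(all(diff(sf) < 0))
})

test_that("the NNK codon table has 32 codons and one amber stop", {
  tab <- alphabody:::nnk_codon_table()
  expect_equal(nrow(tab), 32L)
  expect_true(all(substr(tab$codon, 3, 3) %in% c("G", "T")))
  expect_equal(tab$codon[tab$aa == "*"], "TAG")
  expect_equal(sum(tab$aa == "L"), 3L)
  expect_equal(sum(tab$aa == "W"), 1L)
})

test_that("clone sampling is deterministic and honours the base grammar", {
  des <- make_named_library("scLib_AC11")
  expect_equal(nrow(sample_clones(des, 0)), 0L)
  a <- sample_clones(des, 100, seed = 11)
  b <- sample_clones(des, 100, seed = 11)
  expect_identical(a, b)
  base <- scaffold_sequence(des$base, FALSE)
  fixed <- setdiff(seq_len(nchar(base)), des$positions$residue_index)
  for (i in c(1, 50, 100)) {
    expect_equal(nchar(a$aa_sequence[i]), nchar(base))
    expect_equal(strsplit(a$aa_sequence[i], "")[[1]][fixed],
                 strsplit(base, "")[[1]][fixed])
  }
})

test_that("sampled residue frequencies converge to NNK codon degeneracies", {
  des <- make_named_library("scLib_AC11")
  cl <- sample_clones(des, 1e4, seed = 202)
  n <- nrow(cl)
  # supE mode: Leu 3/32, Trp 1/32, Gln 1 codon + 1 amber = 2/32
  checks <- c(L = 3 / 32, W = 1 / 32, Q = 2 / 32)
  for (aa in names(checks)) {
    p <- checks[[aa]]
    obs <- mean(cl$A2g == aa)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-12)
  }
  # chi-square goodness of fit against the full per-residue NNK law
  tab <- alphabody:::nnk_codon_table()
  expected <- table(ifelse(tab$aa == "*", "Q", tab$aa)) / 32
  big <- sample_clones(des, 1e5, seed = 303)
  obs <- table(factor(big$C3b, levels = names(expected)))
  gof <- suppressWarnings(chisq.test(obs, p = as.numeric(expected)))
  expect_gt(gof$p.value, 0.01)
})

test_that("strict-stop translation truncates amber clones and flags them", {
  des <- make_named_library("scLib_AC11")
  cl <- sample_clones(des, 4000, seed = 5, translation_mode = "strict_stop")
  expect_equal(mean(cl$truncated), 1 - (31 / 32)^11, tolerance = 0.05)
  expect_true(all(nchar(cl$aa_sequence[cl$truncated]) <
                    nchar(scaffold_sequence(des$base, FALSE))))
  expect_false(any(grepl("\\*", cl$aa_sequence)))
})

test_that("maturation libraries restrict motif positions to their classes", {
  base <- build_named_variant("scRef_L16")
  mat <- matlib_from_consensus(scaffold_sequence(base, FALSE),
                               consensus_motif_classes())
  cl <- sample_clones(mat, 400, seed = 17)
  expect_true(all(cl$A2g %in% c("M", "I", "L", "V")))
  expect_true(all(cl$C3e %in% c("W", "Y", "F")))
  expect_true(all(cl$A3c %in% c("A", "G", "S")))
  # an empty motif leaves the base clone untouched
  empty <- matlib_from_consensus(scaffold_sequence(base, FALSE),
                                 tibble::tibble(label = character(),
                                                class = character()))
  cl0 <- sample_clones(empty, 3, seed = 1)
  expect_true(all(cl0$aa_sequence == scaffold_sequence(base, FALSE)))
  expect_error(
    matlib_from_consensus(scaffold_sequence(base, FALSE),
                          tibble::tibble(label = "A9c", class = "small")),
    "absent"
  )
  expect_equal(scaffold_sequence(make_named_library("matLib")$base, FALSE),
               scaffold_sequence(base, FALSE))
})

test_that("clone FASTA export carries position annotations", {
  des <- make_named_library("scLib_AC7")
  cl <- sample_clones(des, 2, seed = 3)
  tmp <- tempfile(fileext = ".fasta")
  write_clone_fasta(cl, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  expect_true(grepl("A1c=", lines[1]))
  expect_equal(lines[2], cl$aa_sequence[1])
})
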