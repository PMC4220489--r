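strand <- function(chain, x0, n = 8, resname = "ALA") {
  tibble::tibble(element = "C", name = "CA", resno = seq_len(n),
                 resname = resname, chain = chain,
                 x = x0, y = 0, z = seq_len(n) * 3.8, occupancy = 1)
}

test_that("quadrature areas match the analytic sphere within 1%", {
  one <- tibble::tibble(element = "C", name = "CA", resno = 1L,
                        resname = "ALA", chain = "A",
                        x = 0, y = 0, z = 0, occupancy = 1)
  s <- sasa(one)
  expect_equal(s$atoms$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # nitrogen radius differs
  one$element <- "N"
  expect_equal(sasa(one)$atoms$sasa, 4 * pi * (1.55 + 1.4)^2,
               tolerance = 0.01)
  expect_error(sasa(dplyr::mutate(one, element = "XX")), "radius")
})

test_that("degenerate geometries behave: overlap and burial", {
  two <- tibble::tibble(element = "C", name = "CA", resno = 1:2,
                        resname = "ALA", chain = "A",
                        x = 0, y = 0, z = 0, occupancy = 1)
  s <- sasa(two)
  expect_equal(sum(s$atoms$sasa), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # an atom caged inside a dense cluster is fully buried
  dirs <- as.matrix(expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1),
                                z = c(-1, 0, 1)))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  cage <- tibble::tibble(element = "C", name = "CA",
                         resno = seq_len(nrow(dirs)) + 1L, resname = "ALA",
                         chain = "A", x = 2.2 * dirs[, 1],
                         y = 2.2 * dirs[, 2], z = 2.2 * dirs[, 3],
                         occupancy = 1)
  caged <- dplyr::bind_rows(
    tibble::tibble(element = "C", name = "CA", resno = 1L, resname = "ALA",
                   chain = "A", x = 0, y = 0, z = 0, occupancy = 1), cage)
  s2 <- sasa(caged)
  expect_lt(s2$atoms$sasa[1], 1)
})

test_that("Fibonacci quadrature agrees with an independent grid oracle", {
  set.seed(7)
  cluster <- tibble::tibble(
    element = sample(c("C", "N", "O"), 12, replace = TRUE),
    name = "X", resno = 1:12, resname = "ALA", chain = "A",
    x = runif(12, 0, 8), y = runif(12, 0, 8), z = runif(12, 0, 8),
    occupancy = 1
  )
  mine <- sasa(cluster)$atoms$sasa
  oracle <- grid_asa(cluster)
  expect_lt(sum(abs(mine - oracle)) / sum(oracle), 0.02)
  # refining the quadrature barely moves the answer
  fine <- sasa(cluster, n_sphere_points = 4000)$atoms$sasa
  expect_lt(max(abs(sum(mine) - sum(fine))) / sum(fine), 0.005)
})

test_that("interface buried areas are additive and vanish when separated", {
  at <- dplyr::bind_rows(strand("A", 0), strand("B", 5))
  rep1 <- interface_report(at, "A", "B")
  s1 <- sum(sasa(at[at$chain == "A", ])$residues$sasa)
  s2 <- sum(sasa(at[at$chain == "B", ])$residues$sasa)
  sc <- sum(sasa(at)$residues$sasa)
  expect_equal(sum(rep1$summary$buried_area), s1 + s2 - sc, tolerance = 1e-9)
  expect_true(all(rep1$summary$buried_area > 0))
  far <- dplyr::bind_rows(strand("A", 0), strand("B", 60))
  rep2 <- interface_report(far, "A", "B")
  expect_equal(sum(rep2$summary$buried_area), 0)
  expect_equal(sum(rep2$summary$n_interface_residues), 0L)
  expect_equal(nrow(rep2$hbonds), 0L)
  expect_error(interface_report(at, "A", "Z"), "empty side")
})

test_that("interface areas and contacts are rigid-motion invariant", {
  at <- dplyr::bind_rows(strand("A", 0), strand("B", 5))
  rep1 <- interface_report(at, "A", "B")
  moved <- apply_rigid_motion(at, seed = 3)
  rep2 <- interface_report(moved, "A", "B")
  # areas are invariant up to quadrature noise (fixed lab-frame lattice)
  expect_equal(rep2$summary$buried_area, rep1$summary$buried_area,
               tolerance = 0.05)
  expect_equal(rep2$residues$interface, rep1$residues$interface)
  expect_equal(nrow(rep2$hbonds), nrow(rep1$hbonds))
  # at a finer quadrature the residual drops well under 1%
  rep1f <- interface_report(at, "A", "B", n_sphere_points = 4000)
  rep2f <- interface_report(moved, "A", "B", n_sphere_points = 4000)
  expect_equal(rep2f$summary$buried_area, rep1f$summary$buried_area,
               tolerance = 0.01)
})

test_that("polar contacts across the interface are detected", {
  atoms <- synthetic_complex_atoms()
  rep <- interface_report(atoms, "M", "P")
  # Gln13 NE2 (M) to Ser60 O (P) at 3.0 A
  expect_true(any(rep$hbonds$resno_1 == 13 & rep$hbonds$resno_2 == 60))
  expect_true(all(rep$hbonds$distance <= 3.5))
  # Lys20 NZ (M) to Glu50 OE1 (P) at 3.4 A
  expect_true(any(rep$salt_bridges$resno_pos == 20 &
                    rep$salt_bridges$resno_neg == 50))
})

test_that("epitope checks report the synthetic complex's binding mode", {
  atoms <- synthetic_complex_atoms()
  rep <- interface_report(atoms, "M", "P")
  checks <- epitope_checks(rep, atoms, scaffold_chain = "M",
                           target_chain = "P")
  byname <- setNames(checks$pass, checks$check)
  expect_true(byname[["trp_ile_contact"]])
  expect_true(byname[["tyr_buried_majority"]])
  expect_true(byname[["helix_b_interface_residues"]])
  counts <- setNames(checks$value, checks$check)
  expect_gte(counts[["n_hbonds"]], 1)
  expect_gte(counts[["n_salt_bridges"]], 1)
  # moving the scaffold far away falsifies the contact checks
  moved <- atoms
  moved$x[moved$chain == "M"] <- moved$x[moved$chain == "M"] + 500
  rep_far <- interface_report(moved, "M", "P")
  far <- epitope_checks(rep_far, moved, "M", "P")
  expect_false(setNames(far$pass, far$check)[["trp_ile_contact"]])
  # absent residues are reported as not evaluable
  noile <- atoms[!(atoms$chain == "M" & atoms$resno == 106), ]
  rep3 <- interface_report(noile, "M", "P")
  ne <- epitope_checks(rep3, noile, "M", "P")
  expect_true(is.na(setNames(ne$pass, ne$check)[["trp_ile_contact"]]))
})

test_that("structure reading filters waters, hetero atoms and altlocs", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   2       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   2       1.500   0.000   0.000  0.60  0.00           C",
    "ATOM      4  O   ALA A   3       2.000   0.000   0.000  1.00  0.00           O",
    "HETATM    5 ZN    ZN A  90       8.000   0.000   0.000  1.00  0.00          ZN",
    "HETATM    6  O   HOH A  99       9.000   0.000   0.000  1.00  0.00           O",
    "END"
  )
  tmp <- tempfile(fileext = ".pdb")
  writeLines(pdb, tmp)
  at <- read_structure(tmp)
  expect_equal(nrow(at), 3L)
  expect_equal(at$x[at$resno == 2], 1.5) # highest-occupancy altloc wins
  expect_false(any(at$resname %in% c("HOH", "ZN")))
  expect_error(read_structure(tempfile()), "cannot parse")
})

test_that("interface tidiers summarise per side", {
  at <- dplyr::bind_rows(strand("A", 0), strand("B", 5))
  rep <- interface_report(at, "A", "B")
  gl <- glance(rep)
  expect_equal(gl$n_hbonds, nrow(rep$hbonds))
  expect_true(all(c("buried_area_side1", "buried_area_side2") %in% names(gl)))
  td <- tidy(rep)
  expect_true(all(c("delta_asa", "interface") %in% names(td)))
})
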