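# Protein-protein interface analysis: solvent-accessible surface areas
# (Shrake-Rupley quadrature), per-side buried areas, interface residues,
# hydrogen bonds and salt bridges of a two-group complex.

# united-atom van der Waals radii, element-keyed (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90)

#' Read a structure into an atom table
#'
#' Thin wrapper over `bio3d::read.pdb()`/`read.cif()`. Hetero atoms and
#' waters are excluded by default; alternate locations are resolved to the
#' highest-occupancy conformer.
#'
#' @param path PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keep_hetero Keep HETATM records (waters are always dropped).
#' @return Tibble with one row per atom: `element`, `name`, `resno`,
#'   `resname`, `chain`, `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_hetero = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE)
    ),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms retained from '", path, "'", call. = FALSE)
  # resolve altlocs: keep the highest-occupancy conformer per atom
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  keep <- !duplicated(key[order(-occ)])[order(order(-occ))]
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem)) {
    # fall back on the first letter of the atom name
    elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
  }
  tibble(
    element = toupper(elem), name = at$elety, resno = at$resno,
    resname = at$resid, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
}

# deterministic quasi-uniform sphere points (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atom set using a deterministic
#' quasi-uniform quadrature on each atom's expanded sphere. For an
#' isolated atom the result converges to the analytic
#' `4 pi (r + probe)^2` to well under 1% at the default point count.
#'
#' @param atoms Atom tibble (needs `element`, `resno`, `chain`, `x`, `y`,
#'   `z`; typically from [read_structure()]).
#' @param probe_radius Probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Quadrature points per atom (default 960).
#' @param radii Named van der Waals radius table, Angstrom.
#' @return List with `atoms` (input + `radius` + `sasa`) and `residues`
#'   (per chain/residue summed areas).
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_sphere_points = 960,
                 radii = VDW_RADII) {
  stopifnot(all(c("element", "resno", "chain", "x", "y", "z") %in% names(atoms)))
  r <- radii[atoms$element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "),
         call. = FALSE)
  }
  r <- unname(r) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  areas <- numeric(n)
  max_r <- max(r)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r[i] + max_r)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    # exact duplicates: the first atom keeps its surface, later copies are
    # shadowed (total area of k coincident spheres = one sphere)
    nb <- nb[!(d2[nb] < 1e-12 & r[nb] == r[i] & nb > i)]
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > r[j]^2 + 1e-9
    }
    areas[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  out <- as_tibble(atoms)
  out$radius <- r - probe_radius
  out$sasa <- areas
  residues <- out |>
    group_by(.data$chain, .data$resno) |>
    summarise(resname = .data$resname[1], sasa = sum(.data$sasa),
              .groups = "drop")
  list(atoms = out, residues = residues)
}

HBOND_ELEMENTS <- c("N", "O")
SB_POSITIVE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
SB_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

cross_group_pairs <- function(a1, a2, cutoff) {
  if (nrow(a1) == 0L || nrow(a2) == 0L) {
    return(tibble(i = integer(), j = integer(), distance = numeric()))
  }
  m1 <- as.matrix(a1[, c("x", "y", "z")])
  m2 <- as.matrix(a2[, c("x", "y", "z")])
  rows <- list()
  for (i in seq_len(nrow(m1))) {
    d <- sqrt(colSums((t(m2) - m1[i, ])^2))
    hit <- which(d <= cutoff)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- tibble(i = i, j = hit, distance = d[hit])
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(i = integer(), j = integer(), distance = numeric())
}

#' Interface report for a two-group complex
#'
#' Computes solvent accessibility for the complex and for each isolated
#' side; the per-residue accessibility difference (dASA) gives the buried
#' area per side, the interface residue lists (dASA above a small cutoff
#' that suppresses quadrature noise) and the buried fraction of each
#' side's free surface. Polar contacts: hydrogen bonds as N/O--N/O pairs
#' across the interface within 3.5 Angstrom (distance-only criterion:
#' deposited models carry no hydrogens), salt bridges as Lys/Arg/His
#' side-chain N to Asp/Glu carboxylate O within 4.0 Angstrom.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param side1_chains,side2_chains Chain identifiers of the two sides
#'   (disjoint, non-empty).
#' @param probe_radius,n_sphere_points Passed to [sasa()].
#' @param delta_cutoff Minimum per-residue dASA (Angstrom^2) to count as
#'   interface (default 0.1).
#' @param hbond_max,salt_bridge_max Distance cutoffs, Angstrom.
#' @return List of class `ab_interface`: `summary` (per-side tibble with
#'   `buried_area`, `n_interface_residues`, `interface_fraction`),
#'   `residues` (per-residue dASA), `hbonds`, `salt_bridges`.
#' @export
interface_report <- function(atoms, side1_chains, side2_chains,
                             probe_radius = 1.4, n_sphere_points = 960,
                             delta_cutoff = 0.1, hbond_max = 3.5,
                             salt_bridge_max = 4.0) {
  stopifnot(length(side1_chains) >= 1, length(side2_chains) >= 1,
            length(intersect(side1_chains, side2_chains)) == 0)
  a1 <- atoms[atoms$chain %in% side1_chains, , drop = FALSE]
  a2 <- atoms[atoms$chain %in% side2_chains, , drop = FALSE]
  if (nrow(a1) == 0L || nrow(a2) == 0L) {
    stop("empty side: no atoms in one of the chain groups", call. = FALSE)
  }
  both <- bind_rows(a1, a2)
  s_complex <- sasa(both, probe_radius, n_sphere_points)$residues
  s1 <- sasa(a1, probe_radius, n_sphere_points)$residues
  s2 <- sasa(a2, probe_radius, n_sphere_points)$residues
  s1$side <- "side1"
  s2$side <- "side2"
  free <- bind_rows(s1, s2)
  free$sasa_complex <- s_complex$sasa[match(paste(free$chain, free$resno),
                                            paste(s_complex$chain, s_complex$resno))]
  free$delta_asa <- free$sasa - free$sasa_complex
  residues <- free |>
    dplyr::rename(sasa_free = "sasa") |>
    mutate(interface = .data$delta_asa > delta_cutoff)
  summary <- residues |>
    group_by(.data$side) |>
    summarise(
      buried_area = sum(.data$delta_asa),
      n_interface_residues = sum(.data$interface),
      total_free_asa = sum(.data$sasa_free),
      interface_fraction = sum(.data$delta_asa) / sum(.data$sasa_free),
      .groups = "drop"
    )
  # polar contacts across the interface
  po1 <- a1[a1$element %in% HBOND_ELEMENTS, , drop = FALSE]
  po2 <- a2[a2$element %in% HBOND_ELEMENTS, , drop = FALSE]
  hb <- cross_group_pairs(po1, po2, hbond_max)
  hbonds <- tibble(
    chain_1 = po1$chain[hb$i], resno_1 = po1$resno[hb$i],
    resname_1 = po1$resname[hb$i], atom_1 = po1$name[hb$i],
    chain_2 = po2$chain[hb$j], resno_2 = po2$resno[hb$j],
    resname_2 = po2$resname[hb$j], atom_2 = po2$name[hb$j],
    distance = hb$distance
  )
  sb_sel <- function(a, table) {
    keep <- rep(FALSE, nrow(a))
    for (rn in names(table)) {
      keep <- keep | (a$resname == rn & a$name %in% table[[rn]])
    }
    a[keep, , drop = FALSE]
  }
  sb_rows <- list()
  for (dir in 1:2) {
    pos <- sb_sel(if (dir == 1) a1 else a2, SB_POSITIVE)
    neg <- sb_sel(if (dir == 1) a2 else a1, SB_NEGATIVE)
    pr <- cross_group_pairs(pos, neg, salt_bridge_max)
    if (nrow(pr)) {
      sb_rows[[dir]] <- tibble(
        chain_pos = pos$chain[pr$i], resno_pos = pos$resno[pr$i],
        resname_pos = pos$resname[pr$i], atom_pos = pos$name[pr$i],
        chain_neg = neg$chain[pr$j], resno_neg = neg$resno[pr$j],
        resname_neg = neg$resname[pr$j], atom_neg = neg$name[pr$j],
        distance = pr$distance
      )
    }
  }
  salt_bridges <- if (length(sb_rows)) bind_rows(sb_rows) else
    tibble(chain_pos = character(), resno_pos = integer(),
           resname_pos = character(), atom_pos = character(),
           chain_neg = character(), resno_neg = integer(),
           resname_neg = character(), atom_neg = character(),
           distance = numeric())
  # one salt bridge per residue pair
  if (nrow(salt_bridges)) {
    salt_bridges <- salt_bridges |>
      group_by(.data$chain_pos, .data$resno_pos, .data$chain_neg,
               .data$resno_neg) |>
      dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  structure(list(summary = summary, residues = residues, hbonds = hbonds,
                 salt_bridges = salt_bridges,
                 side1_chains = side1_chains, side2_chains = side2_chains),
            class = "ab_interface")
}

#' @export
print.ab_interface <- function(x, ...) {
  cat("<interface report> side1 = {",
      paste(x$side1_chains, collapse = ","), "}, side2 = {",
      paste(x$side2_chains, collapse = ","), "}\n", sep = "")
  print(x$summary)
  cat(nrow(x$hbonds), " hydrogen bond(s), ", nrow(x$salt_bridges),
      " salt bridge(s)\n", sep = "")
  invisible(x)
}

min_residue_distance <- function(atoms, chain_a, resno_a, chain_b, resno_b) {
  a <- atoms[atoms$chain == chain_a & atoms$resno == resno_a, , drop = FALSE]
  b <- atoms[atoms$chain == chain_b & atoms$resno == resno_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) return(NA_real_)
  ma <- as.matrix(a[, c("x", "y", "z")])
  mb <- as.matrix(b[, c("x", "y", "z")])
  min(vapply(seq_len(nrow(ma)), function(i) {
    min(sqrt(colSums((t(mb) - ma[i, ])^2)))
  }, numeric(1)))
}

#' Named epitope checks on a scaffold:target complex
#'
#' Boolean assertions about the binding mode of a triple-helix scaffold
#' bound to the p19 subunit: (1) the target's hotspot tryptophan packs
#' against the scaffold's core isoleucine (any-atom distance within
#' `contact_max`); (2) the scaffold's conserved tyrosine buries more than
#' half of its free surface; (3) helix B contributes no interface
#' residues; (4) the interface hydrogen-bond and salt-bridge counts, for
#' comparison against the reported five bonds and two bridges. Residues
#' absent from the model make a check not-evaluable (`NA`).
#'
#' @param report `ab_interface` from [interface_report()] where side1 is
#'   the scaffold.
#' @param atoms Atom tibble the report was computed on.
#' @param scaffold_chain,target_chain Chain ids of the scaffold and the
#'   p19-equivalent target chain.
#' @param trp_resno Hotspot tryptophan residue number on the target
#'   (numbering offset already applied; default 156).
#' @param ile_resno Core isoleucine on the scaffold (default 106).
#' @param tyr_resno Conserved tyrosine on the scaffold (default 110).
#' @param helix_b_range Integer range of helix-B residue numbers on the
#'   scaffold chain.
#' @param contact_max Contact distance cutoff, Angstrom (default 4.5).
#' @return Tibble `check`, `value`, `pass` (logical, `NA` when not
#'   evaluable).
#' @export
epitope_checks <- function(report, atoms, scaffold_chain, target_chain,
                           trp_resno = 156, ile_resno = 106, tyr_resno = 110,
                           helix_b_range = 45:69, contact_max = 4.5) {
  stopifnot(inherits(report, "ab_interface"))
  d <- min_residue_distance(atoms, target_chain, trp_resno,
                            scaffold_chain, ile_resno)
  trp_contact <- if (is.na(d)) NA else d <= contact_max
  res <- report$residues
  tyr <- res[res$chain == scaffold_chain & res$resno == tyr_resno, ]
  tyr_buried <- if (nrow(tyr) == 0L) NA else
    tyr$delta_asa[1] > 0.5 * tyr$sasa_free[1]
  iface_b <- sum(res$chain == scaffold_chain & res$interface &
                   res$resno %in% helix_b_range)
  tibble(
    check = c("trp_ile_contact", "tyr_buried_majority",
              "helix_b_interface_residues", "n_hbonds", "n_salt_bridges"),
    value = c(d, if (nrow(tyr)) tyr$delta_asa[1] / tyr$sasa_free[1] else NA,
              iface_b, nrow(report$hbonds), nrow(report$salt_bridges)),
    pass = c(trp_contact, tyr_buried, iface_b == 0, NA, NA)
  )
}
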