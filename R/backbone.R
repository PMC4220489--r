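# Idealized coiled-coil backbones (Crick-style parameterization) and
# knobs-into-holes core-packing detection. Only Calpha traces are built:
# the geometry is used for self-consistent topology checks, not modelling.

#' Crick-style parameters for an idealized three-helix bundle
#'
#' @param R0 Superhelix radius in Angstrom (axis of each helix sits at R0
#'   from the bundle axis; default 6.5).
#' @param R1 Helix radius in Angstrom (Calpha distance from the local helix
#'   axis; default 2.26).
#' @param omega1 Local helical twist in degrees per residue. The default
#'   720/7 (~102.86) makes the heptad repeat exactly periodic around the
#'   bundle so a/d positions keep facing the core.
#' @param omega0 Superhelical twist in degrees per residue (default 0:
#'   straight helix axes; a small negative value gives the left-handed
#'   supercoil).
#' @param rise Axial rise per residue in Angstrom (default 1.5).
#' @param phase_offset Degrees by which the core-facing direction sits
#'   between the a and d positions (default 720/7/4 ~ 25.7).
#' @param topology `"parallel"` or `"antiparallel_up_down_up"` (helix B
#'   runs opposite to A and C).
#' @return A list of class `ab_crick`.
#' @export
crick_params <- function(R0 = 6.5, R1 = 2.26, omega1 = 720 / 7, omega0 = 0,
                         rise = 1.5, phase_offset = 720 / 28,
                         topology = c("antiparallel_up_down_up", "parallel")) {
  topology <- match.arg(topology)
  if (R0 <= 0 || R1 <= 0 || rise <= 0) {
    stop("Crick radii and rise must be positive", call. = FALSE)
  }
  structure(
    list(R0 = R0, R1 = R1, omega1 = omega1, omega0 = omega0, rise = rise,
         phase_offset = phase_offset, topology = topology),
    class = "ab_crick"
  )
}

#' Build an idealized Calpha backbone for a scaffold
#'
#' Places the three helices on a common bundle axis 120 degrees apart, each
#' as an ideal alpha-helix around its own axis; in the antiparallel
#' up-down-up topology helix B runs in the opposite axial direction. The
#' per-helix phase is chosen so that the midpoint between the a and d core
#' positions faces the bundle axis, the standard core orientation of a
#' coiled coil. Linker residues are not modelled (they are disordered in
#' solved structures). Deterministic for fixed parameters.
#'
#' @param spec `ab_scaffold` specification.
#' @param params `ab_crick` parameters.
#' @return Tibble with one row per helix residue: `helix`, `residue_index`
#'   (within helix), `aa`, `heptad`, `letter`, `label`, `x`, `y`, `z`.
#' @export
build_ideal_backbone <- function(spec, params = crick_params()) {
  stopifnot(inherits(spec, "ab_scaffold"), inherits(params, "ab_crick"))
  phis <- c(A = 0, B = 120, C = 240) * pi / 180
  n <- nchar(spec$helices$A$sequence)
  zmax <- (n - 1L) * params$rise
  rows <- lapply(HELIX_IDS, function(h) {
    reg <- assign_registry(spec$helices[[h]]$sequence,
                           start_letter = spec$helices[[h]]$start_letter,
                           helix = h)
    nh <- nrow(reg)
    i <- seq_len(nh) - 1L
    dir <- if (params$topology == "antiparallel_up_down_up" && h == "B") -1 else 1
    # helix axis position (straight for omega0 = 0, supercoiled otherwise)
    theta <- phis[[h]] + dir * params$omega0 * pi / 180 * i
    ax <- params$R0 * cos(theta)
    ay <- params$R0 * sin(theta)
    z <- if (dir > 0) params$rise * i else zmax - params$rise * i
    # phase: midpoint of a (i=0) and d (i=3) points at the bundle axis
    inward <- theta + pi
    alpha <- inward + dir * params$phase_offset * pi / 180 +
      dir * params$omega1 * pi / 180 * i
    tibble(
      helix = h, residue_index = reg$residue_index, aa = reg$aa,
      heptad = reg$heptad, letter = reg$letter, label = reg$label,
      x = ax + params$R1 * cos(alpha),
      y = ay + params$R1 * sin(alpha),
      z = z,
      axis_x = ax, axis_y = ay
    )
  })
  bind_rows(rows)
}

side_chain_proxy <- function(backbone, extension = 1.5) {
  # push each Calpha 'extension' Angstrom further out radially from its
  # helix's least-squares axis line: a crude side-chain centroid for
  # packing checks that depends only on the coordinates (so the detector
  # is invariant under rigid motions of the whole bundle)
  out <- matrix(NA_real_, nrow(backbone), 3)
  for (h in unique(backbone$helix)) {
    sel <- which(backbone$helix == h)
    m <- as.matrix(backbone[sel, c("x", "y", "z")])
    ctr <- colMeans(m)
    v <- stats::prcomp(m, center = TRUE)$rotation[, 1]
    cm <- sweep(m, 2, ctr)
    foot <- (cm %*% v) %*% t(v) # projection onto the axis line
    radial <- cm - foot
    rl <- sqrt(rowSums(radial^2))
    out[sel, ] <- m + radial * (extension / rl)
  }
  colnames(out) <- c("px", "py", "pz")
  as_tibble(out)
}

#' Detect knobs-into-holes core packing
#'
#' A residue is reported as a knob when its side-chain proxy point (the
#' Calpha pushed 1.5 Angstrom further out from its local helix axis, a
#' crude side-chain centroid) lies within `cutoff` of the proxy points of
#' at least `min_contacts` residues of one other helix (the hole), the
#' SOCKET criterion applied to centroids on both sides. Knobs are grouped
#' into core layers by axial coordinate. In
#' the antiparallel up-down-up fold the a/d knobs of helix B share layers
#' with d/a residues of the parallel helices A and C.
#'
#' @param backbone Tibble from [build_ideal_backbone()] (or any table with
#'   the same columns).
#' @param cutoff Knob-to-hole Calpha distance cutoff in Angstrom
#'   (default 7.4, SOCKET-like).
#' @param min_contacts Minimum hole residues on one helix (default 4).
#' @param layer_gap Axial gap in Angstrom that separates core layers
#'   (default 2.0).
#' @return A list of class `ab_kih` with `knobs` (tibble: knob residue,
#'   hole helix, contact count, layer id, z) and `layers` (tibble: layer id,
#'   z midpoint, participating labels).
#' @export
detect_knobs_into_holes <- function(backbone, cutoff = 7.4, min_contacts = 4,
                                    layer_gap = 2.0) {
  need <- c("helix", "residue_index", "aa", "letter", "label", "x", "y", "z")
  if (!all(need %in% names(backbone)) || anyNA(backbone$x)) {
    stop("backbone must provide coordinates for all helix residues",
         call. = FALSE)
  }
  prox <- side_chain_proxy(backbone)
  pm <- as.matrix(prox)
  knob_rows <- list()
  for (i in seq_len(nrow(backbone))) {
    p <- pm[i, ]
    for (h in setdiff(unique(backbone$helix), backbone$helix[i])) {
      j <- which(backbone$helix == h)
      d <- sqrt(colSums((t(pm[j, , drop = FALSE]) - p)^2))
      nc <- sum(d <= cutoff)
      if (nc >= min_contacts) {
        knob_rows[[length(knob_rows) + 1L]] <- tibble(
          helix = backbone$helix[i], residue_index = backbone$residue_index[i],
          aa = backbone$aa[i], letter = backbone$letter[i],
          label = backbone$label[i], hole_helix = h, n_contacts = nc,
          z = backbone$z[i]
        )
      }
    }
  }
  knobs <- if (length(knob_rows)) bind_rows(knob_rows) else
    tibble(helix = character(), residue_index = integer(), aa = character(),
           letter = character(), label = character(), hole_helix = character(),
           n_contacts = integer(), z = numeric())
  # group knobs into layers by axial coordinate
  if (nrow(knobs)) {
    zs <- sort(unique(round(knobs$z, 6)))
    layer_of_z <- cumsum(c(1, diff(zs) > layer_gap))
    knobs$layer <- layer_of_z[match(round(knobs$z, 6), zs)]
    layers <- knobs |>
      group_by(.data$layer) |>
      summarise(z_mid = mean(.data$z),
                members = paste(sort(unique(.data$label)), collapse = ","),
                n_knobs = dplyr::n(), .groups = "drop")
  } else {
    knobs$layer <- integer()
    layers <- tibble(layer = integer(), z_mid = numeric(),
                     members = character(), n_knobs = integer())
  }
  structure(list(knobs = knobs, layers = layers,
                 cutoff = cutoff, min_contacts = min_contacts),
            class = "ab_kih")
}

#' @export
print.ab_kih <- function(x, ...) {
  cat("<knobs-into-holes report> ", nrow(x$knobs), " knob contacts in ",
      nrow(x$layers), " core layers (cutoff ", x$cutoff, " A, >= ",
      x$min_contacts, " hole contacts)\n", sep = "")
  invisible(x)
}

#' Per-helix axis orientation and pairwise topology classification
#'
#' Fits a least-squares line (first principal component) through each
#' helix's Calpha positions, oriented N- to C-terminus; helix pairs with a
#' negative axis dot product are classified antiparallel. Invariant under
#' rigid rotation/translation of the coordinates.
#'
#' @param backbone Tibble with `helix`, `x`, `y`, `z` (>= 4 residues per
#'   helix).
#' @return List with `axes` (tibble: helix, unit axis components) and
#'   `pairs` (tibble: helix_1, helix_2, dot, orientation).
#' @export
helix_orientation <- function(backbone) {
  helices <- unique(backbone$helix)
  axes <- lapply(helices, function(h) {
    m <- as.matrix(backbone[backbone$helix == h, c("x", "y", "z")])
    if (nrow(m) < 4L) stop("need >= 4 residues per helix", call. = FALSE)
    pc <- stats::prcomp(m, center = TRUE)
    v <- pc$rotation[, 1]
    if (pc$sdev[1] < 1e-8) stop("degenerate helix coordinates", call. = FALSE)
    if (sum((m[nrow(m), ] - m[1, ]) * v) < 0) v <- -v # orient N -> C
    tibble(helix = h, ax = v[1], ay = v[2], az = v[3])
  })
  axes <- bind_rows(axes)
  cmb <- utils::combn(seq_len(nrow(axes)), 2)
  pairs <- tibble(
    helix_1 = axes$helix[cmb[1, ]],
    helix_2 = axes$helix[cmb[2, ]],
    dot = axes$ax[cmb[1, ]] * axes$ax[cmb[2, ]] +
      axes$ay[cmb[1, ]] * axes$ay[cmb[2, ]] +
      axes$az[cmb[1, ]] * axes$az[cmb[2, ]]
  )
  pairs$orientation <- ifelse(pairs$dot < 0, "antiparallel", "parallel")
  list(axes = axes, pairs = pairs)
}

#' Write a Calpha-only backbone as PDB
#'
#' Chain identifiers follow the helix names A/B/C; linkers are absent.
#'
#' @param backbone Tibble from [build_ideal_backbone()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(backbone, path) {
  n <- nrow(backbone)
  resn <- bio3d::aa123(backbone$aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), resn, backbone$helix, backbone$residue_index,
    backbone$x, backbone$y, backbone$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
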