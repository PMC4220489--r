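# Clone quality control: ELISA positivity, antibody-competition indices,
# deletion-architecture classification, panel summaries and consensus
# binding motifs.

#' ELISA positivity call
#'
#' A clone is positive when its target-well OD strictly exceeds three times
#' the background OD.
#'
#' @param od_target,od_background Non-negative optical densities
#'   (vectorized).
#' @return Logical vector.
#' @export
score_positive <- function(od_target, od_background) {
  stopifnot(all(od_target >= 0), all(od_background >= 0))
  od_target > 3 * od_background
}

#' Competition index against a blocking antibody
#'
#' Fractional loss of signal when a competing (neutralizing) antibody is
#' present: 1 - OD_with/OD_without, clamped to [0, 1]. Values near 1 mean
#' the clone's epitope overlaps the antibody's.
#'
#' @param od_with OD with competitor present.
#' @param od_without OD without competitor (> 0).
#' @return Fraction in [0, 1].
#' @export
competition_index <- function(od_with, od_without) {
  if (any(od_without <= 0)) {
    stop("od_without must be positive", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - od_with / od_without))
}

# Best ungapped-window identity of a template segment inside a clone
# sequence, computed only over the segment's fixed (non-randomized)
# positions. Returns the maximum identity and the offset achieving it.
segment_identity <- function(clone_aa, segment_aa, fixed_mask) {
  n_seg <- length(segment_aa)
  n_clone <- length(clone_aa)
  if (n_clone < n_seg || sum(fixed_mask) == 0) {
    return(list(identity = 0, offset = NA_integer_))
  }
  best <- 0
  best_off <- NA_integer_
  fixed_idx <- which(fixed_mask)
  seg_fixed <- segment_aa[fixed_idx]
  for (off in 0:(n_clone - n_seg)) {
    ident <- mean(clone_aa[off + fixed_idx] == seg_fixed)
    if (ident > best) {
      best <- ident
      best_off <- off
    }
  }
  list(identity = best, offset = best_off)
}

helix_segments <- function(template, randomized = character()) {
  reg <- scaffold_registry(template)
  lapply(stats::setNames(HELIX_IDS, HELIX_IDS), function(h) {
    rows <- reg[!is.na(reg$helix) & reg$helix == h, ]
    list(aa = rows$aa, fixed = !(rows$label %in% randomized),
         start = min(rows$residue_index))
  })
}

# variants of a helix segment with a contiguous internal gap of ~two
# heptads (14 +/- 1 residues)
two_heptad_gap_variants <- function(seg, gaps = 13:15) {
  out <- list()
  n <- length(seg$aa)
  for (g in gaps) {
    if (n - g < 4L) next
    for (start in seq_len(n - g + 1L)) {
      keep <- setdiff(seq_len(n), start:(start + g - 1L))
      out[[length(out) + 1L]] <- list(aa = seg$aa[keep], fixed = seg$fixed[keep])
    }
  }
  out
}

# locate up to two non-overlapping linker occurrences (best identity
# first), returning their 0-based offsets sorted left to right
find_linkers <- function(clone_aa, linker_aa, threshold) {
  n_l <- length(linker_aa)
  n_c <- length(clone_aa)
  if (n_c < n_l) return(integer())
  offs <- 0:(n_c - n_l)
  ident <- vapply(offs, function(off) {
    mean(clone_aa[off + seq_len(n_l)] == linker_aa)
  }, numeric(1))
  found <- integer()
  ok <- ident >= threshold
  while (any(ok) && length(found) < 2L) {
    best <- offs[ok][which.max(ident[ok])]
    found <- c(found, best)
    ok <- ok & (offs <= best - n_l | offs >= best + n_l)
  }
  sort(found)
}

region_has <- function(region_aa, seg, threshold) {
  segment_identity(region_aa, seg$aa, seg$fixed)$identity >= threshold
}

region_has_gap_variant <- function(region_aa, seg, threshold) {
  any(vapply(two_heptad_gap_variants(seg), function(v) {
    segment_identity(region_aa, v$aa, v$fixed)$identity >= threshold
  }, logical(1)))
}

#' Classify the deletion architecture of a clone
#'
#' The clone is first segmented at its Gly/Ser linkers (the linkers are
#' never randomized and survive the observed deletion classes), then each
#' resulting region is tested against the positionally corresponding helix
#' template by best ungapped sliding-window identity over the helix's
#' fixed (non-randomized) positions. Classes: `intact` (both linkers, all
#' three helices), `del_two_heptads` (both linkers but one helix carries a
#' contiguous ~14-residue internal gap), `del_helix_B` (one linker joining
#' helices A and C, or an empty middle region), `only_helix_C`, or
#' `other`. Appending non-helix tags at either terminus does not change
#' the call: regions are searched by sliding window.
#'
#' @param clone_seq Clone amino-acid sequence (may include terminus tags).
#' @param template `ab_scaffold` the clone derives from.
#' @param randomized Character vector of randomized position labels to
#'   exclude from identity (e.g. `design$positions$label`).
#' @param threshold Minimum identity over fixed positions to call a
#'   segment present (default 0.8).
#' @return Character scalar, one of the architecture classes.
#' @export
classify_architecture <- function(clone_seq, template, randomized = character(),
                                  threshold = 0.8) {
  stopifnot(inherits(template, "ab_scaffold"))
  aa <- strsplit(clone_seq, "")[[1]]
  if (length(aa) == 0L) return("other")
  segs <- helix_segments(template, randomized)
  linker_aa <- strsplit(template$linkers$L1$full_sequence, "")[[1]]
  n_l <- length(linker_aa)
  linkers <- find_linkers(aa, linker_aa, threshold)

  if (length(linkers) == 2L) {
    rA <- aa[seq_len(linkers[1])]
    rB <- if (linkers[2] > linkers[1] + n_l) {
      aa[(linkers[1] + n_l + 1L):linkers[2]]
    } else character()
    rC <- if (length(aa) > linkers[2] + n_l) {
      aa[(linkers[2] + n_l + 1L):length(aa)]
    } else character()
    okA <- region_has(rA, segs$A, threshold)
    okB <- region_has(rB, segs$B, threshold)
    okC <- region_has(rC, segs$C, threshold)
    if (okA && okB && okC) return("intact")
    gapA <- !okA && region_has_gap_variant(rA, segs$A, threshold)
    gapB <- !okB && region_has_gap_variant(rB, segs$B, threshold)
    gapC <- !okC && region_has_gap_variant(rC, segs$C, threshold)
    if ((okA || gapA) && (okB || gapB) && (okC || gapC) &&
        any(gapA, gapB, gapC)) {
      return("del_two_heptads")
    }
    if (okA && okC && length(rB) == 0L) return("del_helix_B")
    return("other")
  }

  if (length(linkers) == 1L) {
    r1 <- aa[seq_len(linkers[1])]
    r2 <- if (length(aa) > linkers[1] + n_l) {
      aa[(linkers[1] + n_l + 1L):length(aa)]
    } else character()
    okA <- region_has(r1, segs$A, threshold)
    okC <- region_has(r2, segs$C, threshold)
    if (okA && okC) return("del_helix_B")
    if (okC && !okA && !region_has(r1, segs$B, threshold)) {
      return("only_helix_C")
    }
    return("other")
  }

  # no linker left: a bare helix-C remnant or junk
  if (region_has(aa, segs$C, threshold) &&
      length(aa) <= length(segs$C$aa) + 2L * n_l) {
    return("only_helix_C")
  }
  "other"
}

ARCH_CLASSES <- c("intact", "del_two_heptads", "del_helix_B",
                  "only_helix_C", "other")

#' Summarize a clone panel
#'
#' Classifies every clone, tabulates architecture classes, the defective
#' fraction (everything but `intact`), the number of unique sequences, and
#' helix-destabilizer counts (Pro and Gly observed at the randomized
#' positions, split by helix). With protein-level input amber usage is not
#' inferable and is reported as `NA`.
#'
#' @param clones Tibble with at least `id` and `aa_sequence`; optional OD
#'   columns `od_target`, `od_background`, `od_with_competitor`.
#' @param template `ab_scaffold` the panel derives from.
#' @param randomized Randomized position labels of the source design.
#' @param threshold Identity threshold for [classify_architecture()].
#' @return List of class `ab_qc_panel`: `clones` (input + `class` +
#'   positivity if ODs present), `classes` (counts per class), `n`,
#'   `fraction_defective`, `n_unique`, `destabilizers` (per randomized
#'   position Pro/Gly counts among clones where helix A/C was located).
#' @export
qc_panel <- function(clones, template, randomized = character(),
                     threshold = 0.8) {
  stopifnot(nrow(clones) >= 1L, all(c("id", "aa_sequence") %in% names(clones)))
  cl <- as_tibble(clones)
  cl$class <- vapply(cl$aa_sequence, classify_architecture, character(1),
                     template = template, randomized = randomized,
                     threshold = threshold, USE.NAMES = FALSE)
  if (all(c("od_target", "od_background") %in% names(cl))) {
    cl$positive <- score_positive(cl$od_target, cl$od_background)
  }
  counts <- table(factor(cl$class, levels = ARCH_CLASSES))
  classes <- tibble(class = names(counts), n = as.integer(counts))
  n <- nrow(cl)
  destab <- destabilizer_counts(cl, template, randomized, threshold)
  structure(list(
    clones = cl, classes = classes, n = n,
    fraction_defective = sum(cl$class != "intact") / n,
    n_unique = length(unique(cl$aa_sequence)),
    destabilizers = destab,
    amber = NA_integer_ # protein-level input: amber usage not inferable
  ), class = "ab_qc_panel")
}

destabilizer_counts <- function(cl, template, randomized, threshold) {
  if (length(randomized) == 0L) {
    return(tibble(label = character(), helix = character(),
                  n_pro = integer(), n_gly = integer(), n_observed = integer()))
  }
  refs <- parse_position_label(randomized)
  segs <- helix_segments(template, randomized)
  reg <- scaffold_registry(template)
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    h <- refs$helix[i]
    # helix-local offset of the randomized position
    chain_idx <- position_to_residue_index(refs[i, ], template)
    local_idx <- chain_idx - segs[[h]]$start + 1L
    res <- vapply(cl$aa_sequence, function(s) {
      aa <- strsplit(s, "")[[1]]
      hit <- segment_identity(aa, segs[[h]]$aa, segs[[h]]$fixed)
      if (hit$identity >= threshold) aa[hit$offset + local_idx] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    tibble(label = refs$label[i], helix = h,
           n_pro = sum(res == "P", na.rm = TRUE),
           n_gly = sum(res == "G", na.rm = TRUE),
           n_observed = sum(!is.na(res)))
  })
  bind_rows(rows)
}

#' @export
print.ab_qc_panel <- function(x, ...) {
  cat("<clone QC panel> n = ", x$n, ", unique = ", x$n_unique,
      ", defective = ", round(100 * x$fraction_defective), "%\n", sep = "")
  print(x$classes)
  invisible(x)
}

#' Derive a consensus residue-class motif from aligned clones
#'
#' At each queried position the residues of all clones are mapped to the
#' residue classes (aliphatic M/I/L/V, aromatic W/Y/F, small A/G/S); a
#' class is assigned when at least `quorum` of the clones carry one of its
#' members, otherwise the position is left unassigned.
#'
#' @param sequences Character vector of clone sequences, all aligned to the
#'   scaffold grammar (same length as the template's mature sequence).
#' @param positions Position labels (character) or parsed references.
#' @param template `ab_scaffold` defining the grammar.
#' @param quorum Minimum class fraction (default 0.7).
#' @param classes Named list of residue classes.
#' @return An `ab_motif`: list with `assignments` tibble (`label`, `class`,
#'   `members`, `support`) and the inputs.
#' @export
consensus_motif <- function(sequences, positions, template,
                            quorum = 0.7, classes = RESIDUE_CLASSES) {
  if (length(sequences) == 0L) stop("empty clone set", call. = FALSE)
  want <- nchar(scaffold_sequence(template, FALSE))
  if (!all(nchar(sequences) == want)) {
    stop("all clones must be aligned to the scaffold grammar (length ",
         want, ")", call. = FALSE)
  }
  if (is.character(positions)) positions <- parse_position_label(positions)
  idx <- position_to_residue_index(positions, template)
  rows <- lapply(seq_along(idx), function(i) {
    res <- substr(sequences, idx[i], idx[i])
    frac <- vapply(classes, function(mem) mean(res %in% mem), numeric(1))
    best <- which.max(frac)
    assigned <- frac[best] >= quorum
    tibble(
      label = positions$label[i],
      class = if (assigned) names(classes)[best] else NA_character_,
      members = if (assigned) paste(classes[[best]], collapse = "/") else NA_character_,
      support = unname(frac[best])
    )
  })
  structure(list(assignments = bind_rows(rows), quorum = quorum,
                 n_clones = length(sequences)),
            class = "ab_motif")
}

#' @export
print.ab_motif <- function(x, ...) {
  cat("<consensus motif> from ", x$n_clones, " clones (quorum ",
      x$quorum, ")\n", sep = "")
  print(x$assignments)
  invisible(x)
}
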