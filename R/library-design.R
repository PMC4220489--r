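# Phage-display library designs on the triple-helix scaffold: randomization
# schemes, NNK diversity statistics, and synthetic clone sampling.

# NNK degenerate codon: N = A/C/G/T at positions 1-2, K = G/T at position 3.
# 32 codons covering all 20 amino acids with a single stop (amber, TAG).
nnk_codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), c("G", "T"), paste0))
  tibble(codon = codons, aa = unname(Biostrings::GENETIC_CODE[codons]))
}

# residue classes used for consensus motifs and matured-library restriction
RESIDUE_CLASSES <- list(
  aliphatic = c("M", "I", "L", "V"),
  aromatic = c("W", "Y", "F"),
  small = c("A", "G", "S")
)

# terminus presets used on the displayed constructs (leader = first 21
# residues of the pelB signal sequence + Ser, or + Asp for the short
# groove library); generic vs maturation C-terminal tags
PELB21 <- "MKYLLPTAAAGLLLLAAQPAM"
C_TERM_GENERIC <- "TPGGSGGAAAHHHHHHGRAQ"
C_TERM_MATURATION <- "AAAHHHHHHQ" # final Q amber-encoded on the phagemid

new_library_design <- function(name, base, positions, codon_model = "NNK",
                               class_restrictions = list(),
                               n_terminus = "", c_terminus = "") {
  stopifnot(inherits(base, "ab_scaffold"))
  if (anyDuplicated(positions$label)) {
    stop("duplicate randomized positions", call. = FALSE)
  }
  # validates existence on the base scaffold
  positions$residue_index <- position_to_residue_index(positions, base)
  out <- list(
    name = name, base = base, positions = positions,
    codon_model = codon_model, class_restrictions = class_restrictions,
    n_terminus = n_terminus, c_terminus = c_terminus
  )
  class(out) <- "ab_library"
  out
}

#' @export
print.ab_library <- function(x, ...) {
  cat("<ab_library> ", x$name, " on ", x$base$name, "\n", sep = "")
  cat("  randomized positions (", nrow(x$positions), "): ",
      paste(x$positions$label, collapse = " "), "\n", sep = "")
  if (length(x$class_restrictions)) {
    cat("  class-restricted: ",
        paste(names(x$class_restrictions), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Instantiate a named library design
#'
#' Presets: `"scLib_AC11"` (11 NNK positions: six c/g in helix A, five b/e
#' in helix C of the 4-heptad reference scaffold -- the A-C groove
#' library), `"scLib_AC7"` (4 + 3 groove positions on the 3-heptad short
#' scaffold), `"scLib_C9"` (nine b/c/f positions on helix C, the
#' helix-surface library), and `"matLib"` (maturation library:
#' class-restricted randomization at the five consensus-motif positions on
#' the reference grammar, maturation C-terminal tag). The exact position
#' identities within the printed letter/count constraints are package
#' defaults and can be overridden by building a design directly with
#' [matlib_from_consensus()].
#'
#' @param name Preset name.
#' @return An `ab_library` design.
#' @export
make_named_library <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "scLib_AC11") {
    pos <- parse_position_label(c("A1c", "A1g", "A2c", "A2g", "A3c", "A3g",
                                  "C1e", "C2b", "C2e", "C3b", "C3e"))
    return(new_library_design(name, build_named_variant("scRef_L16"), pos,
                              n_terminus = paste0(PELB21, "S"),
                              c_terminus = C_TERM_GENERIC))
  }
  if (name == "scLib_AC7") {
    pos <- parse_position_label(c("A1c", "A1g", "A2c", "A2g",
                                  "C1e", "C2b", "C2e"))
    return(new_library_design(name, build_named_variant("scShort_L16"), pos,
                              n_terminus = paste0(PELB21, "D"),
                              c_terminus = C_TERM_GENERIC))
  }
  if (name == "scLib_C9") {
    pos <- parse_position_label(c("C1b", "C2b", "C3b", "C1c", "C2c", "C3c",
                                  "C1f", "C2f", "C3f"))
    return(new_library_design(name, build_named_variant("scRef_L16"), pos,
                              n_terminus = paste0(PELB21, "S"),
                              c_terminus = C_TERM_GENERIC))
  }
  if (name == "matLib") {
    base <- build_named_variant("scRef_L16")
    motif <- consensus_motif_classes()
    return(matlib_from_consensus(scaffold_sequence(base, FALSE), motif,
                                 base = base, name = "matLib"))
  }
  stop("unknown library preset: ", name, call. = FALSE)
}

#' The five-position consensus binding motif
#'
#' Groove binders selected against IL-23 converge on: A2g aliphatic,
#' A3c small, A3g aromatic, C3b aliphatic, C3e aromatic.
#'
#' @return Tibble with `label` and `class`.
#' @export
consensus_motif_classes <- function() {
  tibble(
    label = c("A2g", "A3c", "A3g", "C3b", "C3e"),
    class = c("aliphatic", "small", "aromatic", "aliphatic", "aromatic")
  )
}

#' Groove census of a library design
#'
#' How much of the A-C groove surface (c/g on helix A, b/e on helix C) the
#' randomization scheme covers. The 11-position groove library randomizes
#' 11 of the 14 groove positions of the reference scaffold (79%).
#'
#' @param design `ab_library` design.
#' @return One-row tibble: `n_randomized`, `groove_total`,
#'   `groove_randomized`, `groove_percent` (rounded to integer).
#' @export
library_census <- function(design) {
  stopifnot(inherits(design, "ab_library"))
  groove <- groove_positions(design$base)
  inter <- intersect(design$positions$label, groove$label)
  tibble(
    library = design$name,
    n_randomized = nrow(design$positions),
    groove_total = nrow(groove),
    groove_randomized = length(inter),
    groove_percent = as.integer(round(100 * length(inter) / nrow(groove)))
  )
}

#' NNK diversity statistics of a design
#'
#' For k fully randomized NNK positions: DNA diversity 32^k, amino-acid
#' upper bound 21^k (20 residues + amber), stop-free fraction (31/32)^k,
#' and the expected library size needed to observe any one given variant
#' with probability `coverage_p` (single-variant coupon bound
#' ceiling(log(1-P)/log(1-32^-k))).
#'
#' @param design `ab_library` design (class-restricted positions are not
#'   counted as NNK).
#' @param coverage_p Target probability for single-variant coverage.
#' @return One-row tibble of diversity statistics.
#' @export
nnk_stats <- function(design, coverage_p = 0.95) {
  stopifnot(inherits(design, "ab_library"))
  k <- sum(!(design$positions$label %in% names(design$class_restrictions)))
  dna <- 32^k
  coverage <- if (k == 0) 1 else ceiling(log1p(-coverage_p) / log1p(-1 / dna))
  tibble(
    library = design$name, n_positions = k,
    dna_diversity = dna, aa_diversity_bound = 21^k,
    stop_free_fraction = (31 / 32)^k,
    coverage_sample = coverage, coverage_p = coverage_p
  )
}

#' Sample synthetic clones from a library design
#'
#' Each clone is the base scaffold sequence with every randomized position
#' redrawn: NNK positions draw a codon uniformly from the 32 NNK codons and
#' translate it; class-restricted positions draw uniformly from the class
#' member set. In `"supE_amber_to_Q"` mode (amber-suppressor host) the TAG
#' codon reads as Gln and is counted in `n_amber`; in `"strict_stop"` mode
#' the sequence is truncated at the first amber and flagged.
#'
#' @param design `ab_library` design.
#' @param n Number of clones (>= 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param translation_mode `"supE_amber_to_Q"` or `"strict_stop"`.
#' @param include_termini Attach the design's terminus presets.
#' @return Tibble: `id`, `aa_sequence`, `source_library`, `n_amber`,
#'   `truncated`, plus one column per randomized position label holding the
#'   sampled residue.
#' @export
sample_clones <- function(design, n, seed = NULL,
                          translation_mode = c("supE_amber_to_Q", "strict_stop"),
                          include_termini = FALSE) {
  stopifnot(inherits(design, "ab_library"), n >= 0)
  translation_mode <- match.arg(translation_mode)
  if (!is.null(seed)) set.seed(seed)
  base_aa <- strsplit(scaffold_sequence(design$base, FALSE), "")[[1]]
  nnk <- nnk_codon_table()
  k <- nrow(design$positions)
  if (n == 0) {
    res <- tibble(id = character(), aa_sequence = character(),
                  source_library = character(), n_amber = integer(),
                  truncated = logical())
    for (lab in design$positions$label) res[[lab]] <- character()
    return(res)
  }
  # draw all positions for all clones at once (column-wise so the draws
  # stay reproducible per position under a fixed seed)
  drawn <- matrix("", nrow = n, ncol = k)
  for (p in seq_len(k)) {
    lab <- design$positions$label[p]
    if (lab %in% names(design$class_restrictions)) {
      drawn[, p] <- sample(design$class_restrictions[[lab]], n, replace = TRUE)
    } else {
      drawn[, p] <- nnk$aa[sample.int(32L, n, replace = TRUE)]
    }
  }
  n_amber <- rowSums(drawn == "*")
  if (translation_mode == "supE_amber_to_Q") {
    drawn[drawn == "*"] <- "Q"
  }
  mat <- matrix(base_aa, nrow = n, ncol = length(base_aa), byrow = TRUE)
  mat[, design$positions$residue_index] <- drawn
  seqs <- apply(mat, 1L, paste, collapse = "")
  truncated <- rep(FALSE, n)
  if (translation_mode == "strict_stop") {
    stop_at <- apply(mat == "*", 1L, function(r) {
      w <- which(r)
      if (length(w)) w[1] else NA_integer_
    })
    truncated <- !is.na(stop_at)
    seqs[truncated] <- substr(seqs[truncated], 1L, stop_at[truncated] - 1L)
  }
  if (include_termini) {
    seqs[!truncated] <- paste0(design$n_terminus, seqs[!truncated],
                               design$c_terminus)
  }
  out <- tibble(
    id = sprintf("%s_%04d", design$name, seq_len(n)),
    aa_sequence = seqs, source_library = design$name,
    n_amber = as.integer(n_amber), truncated = truncated
  )
  for (p in seq_len(k)) out[[design$positions$label[p]]] <- drawn[, p]
  out
}

#' Build a maturation library from a base clone and consensus motif
#'
#' Positions named in the motif are restricted to their residue-class
#' member sets (aliphatic M/I/L/V, aromatic W/Y/F, small A/G/S); all other
#' scaffold positions keep the base clone's residue.
#'
#' @param base_clone Amino-acid sequence of the parental clone, aligned to
#'   the scaffold grammar (same length as the mature base sequence).
#' @param motif Tibble with `label` and `class` columns (see
#'   [consensus_motif_classes()]), or an `ab_motif` from [consensus_motif()].
#' @param base `ab_scaffold` the clone is built on.
#' @param name Library name.
#' @return An `ab_library` with class restrictions at the motif positions.
#' @export
matlib_from_consensus <- function(base_clone, motif,
                                  base = build_named_variant("scRef_L16"),
                                  name = "matLib") {
  if (inherits(motif, "ab_motif")) motif <- motif$assignments
  stopifnot(all(c("label", "class") %in% names(motif)))
  if (nchar(base_clone) != nchar(scaffold_sequence(base, FALSE))) {
    stop("base clone must align to the scaffold grammar (length ",
         nchar(scaffold_sequence(base, FALSE)), ")", call. = FALSE)
  }
  motif <- motif[!is.na(motif$class), , drop = FALSE]
  pos <- if (nrow(motif)) {
    parse_position_label(motif$label)
  } else {
    tibble(helix = character(), heptad = integer(), letter = character(),
           label = character())
  }
  restrictions <- stats::setNames(
    lapply(motif$class, function(cl) {
      if (!cl %in% names(RESIDUE_CLASSES)) {
        stop("unknown residue class: ", cl, call. = FALSE)
      }
      RESIDUE_CLASSES[[cl]]
    }),
    motif$label
  )
  # base differs from the scaffold reference: carry the clone as the base
  base$helices <- replace_clone_helices(base, base_clone)
  new_library_design(name, base, pos, codon_model = "class-restricted",
                     class_restrictions = restrictions,
                     n_terminus = paste0(PELB21, "S"),
                     c_terminus = C_TERM_MATURATION)
}

replace_clone_helices <- function(base, clone_seq) {
  reg <- scaffold_registry(base)
  aa <- strsplit(clone_seq, "")[[1]]
  helices <- base$helices
  for (h in HELIX_IDS) {
    idx <- reg$residue_index[!is.na(reg$helix) & reg$helix == h]
    helices[[h]]$sequence <- paste(aa[idx], collapse = "")
  }
  helices
}

#' Write sampled clones to FASTA
#'
#' Headers carry the clone id and the sampled residues at each randomized
#' position (`label=res` pairs).
#'
#' @param clones Tibble from [sample_clones()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  meta_cols <- setdiff(names(clones),
                       c("id", "aa_sequence", "source_library", "n_amber",
                         "truncated", "class_truth"))
  lines <- unlist(lapply(seq_len(nrow(clones)), function(i) {
    ann <- if (length(meta_cols)) {
      paste(sprintf("%s=%s", meta_cols, unlist(clones[i, meta_cols])),
            collapse = " ")
    } else ""
    c(paste0(">", clones$id[i], " ", clones$source_library[i], " ", ann),
      clones$aa_sequence[i])
  }))
  writeLines(lines, path)
  invisible(path)
}
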