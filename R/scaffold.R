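#' @importFrom dplyr bind_rows mutate filter arrange group_by summarise ungroup
NULL

# Heptad building blocks of the designed scaffold. Core a/d positions are
# Ile; e/g are Gln, b/c Ala, f Lys. The first heptad carries Glu capping
# deviations at b/c and the terminal heptad is truncated after d (IYRM),
# keeping Ile at a and Met at d.
HEPTAD_FIRST <- "IEEIQKQ"
HEPTAD_INTERNAL <- "IAAIQKQ"
HEPTAD_TERMINAL <- "IYRM"

GEOMETRY_CONSTANTS <- list(
  span_per_linker_residue = 3.0, # Angstrom bridged per extended Gly/Ser
  rise_per_helix_turn = 5.4,     # Angstrom per alpha-helical turn
  residues_per_turn = 3.6
)

helix_sequence_for <- function(n_heptads) {
  stopifnot(n_heptads >= 2)
  paste0(
    HEPTAD_FIRST,
    paste(rep(HEPTAD_INTERNAL, n_heptads - 2L), collapse = ""),
    HEPTAD_TERMINAL
  )
}

linker_core_for <- function(n_core_gs) {
  stopifnot(n_core_gs >= 0)
  if (n_core_gs == 0) return("")
  # repeat the GGSG motif and truncate from the C-terminal side
  full <- paste(rep("GGSG", ceiling(n_core_gs / 4)), collapse = "")
  substr(full, 1L, n_core_gs)
}

new_helix_spec <- function(n_heptads, sequence = helix_sequence_for(n_heptads),
                           start_letter = "a") {
  stopifnot(nchar(sequence) == 7L * (n_heptads - 1L) + 4L)
  list(n_heptads = n_heptads, sequence = sequence, start_letter = start_letter)
}

new_linker_spec <- function(n_core_gs, c_cap = "MS") {
  core <- linker_core_for(n_core_gs)
  stopifnot(c_cap %in% c("MS", "MD"))
  list(
    n_core_gs = n_core_gs,
    core = core,
    full_sequence = paste0("T", core, c_cap)
  )
}

new_scaffold_spec <- function(name, helices, linkers,
                              n_terminus = "", c_terminus = "") {
  out <- list(
    name = name, helices = helices, linkers = linkers,
    n_terminus = n_terminus, c_terminus = c_terminus
  )
  class(out) <- "ab_scaffold"
  out
}

#' @export
print.ab_scaffold <- function(x, ...) {
  seq_mature <- scaffold_sequence(x, include_termini = FALSE)
  cat("<ab_scaffold> ", x$name, "\n", sep = "")
  cat("  helices: 3 x ", x$helices$A$n_heptads, " heptads (",
      nchar(x$helices$A$sequence), " aa each)\n", sep = "")
  cat("  linkers: T + ", x$linkers$L1$n_core_gs, " Gly/Ser + ",
      substr(x$linkers$L1$full_sequence, nchar(x$linkers$L1$full_sequence) - 1L,
             nchar(x$linkers$L1$full_sequence)), "\n", sep = "")
  cat("  mature length: ", nchar(seq_mature), " aa\n", sep = "")
  invisible(x)
}

#' Build the reference single-chain triple-helix scaffold
#'
#' Assembles helix-linker-helix-linker-helix with three identical helices of
#' `n_heptads` heptad repeats (first heptad `IEEIQKQ`, internal repeats
#' `IAAIQKQ`, terminal half-heptad `IYRM`) joined by Gly/Ser linkers capped
#' `T`...`MS`. `build_reference(4, 16)` is the 113-residue reference
#' scaffold scRef_L16; `build_reference(4, 8)` is scRef_L8.
#'
#' @param n_heptads Heptads per helix (>= 2).
#' @param n_linker_gs Number of Gly/Ser residues in each linker core (>= 0).
#' @param name Optional scaffold name.
#' @return An `ab_scaffold` specification.
#' @examples
#' sc <- build_reference(4, 16)
#' nchar(scaffold_sequence(sc)) # 113
#' @export
build_reference <- function(n_heptads, n_linker_gs,
                            name = sprintf("scRef%d_L%d", n_heptads, n_linker_gs)) {
  if (n_heptads < 2 || n_linker_gs < 0) {
    stop("need n_heptads >= 2 and n_linker_gs >= 0", call. = FALSE)
  }
  hx <- new_helix_spec(n_heptads)
  lk <- new_linker_spec(n_linker_gs)
  new_scaffold_spec(name, helices = list(A = hx, B = hx, C = hx),
                    linkers = list(L1 = lk, L2 = lk))
}

#' Build a named scaffold preset
#'
#' Known presets: `"scRef_L16"` (4 heptads, 16 Gly/Ser linkers),
#' `"scRef_L8"`, and the shortened three-heptad series `"scShort_L6"` ..
#' `"scShort_L18"` used to probe linker-length effects on stability.
#'
#' @param name Preset name.
#' @return An `ab_scaffold` specification.
#' @export
build_named_variant <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^scRef_L([0-9]+)$", name))[[1]]
  if (length(m) == 2L) {
    sc <- build_reference(4L, as.integer(m[2]), name = name)
    return(sc)
  }
  m <- regmatches(name, regexec("^scShort_L([0-9]+)$", name))[[1]]
  if (length(m) == 2L) {
    n <- as.integer(m[2])
    if (n < 6L || n > 18L) {
      stop("scShort linker presets cover L6-L18, got L", n, call. = FALSE)
    }
    return(build_reference(3L, n, name = name))
  }
  stop("unknown scaffold preset: ", name, call. = FALSE)
}

#' Full scaffold amino-acid sequence
#'
#' @param spec `ab_scaffold` specification.
#' @param include_termini Include N-/C-terminal presets (display tags,
#'   leader sequences) when the spec carries them. The mature scaffold body
#'   is helix-linker-helix-linker-helix.
#' @return A single amino-acid string.
#' @export
scaffold_sequence <- function(spec, include_termini = TRUE) {
  stopifnot(inherits(spec, "ab_scaffold"))
  body <- paste0(
    spec$helices$A$sequence, spec$linkers$L1$full_sequence,
    spec$helices$B$sequence, spec$linkers$L2$full_sequence,
    spec$helices$C$sequence
  )
  if (include_termini) paste0(spec$n_terminus, body, spec$c_terminus) else body
}

#' Per-residue registry table of a scaffold
#'
#' Tabulates the mature chain (termini presets excluded) residue by
#' residue: helix residues carry heptad index/letter assignments, linker
#' residues are marked with `segment` `"L1"`/`"L2"` and `NA` registry.
#'
#' @param spec `ab_scaffold` specification.
#' @return Tibble with columns `residue_index`, `aa`, `segment`, `helix`,
#'   `heptad`, `letter`, `label`.
#' @export
scaffold_registry <- function(spec) {
  stopifnot(inherits(spec, "ab_scaffold"))
  segs <- list(
    list(id = "A", seq = spec$helices$A$sequence, helix = TRUE,
         start = spec$helices$A$start_letter),
    list(id = "L1", seq = spec$linkers$L1$full_sequence, helix = FALSE),
    list(id = "B", seq = spec$helices$B$sequence, helix = TRUE,
         start = spec$helices$B$start_letter),
    list(id = "L2", seq = spec$linkers$L2$full_sequence, helix = FALSE),
    list(id = "C", seq = spec$helices$C$sequence, helix = TRUE,
         start = spec$helices$C$start_letter)
  )
  offset <- 0L
  rows <- lapply(segs, function(s) {
    n <- nchar(s$seq)
    if (n == 0L) return(NULL)
    if (s$helix) {
      reg <- assign_registry(s$seq, start_letter = s$start, helix = s$id)
      out <- tibble(
        residue_index = reg$residue_index + offset, aa = reg$aa,
        segment = s$id, helix = reg$helix, heptad = reg$heptad,
        letter = reg$letter, label = reg$label
      )
    } else {
      out <- tibble(
        residue_index = seq_len(n) + offset,
        aa = strsplit(s$seq, "")[[1]],
        segment = s$id, helix = NA_character_, heptad = NA_integer_,
        letter = NA_character_, label = NA_character_
      )
    }
    offset <<- offset + n
    out
  })
  bind_rows(rows)
}

#' Theoretical maximum span of a Gly/Ser linker
#'
#' An extended linker residue bridges about 3.0 Angstrom, so 16 Gly/Ser
#' residues can span roughly 48 Angstrom. The `T`/`MS` caps are treated as
#' non-bridging.
#'
#' @param n_core_gs Number of Gly/Ser core residues (vectorized).
#' @param span_per_residue Angstrom bridged per residue (default 3.0).
#' @return Span in Angstrom.
#' @export
linker_max_span <- function(n_core_gs,
                            span_per_residue = GEOMETRY_CONSTANTS$span_per_linker_residue) {
  stopifnot(all(n_core_gs >= 0))
  n_core_gs * span_per_residue
}

#' Height of an alpha-helix in turns
#'
#' @param n_turns Number of helical turns.
#' @param rise_per_turn Angstrom per turn (default 5.4).
#' @return Height in Angstrom (7 turns -> 37.8, printed as 38 when rounded).
#' @export
helix_height <- function(n_turns, rise_per_turn = GEOMETRY_CONSTANTS$rise_per_helix_turn) {
  stopifnot(all(n_turns >= 0))
  n_turns * rise_per_turn
}

#' Helical turns of a residue stretch
#'
#' @param n_residues Number of residues.
#' @param residues_per_turn Residues per alpha-helical turn (default 3.6).
#' @return Tibble with `turns` (raw) and `turns_rounded` (nearest integer):
#'   25 residues -> 6.94 turns, rounds to 7.
#' @export
helix_turns <- function(n_residues, residues_per_turn = GEOMETRY_CONSTANTS$residues_per_turn) {
  stopifnot(all(n_residues >= 0))
  turns <- n_residues / residues_per_turn
  tibble(n_residues = n_residues, turns = turns,
         turns_rounded = as.integer(round(turns)))
}

#' Linker-geometry feasibility of parallel vs antiparallel folding
#'
#' In a fully parallel triple helix a linker must bridge the full height of
#' a helix (N- to C-terminal end); in the antiparallel up-down-up fold it
#' only hops laterally between adjacent helix ends. The linker span is
#' counted over its Gly/Ser core at 3.0 Angstrom per residue; the helix
#' height uses the integer-rounded turn count (25 residues ~ 7 turns ~ 37.8
#' Angstrom). A 16-residue linker (48 Angstrom) permits both topologies; an
#' 8-residue linker (24 Angstrom) is too short for parallel folding.
#'
#' @param spec `ab_scaffold` specification.
#' @param lateral_hop Angstrom required for the antiparallel lateral hop
#'   (default 10, about twice the superhelix radius).
#' @return One-row tibble: `span`, `helix_height`, `feasible_parallel`,
#'   `feasible_antiparallel`.
#' @export
parallel_feasibility <- function(spec, lateral_hop = 10) {
  stopifnot(inherits(spec, "ab_scaffold"))
  span <- linker_max_span(spec$linkers$L1$n_core_gs)
  n_res <- nchar(spec$helices$A$sequence)
  turns <- helix_turns(n_res)$turns_rounded
  height <- helix_height(turns)
  tibble(
    scaffold = spec$name,
    span = span,
    helix_height = height,
    feasible_parallel = span >= height,
    feasible_antiparallel = span >= lateral_hop
  )
}

# Average residue masses (Da); +1 water for the free peptide.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MASS_WATER <- 18.01528

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water. The mature 113-residue
#' reference scaffold lands near 11.5 kDa, consistent with the "about 10
#' kDa" scale of the platform.
#'
#' @param sequence Amino-acid string(s), standard 20 residues.
#' @return Molecular weight(s) in Da.
#' @examples
#' molecular_weight("G") # free glycine, 75.07
#' @export
molecular_weight <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- !(aa %in% names(AA_AVG_MASS))
    if (any(bad)) {
      stop("non-standard residue symbol(s): ",
           paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
    }
    sum(AA_AVG_MASS[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write scaffold sequences to FASTA
#'
#' @param specs An `ab_scaffold` or list of them.
#' @param path Output file.
#' @param include_termini Passed to [scaffold_sequence()].
#' @return `path`, invisibly.
#' @export
write_scaffold_fasta <- function(specs, path, include_termini = TRUE) {
  if (inherits(specs, "ab_scaffold")) specs <- list(specs)
  lines <- unlist(lapply(specs, function(s) {
    c(paste0(">", s$name), scaffold_sequence(s, include_termini))
  }))
  writeLines(lines, path)
  invisible(path)
}
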