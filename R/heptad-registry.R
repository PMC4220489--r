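#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

HEPTAD_LETTERS <- c("a", "b", "c", "d", "e", "f", "g")
HELIX_IDS <- c("A", "B", "C")
AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Parse a heptad position label
#'
#' Positions on the three-helix scaffold are named by helix (A, B or C),
#' 1-based heptad index within that helix, and heptad letter a--g, written
#' as e.g. `"A2g"` (helix A, second heptad, g position). The a and d letters
#' are the hydrophobic core; b/c/e/f/g are surface or groove positions.
#'
#' @param label Character vector of position labels such as `"A2g"`.
#'   Case-insensitive: helix is upper-cased, letter lower-cased.
#' @return A tibble with one row per label and columns `helix`, `heptad`
#'   (integer >= 1), `letter` and the normalized `label`.
#' @examples
#' parse_position_label(c("A2g", "C3e"))
#' @export
parse_position_label <- function(label) {
  stopifnot(is.character(label), length(label) >= 1L, !anyNA(label))
  m <- regmatches(label, regexec("^([A-Ca-c])([0-9]+)([A-Ga-g])$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed position label(s): ", paste(label[bad], collapse = ", "),
         " (expected e.g. \"A2g\" with helix A-C, heptad >= 1, letter a-g)",
         call. = FALSE)
  }
  helix <- toupper(vapply(m, `[`, "", 2L))
  heptad <- as.integer(vapply(m, `[`, "", 3L))
  letter <- tolower(vapply(m, `[`, "", 4L))
  if (any(heptad < 1L)) {
    stop("heptad index must be >= 1 in: ",
         paste(label[heptad < 1L], collapse = ", "), call. = FALSE)
  }
  tibble(
    helix = helix, heptad = heptad, letter = letter,
    label = paste0(helix, heptad, letter)
  )
}

#' Format heptad position references as labels
#'
#' Inverse of [parse_position_label()]: `parse_position_label(format_position(x))`
#' restores `x` for any valid reference.
#'
#' @param ref Tibble (or data frame) with columns `helix`, `heptad`, `letter`.
#' @return Character vector of labels.
#' @export
format_position <- function(ref) {
  stopifnot(all(c("helix", "heptad", "letter") %in% names(ref)))
  paste0(ref$helix, ref$heptad, ref$letter)
}

#' Assign heptad register letters along one helix
#'
#' Walks a helix sequence residue by residue, cycling the letters a..g from
#' the given start letter; the heptad index increments each time the cycle
#' wraps past g. For the designed scaffolds the first helix residue is an
#' a-position isoleucine, so `start_letter = "a"` (the default) aligns the
#' Ile/Ile core with a/d.
#'
#' @param sequence One amino-acid string (1-letter codes, standard 20).
#' @param start_letter Heptad letter carried by the first residue.
#' @param helix Helix identifier attached to each row (`"A"`, `"B"` or `"C"`).
#' @return A tibble with columns `residue_index` (1-based), `aa`, `helix`,
#'   `heptad`, `letter`, `label`; zero rows for an empty sequence.
#' @examples
#' assign_registry("IEEIQKQ") # core Ile at a and d
#' @export
assign_registry <- function(sequence, start_letter = "a", helix = "A") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  stopifnot(start_letter %in% HEPTAD_LETTERS, helix %in% HELIX_IDS)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) == 0L) {
    return(tibble(
      residue_index = integer(), aa = character(), helix = character(),
      heptad = integer(), letter = character(), label = character()
    ))
  }
  bad <- !(aa %in% AA1)
  if (any(bad)) {
    stop("non-standard residue symbol(s): ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  }
  offset <- match(start_letter, HEPTAD_LETTERS) - 1L
  idx <- seq_along(aa)
  pos <- (offset + idx - 1L) %% 7L          # 0-based letter position
  heptad <- (offset + idx - 1L) %/% 7L + 1L # wraps past g -> next heptad
  tibble(
    residue_index = idx,
    aa = aa,
    helix = helix,
    heptad = heptad,
    letter = HEPTAD_LETTERS[pos + 1L],
    label = paste0(helix, heptad, HEPTAD_LETTERS[pos + 1L])
  )
}

#' Map a heptad position to its index in the full scaffold chain
#'
#' @param ref A position label (character) or a tibble from
#'   [parse_position_label()]; may hold several positions.
#' @param spec A scaffold specification from [build_reference()] or
#'   [build_named_variant()].
#' @return Integer vector of 1-based indices into the mature scaffold
#'   sequence (termini presets excluded, as in [scaffold_sequence()] with
#'   `include_termini = FALSE`).
#' @seealso [residue_index_to_position()] for the inverse lookup.
#' @export
position_to_residue_index <- function(ref, spec) {
  if (is.character(ref)) ref <- parse_position_label(ref)
  reg <- scaffold_registry(spec)
  labels <- format_position(ref)
  idx <- match(labels, reg$label)
  if (anyNA(idx)) {
    stop("position(s) absent from scaffold '", spec$name, "': ",
         paste(labels[is.na(idx)], collapse = ", "),
         " (truncated terminal heptads only contain the letters present)",
         call. = FALSE)
  }
  reg$residue_index[idx]
}

#' Inverse lookup: chain index to heptad position
#'
#' @param index 1-based residue index into the mature scaffold chain.
#' @param spec Scaffold specification.
#' @return Tibble with `helix`, `heptad`, `letter`, `label` for each index.
#' @export
residue_index_to_position <- function(index, spec) {
  reg <- scaffold_registry(spec)
  hit <- match(index, reg$residue_index)
  if (anyNA(hit)) {
    stop("residue index/indices not on a helix: ",
         paste(index[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  reg[hit, c("helix", "heptad", "letter", "label")]
}

#' Enumerate the A--C groove positions of a scaffold
#'
#' The concave binding groove between the two parallel helices A and C is
#' lined by the c- and g-positions of helix A and the b- and e-positions of
#' helix C. Only positions physically present are returned: a terminal
#' heptad truncated after d contributes its c (helix A) and b (helix C) but
#' no g/e. For an n-heptad scaffold truncated at d this census is 4n - 2
#' positions (14 for the 4-heptad reference, 10 for the 3-heptad short
#' variant).
#'
#' @param spec Scaffold specification.
#' @return Tibble of groove positions (`helix`, `heptad`, `letter`, `label`,
#'   `aa`, `residue_index`).
#' @export
groove_positions <- function(spec) {
  reg <- scaffold_registry(spec)
  keep <- (reg$helix == "A" & reg$letter %in% c("c", "g")) |
    (reg$helix == "C" & reg$letter %in% c("b", "e"))
  out <- reg[keep, c("helix", "heptad", "letter", "label", "aa", "residue_index")]
  out[order(match(out$helix, HELIX_IDS), out$heptad, out$letter), ]
}
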