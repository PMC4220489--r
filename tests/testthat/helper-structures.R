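# synthetic miniature scaffold:target complex (labelled synthetic: it is a
# hand-built stand-in for a deposited complex, used to exercise the
# interface/epitope machinery, not to reproduce its numbers)
synthetic_complex_atoms <- function() {
  atom <- function(chain, resno, resname, name, element, x, y, z) {
    tibble::tibble(element = element, name = name, resno = resno,
                   resname = resname, chain = chain,
                   x = x, y = y, z = z, occupancy = 1)
  }
  rows <- list(
    # scaffold chain M: core Ile, conserved Tyr, an H-bond donor,
    # a salt-bridge Lys, and a far-away helix B stretch (resno 45..69)
    atom("M", 106, "ILE", "CD1", "C", 0, 0, 0),
    atom("M", 110, "TYR", "OH", "O", 0, 0, 6),
    atom("M", 13, "GLN", "NE2", "N", 6, 0, 0),
    atom("M", 20, "LYS", "NZ", "N", 0, 6, 0),
    # target chain P: hotspot Trp within contact range of Ile 106
    atom("P", 156, "TRP", "CZ2", "C", 3.6, 0, 0),
    atom("P", 50, "GLU", "OE1", "O", 0, 6, 3.4),
    atom("P", 60, "SER", "O", "O", 6, 0, 3.0)
  )
  # pocket atoms that bury the Tyr 110 probe from most directions
  ring <- lapply(seq(0, 315, by = 45), function(a) {
    th <- a * pi / 180
    atom("P", 200 + a / 45, "LEU", "CD1", "C",
         3.4 * cos(th), 3.4 * sin(th), 6)
  })
  cap <- atom("P", 210, "LEU", "CD2", "C", 0, 0, 9.4)
  helixb <- lapply(45:69, function(i) {
    atom("M", i, "ALA", "CB", "C", 60 + (i - 45) * 3.8, 0, 0)
  })
  dplyr::bind_rows(c(rows, ring, list(cap), helixb))
}
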