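Package: alphabody
Title: Design and Characterization of Single-Chain Triple-Helix Coiled-Coil Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single-chain antiparallel triple-helix coiled-coil
    ("alphabody") protein scaffolds: heptad register bookkeeping and position
    nomenclature, assembly of reference and shortened scaffold variants with
    Gly/Ser linkers, linker-geometry feasibility arguments, idealized
    coiled-coil backbone generation with knobs-into-holes core detection,
    NNK phage-display library design and diversity statistics, clone
    quality-control triage (positivity scoring, deletion-architecture
    classification, consensus binding motifs), 1:1 binding-assay models and
    fitters (equilibrium and kinetic ELISA, competitive inhibition, SPR
    sensorgrams, one-site ITC, thermal denaturation with GuHCl
    extrapolation), and a buried-surface interface analyzer for two-group
    protein complexes. All results are returned as tidy tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
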