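# alphabody

Toolkit for designing, randomizing, quality-controlling and characterizing
single-chain antiparallel triple-helix coiled-coil protein scaffolds
("alphabodies") of the kind used as antibody alternatives against
protein–protein interaction targets such as the cytokine IL-23. It is
aimed at protein engineers running phage-display campaigns on designed
coiled-coil scaffolds and at structural biologists characterizing the
resulting binders.

The package covers the full computational side of such a campaign:

- **Heptad registry** — position nomenclature `<helix><heptad><letter>`
  (e.g. `A2g`), register assignment over the cycle `a b c d e f g`, and
  enumeration of the A–C groove surface (c/g on helix A, b/e on helix C).
- **Scaffold building** — reference and shortened variants assembled from
  the heptad grammar (Ile at a/d, Gln at e/g, Ala at b/c, Lys at f;
  `IEEIQKQ(IAAIQKQ)ₙIYRM` helices joined by `T(G/S)ₙMS` linkers), the
  linker-geometry feasibility argument (span ≈ 3.0 Å per residue vs helix
  height ≈ 5.4 Å per turn), idealized coiled-coil backbones and a
  SOCKET-style knobs-into-holes core detector.
- **Library design** — NNK randomization schemes (32 codons, one amber
  stop), diversity statistics (32^k DNA diversity, (31/32)^k stop-free
  fraction, coupon-bound coverage), synthetic clone sampling with amber
  suppression, and consensus-motif-restricted maturation libraries.
- **Clone QC** — ELISA positivity (OD_target > 3 × OD_background),
  antibody-competition indices, deletion-architecture classification
  (intact / two-heptad gap / helix-B loss / helix-C-only), panel
  summaries and consensus binding motifs.
- **Binding and stability models** — K_D = k_off/k_on bookkeeping and
  simulate/fit pairs for equilibrium and kinetic ELISA, competitive
  inhibition (K_I through a 4PL calibration and the exact 1:1 mass
  balance), 1:1 Langmuir SPR sensorgrams, one-site ITC (with
  ΔG° = RT ln K_D, ΔG° = ΔH° − TΔS°), and two-state thermal melts with
  linear extrapolation of T_m to 0 M GuHCl.
- **Interface analysis** — Shrake–Rupley solvent accessibility, per-side
  buried surface, interface residues, hydrogen bonds and salt bridges of
  a two-group complex, plus named epitope checks for scaffold:target
  binding modes.

Everything takes and returns tidy tibbles, fitted objects have
`tidy()`/`glance()` and `autoplot()` methods, and all simulators are
deterministic under a seed.

## Worked example

```r
library(alphabody)

# the 113-residue reference scaffold and the linker-geometry argument
sc <- build_named_variant("scRef_L16")
sc
#> <ab_scaffold> scRef_L16
#>   helices: 3 x 4 heptads (25 aa each)
#>   linkers: T + 16 Gly/Ser + MS
#>   mature length: 113 aa

parallel_feasibility(build_named_variant("scRef_L8"))
#>   scaffold  span helix_height feasible_parallel feasible_antiparallel
#> 1 scRef_L8    24         37.8 FALSE             TRUE
```

An 8-residue linker spans at most 24 Å but a 7-turn helix is 37.8 Å high,
so the shortened scaffold cannot fold parallel — the geometric argument
for the antiparallel up-down-up topology.

```r
library_census(make_named_library("scLib_AC11"))
#>   library    n_randomized groove_total groove_randomized groove_percent
#> 1 scLib_AC11           11           14                11             79
```

The 11-position groove library randomizes 11 of the 14 A–C groove
positions (79%).

```r
# a synthetic 80-clone sequencing panel with the observed deletion classes
des <- make_named_library("scLib_AC11")
panel <- generate_clone_panel(
  c(intact = 35, del_two_heptads = 5, del_helix_B = 35, only_helix_C = 5),
  des, seed = 1
)
qc_panel(panel, des$base, randomized = des$positions$label)
#> <clone QC panel> n = 80, unique = 80, defective = 56%

# rate constants to affinity: SPR rates of the matured binder
p <- kinetic_params(k_on = 2.6e5, k_off = 1.2e-4)
signif(p$K_D * 1e9, 2)
#> [1] 0.46   # nM

# recover kinetic parameters from a simulated kinetic ELISA
g <- simulate_kinetic_elisa(kinetic_params(1e5, 7e-4),
                            concs = 1e-6 / 5^(0:7),
                            times = c(24*3600, 3*3600, 3600, 900, 480, 240))
tidy(fit_kinetic_elisa(g))
#>   term   estimate
#> 1 K_D        7e-9
#> 2 k_on       1e+5
#> 3 k_off      7e-4
#> 4 od_max     1e+0
```

A thin command-line wrapper ships in `inst/cli/alphabody.R`
(`scaffold build`, `scaffold check-linker`, `library census`,
`library sample`, `qc panel`, `simulate`, `fit melt`).

## Scope

Wet-lab protocol steps, crystallographic structure determination,
all-atom modelling and stability prediction are out of scope: measured
melting temperatures, affinities and structures are inputs here, not
predictions.
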