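---
title: "Models and methods for single-chain triple-helix scaffold design and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-chain triple-helix scaffold design and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphabody)
```

## The scaffold and its grammar

The package models a computationally designed ~10 kDa protein scaffold in
which three alpha-helices of a single polypeptide chain fold into an
antiparallel (up-down-up) coiled coil. Each helix is a run of heptad
repeats with the canonical coiled-coil register `a b c d e f g`: Ile at the
core a/d positions (Ile layers strongly favour three-stranded coiled
coils), Gln at the interhelical e/g positions, Ala at the exposed b/c
positions and Lys at f. The first heptad carries Glu capping substitutions
at b/c and each helix ends in a truncated fourth heptad `IYRM` (letters
a--d only), so an n-heptad helix has 7(n-1)+4 residues. Helices are joined
by Gly/Ser linkers written `T` + (Gly/Ser core) + `MS`; the Thr and Met-Ser
caps are bookkept as part of the linker.

`assign_registry()` walks a helix and assigns each residue its heptad
letter, cycling a through g from a configurable start letter. The start
letter defaults to `a` because the designed helix begins with its core
isoleucine; with that origin the consensus-motif labels used in selection
work (e.g. `A2g`, `C3e`) fall on the expected chemistry. Heptad indices
and chain indices are both 1-based. Positions are named
`<helix><heptad><letter>` and `parse_position_label()` /
`format_position()` round-trip them.

A design question the text sources leave open is whether heptad numbering
counts from the helix N-terminus. We number from the N-terminus; under
that convention the consensus positions land on groove-facing letters
consistently, which is the only internal check available without the
original design files.

## Linker-geometry feasibility

The folding-topology argument is purely geometric. An extended linker
residue bridges about 3.0 A, so a 16-residue Gly/Ser core spans about 48
A. One helix of 25 residues is about 25/3.6 = 6.94 ~ 7 turns, i.e. 7 x
5.4 = 37.8 A (displayed rounded as 38). A fully parallel arrangement
requires the linker to run the full helix height; the antiparallel
up-down-up arrangement only needs a short lateral hop between adjacent
helix ends, for which we use 10 A (about twice the superhelix radius) as
the default threshold -- the quantitative argument in the source work
concerns only the parallel case, so this constant is configurable.
`parallel_feasibility()` therefore classifies the 16-residue-linker
scaffold as compatible with both topologies and the 8-residue variant (24
A span) as antiparallel-only. Feasibility is monotone in linker length by
construction.

The span counts only the Gly/Ser core: the `T`/`MS` caps are treated as
non-bridging, which is what the quoted "16 residues x 3 A" arithmetic
implies even though the full printed linker is 19 residues.

## Idealized backbones and knobs-into-holes detection

`build_ideal_backbone()` places the three helices 120 degrees apart at
superhelix radius R0 = 6.5 A, each built as an ideal alpha-helix (helix
radius R1 = 2.26 A, rise 1.5 A/residue) with local twist 720/7 degrees
per residue so the heptad repeat is exactly periodic around the bundle.
The per-helix phase is set so the mid-direction between the a and d
positions faces the bundle axis -- the standard core orientation. In the
antiparallel topology helix B runs in the opposite axial direction.
Linkers are not modelled (they are disordered in solved structures); only
Calpha positions are produced. This backbone is used for self-consistent
topology checks, not for modelling: all-atom packing, energetics and
stability prediction are out of scope.

`detect_knobs_into_holes()` is a SOCKET-style detector operating on a
side-chain proxy: each Calpha pushed 1.5 A further out radially from its
helix's least-squares axis (computed from the coordinates, so the
detector is rigid-motion invariant). A residue is a knob when its proxy
lies within 7.4 A of the proxies of at least 4 residues of one other
helix; knobs are grouped into layers by axial coordinate. On the ideal
antiparallel build this reports exclusively a/d knobs, with helix B's
a-residues sharing layers with the d-residues of the parallel helices A
and C and vice versa -- the expected antiparallel core packing. The
chain-terminal residue of each helix has no complete 4-residue hole
beyond the helix end and is not reported as a knob, the same edge
behaviour SOCKET shows at helix termini.

## Library designs and NNK statistics

The groove between helices A and C is lined by the c/g letters of A and
the b/e letters of C; for an n-heptad scaffold with d-truncated terminal
heptads that census is 4n - 2 positions (14 for the reference scaffold).
The preset `scLib_AC11` randomizes 11 of those 14 (79%); `scLib_AC7` is
the same theme on the 3-heptad short scaffold (4 + 3 positions);
`scLib_C9` randomizes nine b/c/f positions of helix C (the convex
helix-surface theme). The published material prints only counts and
letters, not the exact heptads, so the position identities inside those
constraints are package defaults chosen to include the five
consensus-motif positions; they are overridable. Note that b-positions of
helix C face the A-C groove by the register definition, so the
helix-surface preset necessarily overlaps the groove census at its three
b-positions; we report that overlap as computed rather than forcing it
to zero.

Randomization uses the NNK degenerate codon (N = A/C/G/T, K = G/T): 32
codons, all 20 amino acids, one amber stop (TAG). For k fully randomized
positions, DNA diversity is 32^k, the amber-free fraction (31/32)^k, and
the library size needed to observe one given variant with probability P
is the coupon bound ceiling(log(1-P)/log(1-32^-k)); full-library coverage
is astronomically infeasible for k = 11 and would mislead, so it is not
reported. `sample_clones()` draws codons uniformly and translates them;
in amber-suppressor (supE) mode TAG reads as Gln (so Gln appears at
2/32), in strict-stop mode clones truncate at the first amber and are
flagged rather than dropped. The maturation library restricts the five
consensus positions to residue classes (aliphatic M/I/L/V, aromatic
W/Y/F, small A/G/S -- the union of the residues observed per class) and
keeps the parental residue elsewhere; the original partial-randomization
codons are not published, so class-restricted sampling stands in for
them.

## Clone quality control

Screening positivity is the strict rule OD_target > 3 x OD_background.
Competition against a blocking antibody is 1 - OD_with/OD_without clamped
to [0, 1]. Architecture classification reflects the deletion classes
observed among sequenced binders: intact; a contiguous ~two-heptad
(14 +/- 1 residue) gap within one helix; loss of the entire helix B; and
clones reduced to helix C. Because the three helices share one template
sequence, naive sliding-window matching cannot tell helix B from helix C;
the classifier therefore first anchors on the Gly/Ser linkers (never
randomized, and retained in the observed deletion classes) and then tests
each inter-linker region against its positional helix template by
ungapped identity over the non-randomized positions, threshold 0.8.
Terminus tags do not affect the call. Panel summaries count classes
(which partition the panel), the defective fraction, unique sequences,
and Pro/Gly "destabilizer" occurrences at the randomized positions;
amber usage cannot be inferred from protein-level input and is reported
as unavailable. Consensus motifs assign a residue class to a position
when at least 70% of clones carry a member of that class.

## Binding and stability models

All concentrations are molar internally. The models are the standard 1:1
forms:

- Equilibrium: bound fraction c/(c + K_D), with a depletion-corrected
  quadratic variant for finite target.
- Kinetic ELISA: OD(c, t) = OD_max c/(c+K_D) (1 - exp(-(k_on c + k_off) t)),
  the pseudo-first-order solution with analyte in excess over coated
  target (the excess is orders of magnitude, and the published
  two-parameter fit implies this closed form). The fit has two binding
  parameters, K_D and k_on, with k_off reported as their product; OD_max
  is co-fitted unless fixed. Parameters are searched in log space with
  log-spaced multistarts (K_D over 1e-12..1e-6 M, k_on over 1e3..1e8) to
  avoid local minima on plateaued curves.
- Competitive inhibition: an inhibition series at fixed target L_tot is
  mapped through a monotone four-parameter-logistic calibration fitted to
  a parallel dose-response; the free target at inhibitor concentration I
  comes from the exact 1:1 mass balance (solved for the free-ligand root
  directly, avoiding catastrophic cancellation), and K_I is the
  least-squares scale of that composition. A 4PL is used instead of raw
  interpolation because the calibration is a smooth dose-response and the
  4PL is identifiable from the 0.01-10 nM design.
- SPR: 1:1 Langmuir association to R_eq = R_max c/(c + K_D) with rate
  k_on c + k_off, exponential dissociation, response continuous at the
  phase boundary; k_on, k_off and R_max are fitted globally across the
  concentration series. Mass-transport limitation is out of scope.
- ITC: the single-site total-heat model with displaced-volume
  bookkeeping and a co-fitted constant dilution-heat offset (standard
  practice; the source is silent on dilution heats). The fit reports N,
  K_D, dH and the exact identities dG = RT ln K_D and T dS = dH - dG at
  the experiment temperature (30 C). The Wiseman c-value N[cell]/K_D
  governs K_D identifiability; outside [1, 1e4] the fit warns. The
  reference geometry (4.9 uM cell, subnanomolar K_D) sits above that
  window, which is why the recovered K_D there should be read as a lower
  bound in noisy data.
- Thermal melts: a two-state sigmoid with (optionally linear) baselines;
  Tm is the midpoint, flagged when it falls outside the scanned window.
  Melting temperatures measured in 3-6 M GuHCl extrapolate linearly to 0
  M by ordinary least squares; extreme native stability (Tm near 120 C)
  is an experimental observable obtained this way, not a prediction.

## Interface analysis

`sasa()` implements Shrake-Rupley accessibility with a deterministic
Fibonacci-lattice quadrature (960 points per atom by default, probe 1.4
A) over an element-keyed united-atom radius set (C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20 A). `interface_report()` computes the complex and
per-side free accessibilities; the per-residue difference gives each
side's buried area (so side1 + side2 buried equals the total accessibility
loss exactly, by construction), the interface residue list (dASA > 0.1
A^2, suppressing quadrature noise) and each side's buried fraction of its
free surface. Hydrogen bonds are counted as N/O--N/O pairs across the
interface within 3.5 A -- deposited models carry no hydrogens, so the
donor-geometry angle test is downgraded to distance-only -- and salt
bridges as Lys/Arg/His side-chain nitrogens within 4.0 A of Asp/Glu
carboxylate oxygens, deduplicated per residue pair. Named epitope checks
test the hallmark binding-mode features of the scaffold:target complex:
the target's hotspot tryptophan packing against the scaffold's core
isoleucine, the scaffold's conserved tyrosine burying most of its free
surface, and helix B contributing no interface residues.

Because the quadrature lattice is fixed in the laboratory frame, areas
are rotation invariant only up to quadrature noise (a few percent at 960
points, under 1% at 4000); contact lists and interface membership are
exact under rigid motions. Structure input goes through `bio3d` (PDB and
mmCIF), dropping waters and hetero atoms and resolving alternate
locations to the highest-occupancy conformer. Analyses of the deposited
scaffold:cytokine complex require downloading those coordinates; the test
suite instead exercises the full pipeline on a small synthetic complex
constructed in code (and labelled synthetic), which validates the
machinery but says nothing about the deposited entry's numbers.

## Synthetic data: what it emulates and what it does not

`generate_clone_panel()` reproduces the sequenced-panel composition (35
intact, 35 helix-B deletions, 5 two-heptad deletions, 5 helix-C-only in
the 80-clone configuration, i.e. 56% defective) with clone sequences
drawn from the NNK scheme, and `generate_assay_fixture()` wraps the assay
simulators at the published designs: the 24 h-4 min kinetic-ELISA time
grid with fivefold dilutions, inhibition at 2.6 pM and 200 pM fixed
target, the 0.5-40 nM SPR series with 3-min association and 20-min
dissociation, and the 4.9/53.2 uM ITC geometry with 5-ul injections.
Noise is independent Gaussian on the response. Real screening data add
features the generator does not emulate -- plate effects, heteroscedastic
ELISA noise, phage-display selection biases, correlated ITC baseline
drift -- so passing recovery tests demonstrates correctness of the
models and fitters, not robustness to every experimental artefact.

## Numerical choices

Fits use Levenberg-Marquardt (`minpack.lm`) with multistarts in log
parameter space, or Nelder-Mead for the ITC model; the inhibition fit is
a one-dimensional golden-section refinement of a log-grid scan. The
free-ligand quadratic is solved in the cancellation-free form and is
checked against a bisection oracle to 1e-10 relative. Problem sizes in
the test suite (1e4-1e5 sampled clones for frequency checks, 50-100
noisy replicates per fitter, 960-4000 quadrature points) were chosen so
that each statistical check has comfortable power while the whole suite
stays quick to run on one CPU.

## A worked pass

```{r example}
sc <- build_named_variant("scRef_L16")
parallel_feasibility(sc)
library_census(make_named_library("scLib_AC11"))
p <- kinetic_params(k_on = 2.6e5, k_off = 1.2e-4)
signif(p$K_D * 1e9, 2) # nM
```
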