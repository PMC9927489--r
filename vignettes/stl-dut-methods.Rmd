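---
title: "Methods: structural and kinetic analysis of Stl–dUTPase recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural and kinetic analysis of Stl-dUTPase recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dutstl)
```

## Scientific setting

The SaPIbov1 repressor Stl keeps its pathogenicity island silent until a
helper phage appears; the phage's dUTPase (Dut) then acts as the
antirepressor. Stl achieves breadth by substrate mimicry: its middle-domain
helix α8 inserts tyrosines and an aspartate into the Dut active site where
the dUTP substrate would sit, contacting the five conserved catalytic
motifs (I–V) of trimeric Duts — motif V being the flexible C-terminal
P-loop that normally closes over the bound nucleotide. Because monomeric
(herpesviral) Duts share the same catalytic chemistry, the same mimicry
lets Stl bind them too.

This package implements the quantitative layers of that analysis: rigid
superposition and RMSD, ligand-anchored transfer of a binder onto a new
receptor, interface-contact typing over the motifs, a family-conservation
pipeline, and 1:1 binding kinetics. This vignette records the models, the
tunable parameters, and the design decisions where the method itself left a
choice open.

## Rigid superposition (structcore)

Coordinates are Ångström in a right-handed frame; residue numbering is the
author numbering as deposited, because all residue-level statements in this
field ("R130 to G136", "D79 and Y82") use it. Superposition is classical
Kabsch: centre both paired coordinate sets, take the SVD of the
cross-covariance, and force a proper rotation (determinant +1) by
sign-flipping the smallest singular vector, so mirror solutions are never
returned. Degenerate (collinear) point sets leave the rotation
under-determined and raise an error rather than returning an arbitrary fit.

Atom pairing has three modes. `residue_number` pairs CA atoms on equal
(residue number, insertion code) and is what crystallographers use between
isomorphous chains. `atom_name` pairs atoms of two single residues and is
the anchor mode for ligands. `sequence_alignment` extracts residue
sequences, aligns them globally (BLOSUM62, gap opening 10, extension 0.5 —
conventional protein-alignment costs), and pairs CA atoms of gap-free
columns, substituted positions included; this mirrors how non-identical
Duts are compared. Waters and heteroatoms are excluded from polymer
selections by default; ligands are selected explicitly.

Parsing is first-model-only (the crystal structures in scope are
single-model); alternate locations resolve deterministically to the highest
occupancy with ties going to the first record in the file. The neighbour
search uses a uniform grid with cell size equal to the cutoff and is
contract-equivalent to the all-pairs scan — the test suite holds it to that
contract against an independent brute-force oracle.

## Ligand-anchored binder transfer (complex_transfer)

To place a binder (Stl) from a solved complex onto a new receptor (a
monomeric Dut) the pipeline chains two superpositions:

1. **T1** maps the reference receptor's ligand onto the target receptor's
   ligand, atoms paired by name with explicit aliases for analogue atoms
   (the α,β-imido nucleotide's bridging N pairs with dUTP's bridging O).
   This exploits the near-identical bound-nucleotide conformation across
   Dut families and carries the whole reference receptor into the target
   frame.
2. **T2** maps the solved complex's receptor onto the T1-placed reference
   receptor by CA pairing, carrying the binder with it. The reference
   receptor is then discarded; the output is the untouched target receptor
   plus the placed binder, with both component transforms, the ligand
   residual (`anchor_rmsd`) and the receptor residual (`receptor_rmsd`)
   recorded as provenance.

Receptor anchors with fewer than 50 CA pairs abort unless forced — below
that the placement is not meaningfully constrained for proteins of this
size. When the complex holds three binder copies (a Dut trimer binds three
Stl monomers), the transferred copy is selected by chain; the choice of
active centre is a flag, not a guess, because nothing in the underlying
analysis fixes it. One binder per monomeric receptor is assumed.

Force-field minimisation of the final model is deliberately replaced by
steric-clash assessment: the acceptance statement for such a model is the
absence of steric problems, which a van-der-Waals overlap criterion
measures directly without an external engine. A clash is a heavy-atom cross
pair closer than the sum of vdW radii minus a tolerance of 0.4 Å — the
common crystallographic convention. Radii: C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; unknown elements fall back to 1.70 Å with a warning. Hydrogens
are ignored throughout (the crystal structures lack them).

## Interface contacts and motif mimicry (interface_analysis)

Contact typing is distance-only, PISA-like, because the models carry no
hydrogens and angle terms would be fictions: within a 4.0 Å heavy-atom
cutoff a pair is a **salt bridge** if a charged-group nitrogen (Arg
NH1/NH2/NE, Lys NZ, His ND1/NE2) meets a carboxylate oxygen (Asp OD1/OD2,
Glu OE1/OE2) at ≤ 4.0 Å; otherwise a **hydrogen bond** if donor-capable and
acceptor-capable heavy atoms sit at ≤ 3.5 Å; otherwise a van-der-Waals
contact. His is counted as a potential salt-bridge donor (protonation
unknown at crystallographic pH) and such contacts carry a flag. All cutoffs
are configurable; the defaults reproduce the qualitative contact lists of
the field's interface tools.

Motif definitions ship as per-protein data files (mDut, hDut, ϕ11Dut,
EBVDut) rather than a sequence-pattern matcher: the exact interval edges
are a convention, but every key residue (e.g. hDut R62/S63 in motif II,
D79/Y82 in motif III, R105 in motif IV, D127–G136 in motif V) is validated
against the supplied sequence and a mismatch is an error naming the
residue. The monomeric EBV Dut arose by gene triplication with sequence
reshuffling, so its motif order along the chain is not I→V; its spec is
flagged accordingly. The mimicry report tallies contacts per motif, flags
which of I–V are touched, and summarises the Stl mimic residues Y105, Y106,
Y112, Y113, S114, Y116, D117 with their Dut partners.

## Family conservation pipeline (conservation)

The pipeline consumes an existing alignment; alignment construction itself
is an external, well-solved problem and is out of scope. Stages:

- **Length filter**, inclusive 125–225 residues: the Dut family's members
  fall mainly in this band; shorter entries are fragments, longer ones
  fusions.
- **Length modes**: a 5-residue histogram; local maxima holding > 5% of the
  sequences are modes, maxima closer than two bins merge into the taller.
  The 5% mass floor is this module's decision — the underlying observation
  is only that the family is bimodal near 150 (trimeric) and 190
  (monomeric + insertion-carrying trimeric) residues.
- **Greedy identity clustering** at 95%: sequences visited by decreasing
  length (a common convention, documented because the original clustering
  tool's parameters beyond the threshold are unstated); each joins the
  first representative it matches at ≥ 95% identity, else founds a
  cluster. Identity is exact matches over *all* columns of the global
  pairwise alignment, gaps included — the strictest deterministic choice;
  a coverage floor is exposed as a second knob since "identity coverage"
  is ambiguous.
- **gappyout-style trimming**: per-column gap fractions are sorted and a
  three-point slope scan over the sorted curve locates the steepest window;
  columns gappier than the window centre are removed, provided the curve
  shows a clear break (largest consecutive jump ≥ 0.2 and at least twice
  the mean jump) so smooth gap distributions are left untouched. All-gap
  columns are always removed; gap-free columns never. The rule is applied
  to a fixed point, which makes the operation idempotent by construction.
  The published heuristic's exact internals are not printed anywhere in
  scope, so this deterministic variant is documented here and held, in the
  tests, to an independently coded implementation of the same stated rule.
- **Logo profile**: per-column frequencies over the 20 amino acids among
  non-gap residues; information content log₂20 − H − e_n with the standard
  small-sample correction e_n = 19/(2·ln2·n), clamped at 0. The
  HMM-weighted variant used by logo webservers is not replicated — no HMM
  is in scope — so absolute bit values differ slightly from such renderers
  while the conservation ranking does not.
- **Motif conservation**: a named column is "highly conserved" when its
  modal residue reaches a configurable frequency threshold (default 0.5).

## 1:1 binding kinetics (kinetics)

The BLI model is plain 1:1 Langmuir binding — mass-transport, avidity and
drift terms are deliberately omitted, matching the instrument analysis it
re-implements:

\[
R(t) = R_{eq}\,(1 - e^{-k_{obs} t}),\quad k_{obs} = k_{on} C + k_{off},
\quad R_{eq} = \frac{R_{max} C}{C + K_D},\qquad
R(t) = R(t_{assoc}) e^{-k_{off}(t - t_{assoc})}
\]

Defaults mirror the capture protocol: 120 s association, 120 s
dissociation, 0.5 s sampling, analyte ladder 218.7 nM in seven serial
one-half dilutions. The global fit shares (k_on, k_off, R_max) across the
ladder — one loaded sensor per series — with per-curve R_max behind a
flag.

Numerically, the model is linear in R_max, so the fit uses variable
projection: for any (k_on, k_off) the optimal amplitude has a closed form,
and Levenberg–Marquardt searches only over log₁₀ k_on and log₁₀ k_off.
This keeps slow-dissociation series (where a naive 3-parameter search can
drift into a k_off ≈ 0 plateau) well conditioned. Starting values: k_off
from the log-linear tail of the highest-concentration dissociation, k_on
from regressing per-curve observed rates on concentration. The pooled R² is
reported against the grand mean; 0.95 is the conventional goodness floor
for accepting a fit.

The enzyme-assay module converts A630 to Pi through an ordinary
least-squares standard curve, takes initial rates as slopes over the linear
0–5 min window, and reports 100·(1 − v_inhibited/v_free). The result is
invariant to rescaling the standard curve, as units must cancel.

The His→Phe mutant of the M. tuberculosis Dut appears in the source
literature under two numberings (H135F in prose, H145F in the kinetics
table); the package records them as one entity, `mdut_h145f`.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of (spec, seed) and its ground truth is
returned alongside the data, so consuming modules can be tested exactly.

- **Toy complexes**: receptor chains are ideal α-helical CA traces (2.3 Å
  radius, 1.5 Å rise, 100°/residue — the CA geometry implied by φ/ψ =
  −57/−47) arranged around a small rigid mixed-element ligand, with a
  binder helix placed at a stated closest-approach distance (3.5 Å
  default, clash-free by construction). A full-backbone build from
  dihedrals was considered and rejected: the consuming stages (CA pairing,
  clash scoring, contact counting) use nothing a backbone would add. The
  toys do not mimic real Dut folds; passing transfer tests demonstrates
  exactness of the geometry pipeline, not biological realism.
- **Sequence families**: a conserved 125-column core from a random
  ancestor (background per-column identity 0.3), planted motif columns at
  stated conservation (default 0.9), mode-specific insertion lengths
  giving the bimodal 150/190 length mixture (weights 0.6/0.4, SD 5), a 2%
  fraction of fragments/fusions to exercise the length filter, and
  rare-insertion columns (occupancy 0.02) at a 5% rate standing in for the
  mostly-empty alignment columns that motivate trimming. The aligned
  variant covers the core — insertions live outside it, as they would
  after building a family alignment on the conserved domain. No
  phylogenetic correlation structure is modelled, so tests show estimator
  correctness under independence, not robustness to tree-structured
  redundancy (that is what the 95% clustering step is for on real data).
- **Sensorgrams and assays**: exact model curves plus additive Gaussian
  noise; planted rates map through a linear standard curve. Instrument
  artefacts (drift, jumps, depletion) are intentionally absent.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: sensorgram
series of 7 × 482 points, 50-replicate noise-recovery studies at σ = 2% of
R_max, families of 200–1000 sequences, 100-seed transfer-recovery and
oracle sweeps. These sizes were chosen so the full suite exercises every
statistical claim in minutes on a laptop while keeping Monte-Carlo noise
well inside the asserted bands.

## Known limitations

- mmCIF reading covers the `atom_site` loop (coordinates, occupancies,
  elements, models) — not the full dictionary.
- No force-field energetics anywhere: a clash-free model is a necessary,
  not sufficient, condition for a plausible complex.
- Contact typing has no angular terms; reported H-bonds are
  distance-compatible donor/acceptor pairs.
- The conservation logo is unweighted by sequence similarity beyond the
  clustering step.
- Accession-dependent reproductions (asymmetric-unit RMSDs, the
  monomeric-Dut transfer model on real structures) run only when the user
  supplies the PDB entries locally; the package performs no downloads.
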