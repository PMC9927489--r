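# dutstl

Structural and kinetic analysis of how the SaPIbov1 master repressor **Stl**
recognises and inhibits **dUTPases (Duts)**.

Stl derepresses its pathogenicity island by binding the dUTPase of a helper
phage — and it does so by *mimicking the dUTP substrate*, which lets one
repressor inhibit trimeric, dimeric and even monomeric Duts from phages,
bacteria, humans and herpesviruses. This package re-implements the
computational analyses behind that picture as a tested, reusable pipeline
for structural bioinformaticians and biophysicists:

- **structcore** — PDB/mmCIF reading, atom selection, Kabsch rigid-body
  superposition and RMSD, fast cross-group neighbour search;
- **complex transfer** — ligand-anchored placement of a binding partner onto
  a new receptor (how an Stl–monomeric-Dut model is built from the solved
  trimeric complexes), with van-der-Waals clash scoring in place of force-field
  minimisation;
- **interface analysis** — typed Dut–Stl contacts (van der Waals, H-bond,
  salt bridge) mapped onto the five catalytic motifs I–V of trimeric Duts,
  plus the Stl substrate-mimicry residue summary (Y105/Y106/Y112/Y113/S114/Y116/D117);
- **conservation** — the Dut-family sequence pipeline: inclusive 125–225
  length filter, length-mode (bimodality) detection, greedy 95%-identity
  clustering, gappyout-style alignment trimming, and information-content
  logos with per-motif conservation calls;
- **kinetics** — 1:1 Langmuir BLI model: sensorgram simulation, global
  (k_on, k_off, R_max)-shared fitting with
  K_D = k_off/k_on, and malachite-green enzyme-assay analysis
  (standard curve, initial rates, % inhibition);
- **synthetic data** — seeded generators for every fixture class (toy
  receptor–ligand–binder complexes with exact ground truth, motif-bearing
  bimodal sequence families, noisy sensorgrams, assay time courses), so the
  whole pipeline is testable offline.

## The model at the core

Association and dissociation of a 1:1 complex follow

```
R(t) = R_eq (1 - exp(-k_obs t)),   k_obs = k_on C + k_off,
R_eq = R_max C / (C + K_D),        K_D = k_off / k_on,
R(t > t_assoc) = R(t_assoc) exp(-k_off (t - t_assoc))
```

and the geometric stages rest on least-squares rigid superposition
(Kabsch/SVD with a determinant-+1 guard) of paired atom sets.

## Worked example

Simulate a noise-free BLI series from the published phage ϕ11 Dut rate
constants (k_on = 2.84×10⁵ M⁻¹s⁻¹, k_off = 2.25×10⁻³ s⁻¹) over the
half-dilution ladder 218.7 → 3.4 nM, then refit the 1:1 model globally:

```r
library(dutstl)
p     <- kinetic_params(k_on = 2.84e5, k_off = 2.25e-3, r_max = 1)
grams <- make_sensorgrams(p)            # 7 curves, 120 s + 120 s at 0.5 s
fit   <- fit_one_to_one(grams)
dissociation_constant(fit$params)
#> [1] 7.922535
fit$r_squared
#> [1] 1
```

The fitted K_D of 7.92 nM matches the printed 7.94 nM to better than 1%
(the gap is the rounding of the printed rate constants). The same
simulate-and-refit loop over all four Duts reproduces 39.06 (mDut), 12.45
(mDut H145F), 34.65 (hDut) and 7.92 (ϕ11Dut) nM — the mutant binds ~3.1×
tighter than wild-type mDut (the motif-V His→Phe gain of function), and the
human Dut sits within 5× of the phage Dut.

A structural stage on synthetic ground truth:

```r
toy   <- make_toy_complex(toy_complex_spec(seed = 1))
model <- build_transfer_model(
  toy$target, toy$reference, toy$complex,
  target_ligand = list(chains = "X"), ref_ligand = list(chains = "X"),
  receptor_chains = c("A", "B", "C"), binder_chains = "Z")
max(abs(atom_coords(model$binder) - toy$truth$binder_coords))
#> [1] 1.421085e-14
detect_clashes(model$receptor, model$binder)
#> clash_report: 0 clash(es) at tolerance 0.4 A
```

A shell entry point wraps every stage
(`system.file("cli", "structkit", package = "dutstl")`):
`structkit superpose|transfer|contacts|conserve|blisim|blifit|inhibition|fixtures|reproduce`.

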