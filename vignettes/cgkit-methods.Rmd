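---
title: "Coarse-grained modeling of protein-responsive polypeptide nanoassemblies with cgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modeling of protein-responsive polypeptide nanoassemblies with cgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgkit)
```

## The system

P1 is an amphiphilic random copolypeptide built from three substituted
glutamic-acid monomers: hydrophobic **M1**, hydrophilic oligoethylene-glycol
**M2**, and **M3**, which carries an OEG spacer ending in a
benzene-sulfonamide ligand that bovine carbonic anhydrase II (bCA-II)
recognises at its Zn site. In water, P1 unimers assemble into micelles with
an M1 core, a backbone shell and M3 ligands on the surface; micelles then
aggregate into multicore nanoparticles that encapsulate hydrophobic cargo
such as the carbocyanine dye DiI. Specific bCA-II binding to the surface
ligands destabilises the aggregate and drives a stepwise disassembly that
ultimately exposes the cargo.

`cgkit` implements the modelling side of this story: Martini-3-style
coarse-grained (CG) topologies for P1 and DiI, the force-field modifications
that encode the specific Zn-sulfonamide interaction, construction of
simulation systems for the three phases (self-assembly, cargo loading,
protein-triggered disassembly), and the full trajectory-analysis suite. A
fixture generator produces synthetic bead configurations with the structural
motifs of interest, so the analysis code is tested end to end without
running microsecond molecular dynamics.

## The CG model

Beads follow Martini 3 size classes: regular, small and tiny beads map 4, 3
and 2 heavy atoms and weigh 72, 54 and 36 u. Each P1 chain carries 5–6 M1,
exactly 4 M2 and 1–2 M3 monomers — 10–12 monomers in total, consistent with
the experimental 11 ± 4 monomers and the 0.48 : 0.37 : 0.15 molar ratio.
Monomer order is uniformly shuffled per chain (P1 is a random copolymer; no
block structure is imposed). The default four-chain set cycles through the
compositions (5,4,1), (6,4,2), (5,4,2), (6,4,1), so the mean chain length is
exactly 11 monomers; the exact experimental sequences are not public, so a
seeded generator under the stated bounds stands in.

The disordered backbone uses coil-type P2 beads. Non-standard typing is
confined to three sites, each motivated by resonance or enhanced
hydrophilicity:

| site | default (nonstandard) | strict Martini 3 |
|---|---|---|
| M3 backbone amide | P3 | P2 |
| M3 benzene-sulfonamide anchor | TN6d | TC5 |
| DiI conjugated linker | TN6d | TC1 |

`variant_overrides()` is the single source of truth for this table; the
`strict_standard` variant differs from the default in exactly these three
type labels and nothing else, which the test suite asserts. The terminal
sulfonamide of M3 is one highly polar regular P6 bead (4 heavy atoms:
S, O, O, N) — the specific binding site. The M3 backbone amide is the single
documented exception to the size-class mapping (6 heavy atoms on one regular
bead), which keeps the downstream OEG segment intact as a hydrophilic unit.

DiI carries its +1 formal charge as two +0.5 partial charges on the two
nitrogen-bearing headgroup beads, reflecting the resonant carbocyanine
charge distribution. Reading the headgroup off the mapping figure involves a
judgement call; the shipped template uses seven headgroup beads (two charged
SN6, four TC5 ring beads, one TN6d methine linker) and two equal four-bead
C1 tails. With the default SASA radii this headgroup measures ≈ 476 Å²
isolated, consistent with the ~500 Å² scale expected for the solvated dye.

**Bonded parameters.** The reference workflow measures bond lengths from
energy-minimised all-atom structures; those structures are not shipped, so
`assign_bonded_parameters()` accepts a user distance table or coordinate set
and falls back to a versioned default table (lengths 2.8–3.5 Å by size-class
pair; bond k 2.99 kcal/mol/Å² ≡ 1250 kJ/mol/nm², angle k 5.98 kcal/mol ≡
25 kJ/mol — Martini-typical values, flagged as assumptions because no force
constants are printed in the protocol).

**Units.** Internally everything is Å and kcal/mol, the units the protocol
quotes; `write_topology()`, `write_nonbond_params()` and `write_mdp()`
convert to the GROMACS convention (nm, kJ/mol, ps; 4.184 kJ per kcal,
exact). Readers invert the conversion, and round-trips are tested to 1e-6
relative error.

## Force-field patches

Three modifications, applied by `ff_patch` functions to a nonbonded
parameter table:

1. **Protein–water scaling** (`scale_protein_water()`): every protein bead
   type X is duplicated as WX with all self/cross LJ rows copied (TP1-TP1 →
   WTP1-WTP1 and WTP1-TP1), then ε(WX–W) is multiplied by 1.10. This is the
   standard remedy for spurious Martini protein self-aggregation. Only ε is
   scaled: "interaction strength" is the LJ well depth, and σ is geometry,
   not strength.
2. **Zn–ligand cross term** (`add_zn_ligand_crossterm()`): one LJ override
   between the Zn bead and the terminal P6 sulfonamide bead with σ = 5 Å and
   ε = 15 kcal/mol (62.76 kJ/mol in file units), comparable to the 4–6 Å
   Zn–ligand distance in bound structures and the 10–12 kcal/mol binding
   free energy of benzene-sulfonamide analogues. The potential minimum sits
   at 2^(1/6)·σ ≈ 5.61 Å.
3. **Zn coordination** (`add_zn_coordination()`): three harmonic bonds of
   length 2.4 Å from the Zn bead to the side chains of the coordinating
   histidines (H93, H95, H188 in bCA-II numbering), with the Zn bead typed
   SD (the Ca²⁺ type; Martini has no Zn default) and mass 65.4 u. No force
   constant is printed anywhere; the default 50 kcal/mol/Å² keeps the
   thermal bond-length fluctuation near 0.08 Å at 303 K, far below 2.4 Å.

All three patches are idempotent and leave untargeted rows untouched; both
properties are tested. A minimal synthetic Zn-protein stand-in
(`make_synthetic_zn_protein()`) ships so the patching and placement
machinery is testable without a real protein structure — it is a labelled
bead cloud, not a CG bCA-II model.

## System construction

`place_unimers()` initialises self-assembly systems: chains drawn 2:1:1:1
across the four standard sequences (largest-remainder apportionment, so the
ratio is exact whenever n is a multiple of 5), random conformations and
orientations, uniform positions, and a minimum intermolecular bead
separation enforced under the periodic minimum image. The default
`min_sep = 3.5` Å is a choice (no value is printed); the retry budget is
10⁴ per molecule, after which a larger box is suggested.
`insert_cargo()` adds DiI at random positions outside the assembly's
bounding sphere — cargo starts in the bulk. `place_proteins_near_ligands()`
puts each protein's Zn bead within 5–10 Å of a distinct *exposed*
benzene-sulfonamide anchor; "exposed" means anchor SASA > 10 Å², a
criterion this package defines because the protocol states the placement
window but not the exposure test.

`emit_run_parameters()` reproduces the run protocol field for field:
10 fs timestep, neighbour list every 20 steps, 1.1 nm LJ and
reaction-field cutoffs with ε_r = 15, Berendsen thermostat at 303 K
(τ_T = 0.5 ps; kept despite its known sampling artifacts — fidelity to the
stated protocol over best practice), Parrinello-Rahman barostat at 1 bar
(4.5 × 10⁻⁵ bar⁻¹, τ_p = 4.0 ps), 5000 steepest-descent minimisation steps,
and 200 ps equilibration with 0.1 kcal/mol/Å² positional restraints.
Solvation is bookkeeping only: water bead counts come from box free volume
at the standard CG water density (8.35 beads/nm³) and counter-ions
neutralise the net solute charge exactly; the MD engine equilibrates actual
solvent. Box sizes are not printed in the protocol, so defaults scale with
molecule count (one chain per (35 Å)³).

## Trajectory analysis

**Aggregation clustering.** DBSCAN over entities — whole polymers or
individual M1 side chains — with eps = 8 Å, min_samples = 5, and the metric
defined as the minimum bead–bead minimum-image distance between entities.
min_samples counts the point itself (the scikit-learn convention the
original analysis used). Noise entities get an `NA` label, so a fully
dispersed frame has 0 clusters. Border-point ties are broken
deterministically in entity-index order. No R DBSCAN implementation was
available, so the algorithm is implemented here and validated against
threshold-graph connected components (igraph) on instances where the two
provably coincide: every cluster ≥ min_samples and no borderline chains.
`micelle_core_sizes()` histograms M1-side-chain cluster sizes — the
per-core hydrophobic population.

**Cylindrical density profile.** A 6 Å-diameter cylinder along the x axis
through the aggregate centre of mass; beads within 3 Å radial distance are
histogrammed in 0.5 Å bins and averaged over a trailing window (default
50 ns where timestamps allow). Bin counts sum to the mean in-cylinder bead
count by construction.

**Shape metrics.** The unweighted gyration tensor
S<sub>αβ</sub> = Σᵢ (r<sub>αi</sub> − r<sub>α</sub><sup>com</sup>)(r<sub>βi</sub> − r<sub>β</sub><sup>com</sup>)
with eigenvalues λ₁ ≤ λ₂ ≤ λ₃ gives asphericity
a = [(λ₂−λ₁)² + (λ₃−λ₁)² + (λ₃−λ₂)²] / [2(λ₁+λ₂+λ₃)²] ∈ [0, 1]
and prolateness
p = (2λ₁−λ₂−λ₃)(2λ₂−λ₁−λ₃)(2λ₃−λ₁−λ₂) / [2(λ₁²+λ₂²+λ₃²−λ₁λ₂−λ₁λ₃−λ₂λ₃)^{3/2}] ∈ [−1, 1].
The 3/2-power normalisation was verified on archetypes before freezing the
sign convention: exact axis constructions give p = +1 for prolate
(λ₁ = λ₂ < λ₃), p = −1 for oblate (λ₁ < λ₂ = λ₃), and a = 1 for collinear
points, so the formulas are implemented exactly as stated. When all three
eigenvalues coincide, p is 0/0; `gyration_shape()` returns 0 with a
`degenerate` flag, since a sphere is neither prolate nor oblate. Near-spherical
(but not exactly degenerate) clouds have ill-conditioned p — a known property
of the descriptor, not a numerical defect. The tensor is applied unweighted
to whatever bead selection is passed, single polymer or whole aggregate.

**SASA.** Shrake-Rupley quadrature on CG beads: each target bead's expanded
sphere (bead radius + probe) is sampled with a deterministic golden-spiral
point set (512 points/bead by default); points inside any other bead's
expanded sphere are inaccessible. An isolated bead returns its closed-form
area exactly. Default radii are half the Martini size-class σ (2.35 / 2.05 /
1.70 Å) with a 1.4 Å water-sized probe — no CG SASA convention is universal,
which is why headgroup-scale comparisons carry a ±25% band. The
implementation agrees with an independent randomised quadrature at 10× point
density to better than 2% on bead toys, and is monotone non-increasing as
occluders accumulate.

```{r shape-demo}
tidy(gyration_shape(make_shape_cloud("prolate", n = 60, seed = 1)))
```

## Fixtures: what they do and do not show

`make_micelle()` places beads directly into the three-layer geometry (M1
side chains inside the 15 Å core with a centre-weighted radial distribution,
backbones in the 15–22 Å shell, M3 anchors and terminal sulfonamides at the
27 Å surface; M2 mixed through core and shell). The 15/22/27 Å defaults
match the ~5 nm micelle scale of the bCA-II-sized assemblies.
`make_multicore_aggregate()` rows micelles up with interpenetrating shells
(default centre spacing = core + shell radius) so whole-polymer clustering
sees one aggregate while M1 cores stay > 8 Å apart; the bridged variant
threads dense chains of M1 entities between cores — dense enough that every
bridge entity is a DBSCAN core point, because border points alone cannot
merge clusters. `make_disassembly_series()` detaches whole micelles
stepwise with ≥ 46 Å gaps so the largest-cluster series follows the
requested step sizes exactly. `make_cargo_states()` encloses DiI in a
watertight simple-cubic shell of M1 beads (2.9 Å spacing — lattice gaps are
smaller than the smallest expanded-sphere coverage radius, so no quadrature
point leaks) for the buried state, or buries only the tails for the exposed
state.

These are geometric stand-ins validated by brute-force oracles, not
thermodynamic configurations. Passing tests demonstrate that the analyses
measure what they claim on known geometry; they say nothing about whether
microsecond MD of this force field reproduces the experimental assembly
statistics (peak cluster counts, micelle size distributions, disassembly
kinetics), which are outside what desk-scale computation can verify.

## Numerical choices and limitations

* Problem sizes in the tests — micelles of 10–20 polymers, aggregates of up
  to 80, 10⁴-cloud invariance sweeps, 25-frame noise trajectories — were
  chosen as the smallest sizes at which each property is unambiguous.
* Eigen-decomposition round-off can produce tiny negative eigenvalues for
  rank-deficient tensors; values above −10⁻⁹·λ₃ are clipped to zero.
* The degenerate-prolateness threshold is 10⁻¹² · λ₃² on the denominator.
* PBC: entity distances use the minimum image in orthorhombic boxes;
  triclinic boxes are not supported.
* The synthetic protein stand-in has no realistic fold; Zn-site patching on
  real CG protein topologies requires the user to supply them (conversion of
  atomistic protein structures to CG is out of scope).
* The uniformity check for placements is statistical (χ² over octants at a
  fixed seed), as any test of randomness must be.
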