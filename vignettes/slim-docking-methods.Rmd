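---
title: "Modelling SLiM-mediated protein-protein interactions with slimdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SLiM-mediated protein-protein interactions with slimdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimdock)
```

## The modelling problem

Many protein-protein interactions are not mediated by two large, rigid
interfaces but by a **short linear motif (SLiM)**: a contiguous peptide
segment, typically around ten residues, of one partner (here called the
*partner protein*) that binds a well-defined site on the other (the
*receptor*) and contributes the bulk of the binding energy. This suggests a
divide-and-conquer route to modelling the full complex:

1. **Dock the motif alone.** The motif *sequence* is treated as a fully
   flexible peptide and docked over the entire receptor surface by
   coarse-grained replica exchange Monte Carlo (REMC), with the receptor
   held near its input conformation by distance restraints. Only the
   sequence enters the docking; any known bound-state coordinates of the
   peptide are reserved for evaluation.
2. **Rebuild the complex.** The full partner protein is superposed, by an
   RMSD-minimizing rigid fit on the motif's CA atoms, onto the best docked
   peptide pose, which places the whole protein without docking it.
3. **Screen the interface.** In place of external all-atom refinement,
   the rebuilt interface is screened for steric clashes; the complex can
   then be handed to any refinement tool the user prefers.

The package implements all three stages plus the evaluation metrics used to
judge them (contact maps, fraction of native contacts, interface RMSD), and
a synthetic-fixture generator so the entire protocol runs and is tested
without any external structure download.

## Coarse-grained representation

Each residue is reduced to up to four pseudo-atoms: the alpha carbon (CA),
the beta carbon (CB), a united side chain (SC) and the peptide-bond center
(PB). From all-atom input, SC is the centroid of all side-chain heavy
atoms (CB included, so alanine's SC *is* its CB; glycine has neither CB nor
SC and interacts through its CA), CB is rebuilt from N/CA/C ideal
tetrahedral geometry when missing, and PB is the midpoint of C(i) and
N(i+1). The model is **off-lattice**: continuous coordinates with a
virtual CA-CA bond of 3.8 Å. Chains whose consecutive CA distances fall
outside [3.2, 4.3] Å are rejected as broken; the window leaves room for
cis-peptides and experimental noise.

For peptides built from sequence alone there are no side-chain atoms to
average, so SC (and CB) are placed along the local bisector of the two
virtual bonds at a per-residue-type typical CA-centroid distance; for a
CA-only trace PB degenerates to the virtual-bond midpoint. The same
derivation rule is used by the sampler whenever a CA moves, so a peptide
conformation is fully described by its CA trace.

A deliberate asymmetry: re-coarse-graining a backbone-level (CA/CB-only)
file raises an error rather than silently collapsing SC onto CB, because a
potential evaluated on such degenerate side chains would be garbage with no
visible symptom.

## The surrogate potential

The docking engine needs a potential with a few specific properties --
residue-type-specific inter-chain attraction, hard-core repulsion, chain
connectivity, receptor restraints -- rather than any particular published
parameterization. The package therefore uses a transparent knowledge-based
surrogate in which **every constant is configuration**
(`energy_model()`):

| term | form | default |
|---|---|---|
| contact | table value per inter-chain SC-SC pair within radius | 20×20 table, 6.5 Å |
| excluded volume | quadratic penalty below hard radius, CA/SC pairs | 3.5 Å, weight 1 |
| bond geometry | harmonic on consecutive CA-CA | target 3.8 Å, weight 5 |
| receptor restraints | flat-bottom harmonic on CA pairs | δ = 1 Å, k = 1 |
| confinement | quadratic beyond a sphere around the receptor | radius + 25 Å |

The shipped default contact table (a plain-text CSV under `extdata`,
user-replaceable) is a hydrophobicity outer product: `e_ij = -q_i q_j`
with `q` an affinely rescaled Kyte-Doolittle scale. This is the rank-one
structure that dominates statistical contact potentials -- hydrophobic
pairs attract (I-I ≈ -1.96, L-L ≈ -1.67), polar pairs are neutral -- and
is easy to reason about in tests. Three scoping choices are worth
spelling out:

* the **contact term is inter-chain only**; intra-peptide packing is
  governed by excluded volume and the bond term. This keeps the docking
  funnel a function of peptide placement rather than peptide collapse.
* **excluded volume acts on CA and SC sites only.** CB lies between CA and
  SC and PB lies on the virtual bond, so both are sterically inside the
  CA/SC envelope; including them would double the cost of every move for
  no discriminative gain.
* the **confinement sphere** (soft wall at receptor radius + 25 Å by
  default) is not part of the physical model; it prevents an unbound
  peptide from diffusing away during the early high-temperature phase.
  Its contribution is zero whenever the peptide is anywhere near the
  receptor.

Receptor restraints follow common near-native practice: every CA pair with
sequence separation ≥ 5 and starting distance in [5, 15] Å receives a
flat-bottom harmonic centred on the starting distance, so the restraint
energy of the input conformation is exactly zero. The receptor's bond
term is likewise referenced to its own starting bond lengths.

## Sampling

REMC with a geometric temperature ladder, by default T ∈ [1.0, 3.0]
(dimensionless) over 10 replicas, exchange attempted every 10 sweeps with
alternating even/odd pairing and the standard acceptance
`min(1, exp(Δβ·ΔE))`. The move set mixes rigid-body peptide moves
(translation ≤ 2 Å, rotation ≤ 30°), local peptide moves (single-CA
displacement ≤ 1 Å with SC re-derivation, two-bond crankshaft, end pivot)
and small receptor CA displacements (≤ 0.5 Å). All proposals are
symmetric, so the Metropolis rule alone preserves detailed balance; the
test suite checks the two-level-system occupancy ratio and the empirical
acceptance rate against `exp(-ΔE/T)`.

One root seed drives everything. Each replica owns a private
L'Ecuyer-CMRG stream (plus one stream for exchange decisions), so a
replica's trajectory is reproducible independently of how many replicas
run, and reruns with the same configuration are bit-identical. Energies
are tracked incrementally (each move evaluates only the terms touching the
moved residues) and must agree with a from-scratch recomputation to 1e-6
at every snapshot -- this invariant is tested, not assumed.

The protocol-level counts are the method's fixed points: 10 replicas, one
random self-avoiding peptide conformation each, placed at random
orientations and directions with the minimum pseudo-atom distance to the
receptor equal to 20 Å (bisection to ±0.1 Å); 1000 snapshots per replica
(10,000 models); 100 lowest-energy states per replica selected (1000
poses); k-medoids clustering under L-RMSD; 10 representatives of the 10
densest clusters. The Monte Carlo *schedule* between those fixed points
(sweeps between snapshots, ladder bounds, exchange cadence, move
amplitudes) is this package's own configuration with documented defaults,
chosen so that a default run on the bundled synthetic system finishes in
minutes on one CPU.

## Pose selection

L-RMSD -- the RMSD over peptide CA atoms after superposing the receptor,
with no further fitting of the peptide -- is the clustering distance.
Because every snapshot's receptor is first superposed onto the starting
receptor (the receptor does move a little under its restraints), all poses
share one frame and the full distance matrix reduces to scaled Euclidean
distances between flattened coordinate rows, i.e. a single `dist()` call
even for the default 1000×1000 matrix.

The k-medoids clustering is seeded k-means++-style on the distance matrix
and then alternates nearest-medoid assignment with medoid updates until
the medoid set is stable (iteration-capped at 100); the total
distance-to-medoid cost is non-increasing, ties go to the lower index, and
a medoid is always its own nearest medoid so clusters cannot empty. The
test suite cross-checks the achieved cost against `cluster::pam` and
against exhaustive medoid enumeration on small instances.

Clusters are ranked by **density** = members / mean pairwise L-RMSD. A
single-member cluster has no pairwise distances; it is given infinite
density and therefore ranks first. This sentinel is deliberate: a
singleton in a k = 10 partition of 1000 poses is an extremely tight,
isolated candidate and hiding it would be worse than over-ranking it.
Ties are broken by larger membership, then lower medoid energy.

## Assembly and evaluation

Complex reconstruction fits the CA atoms of the partner's motif residues
onto the docked pose's CA trace (CA is the currency both representations
share), with the Kabsch SVD solution and the determinant correction that
excludes reflections; collinear fit sets are rejected as degenerate. The
resulting rigid transform is applied to the entire partner chain; the
receptor is passed through bitwise untouched. By default the rank-1 model
is assembled; any rank can be selected, mirroring the fact that with a
reference in hand one would pick the best of the 10 representatives.

Evaluation follows the standard interface metrics, all based on minimum
heavy-atom distances with a strict `<` at the cutoff (the convention is
documented because "within" is ambiguous at the boundary):

* **contact map**: residue pairs closer than 8 Å;
* **fNC**: native contacts reproduced by the model divided by all native
  contacts; when the model contains only the motif (a docked pose), the
  native set is restricted to the motif region, matching how a pose can
  reproduce "its" native contacts only;
* **interface**: the motif plus receptor residues within 4.5 Å of it,
  defined on the reference;
* **iRMSD**: CA RMSD over the interface set after least-squares fitting
  the model's interface CA atoms onto the reference's. The wording "RMSD
  of the interface CA atoms" admits either fitting on the interface
  itself or on the whole receptor; the interface fit is the default and
  the receptor fit is exposed via `fit = "receptor"`.

Residue correspondence between model and reference is by chain, author
number and insertion code only -- no sequence-alignment fallback.

## The synthetic benchmark

`make_toy_complex()` builds a deterministic miniature of a SLiM-mediated
complex: a receptor folded into two antiparallel strands joined by a
circular-arc turn (consecutive CA distances exactly 3.8 Å), enclosing an
open channel ~10 Å wide, and a motif peptide laid along the channel
mid-line with glycine flanks rising out of the channel to form the partner
chain. Side chains are reduced (CB plus one dummy side-chain atom), which
is enough to exercise every heavy-atom distance rule without a rotamer
library. Three design details matter for testing:

* **registry encoding.** The default motif has eight all-distinct residue
  types, and every receptor residue in actual reference contact (at the
  8 Å definition) is assigned the type of its nearest motif residue; all
  other residues are serine. The planted contact list is the realized
  contact map, verified with the package's own `contact_map()` before the
  fixture is handed out, and the engineered table built from it
  (`funnel_energy_table()`: -2.0 for planted type pairs, 0 elsewhere)
  makes the designed registry the global minimum: on the bundled 30-residue
  system the designed pose scores about -75 against -71 for a one-step
  registry shift (within 5 Å L-RMSD of the designed pose) and -55 or worse
  for anything farther.
* **broken symmetries.** The planar fold would make poses mirrored through
  the strand plane energetically degenerate, so the channel-lining side
  chains are tilted toward the peptide side; and a perfectly straight
  motif trace would make the assembly fit degenerate, so the designed
  trace carries a small z zig-zag.
* **self-verification.** A fixture spec carrying an explicit planted
  contact list is rebuilt only if the construction realizes it exactly;
  flank/receptor steric overlap aborts construction.

What these fixtures do **not** emulate: real side-chain rotamers,
Ramachandran statistics, solvent, crystallographic noise, or the size of a
real receptor (hundreds of residues). Passing the funnel-recovery test
therefore shows that the sampler, selection and ranking machinery find and
keep a designed energy minimum -- it does not certify docking accuracy on
real proteins, which depends on the force field a user supplies.

## Problem sizes and numerical choices

The default test and benchmark sizes are a 30-36-residue receptor with an
8-mer motif: large enough that the peptide must search a genuinely 3-D
volume (the confinement sphere is ~40 Å in radius), small enough that a
full 10 × 1000 protocol run completes in a few minutes on one CPU. The
funnel-recovery check uses 200 snapshots per replica with 5 sweeps between
snapshots and a slightly colder ladder (t_min = 0.6) and stronger
translations (3 Å), which repeated trials showed is enough schedule for
the deep engineered funnel; the protocol-scale run in the acceptance
script keeps the full 1000 snapshots per replica.

Other numerical choices: placement solves for the 20 Å surface distance by
bisection to 0.05 Å; altloc resolution keeps the highest occupancy with
ties broken by altloc letter; non-standard residues are retained with
one-letter code `X` and excluded from contact energetics (no table row);
k-medoids ties (assignment and medoid updates) go to the lower index so
clustering is deterministic given its seed; the single-member cluster
density sentinel defaults to `Inf` and can be capped with the
`singleton_density` argument when stray lone poses should not outrank
large tight clusters.

## Limitations

* The potential is a surrogate: it reproduces the *shape* of a
  knowledge-based docking energy, not any published parameter set.
  Everything downstream of the energy (sampling, selection, assembly,
  metrics) is independent of this choice, and the table is replaceable.
* Domain-scale conformational change of the receptor is out of scope: the
  restraints are designed to keep the receptor near-native.
* No all-atom reconstruction or refinement: exported models are CA/CB
  backbone-level PDB files flagged as coarse; the clash report marks where
  a refiner would have to work.
* The L-RMSD frame assumes the receptor stays superposable on its input
  (true under the default restraints; unrestrained receptors would need a
  different alignment strategy).
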