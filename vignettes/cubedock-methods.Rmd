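---
title: "Symmetric assembly docking in cubedock: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric assembly docking in cubedock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Homomeric complexes with cubic symmetry — tetrahedral (T), octahedral (O)
and icosahedral (I) rotational point groups, with 12, 24 and 60 chains in
the simplest homomeric case — form closed spherical shells. Structure
predictors produce accurate subunits and small oligomeric subcomponents
but not the full shell. Under an exact point-group constraint the shell
is determined by one subunit and six rigid-body degrees of freedom, so
assembly prediction becomes a six-dimensional global optimization over a
placement, plus a discrete choice of subunit backbone from an ensemble.

`cubedock` parametrizes the placement as follows (all conventions fixed
for reproducibility):

* the *setup-fold* axis — the n-fold axis the parametrization is built
  around — is the global z axis; the point group is conjugated so one of
  its canonical n-fold axes coincides with z (`oriented_group()`);
* the subunit is rotated by the intrinsic Z-Y-Z Euler angles (ψ, ϴ, φ)
  about its center of mass, translated so the COM sits at (x, 0, z),
  rotated by λ about z, and copied through every group rotation
  (`place_and_expand()`); chain 1 is the *main subunit*;
* group matrices are generated in standard orientations (octahedron on
  the coordinate axes; tetrahedron as the rotation subgroup of that
  frame; icosahedron with a 2-fold on z and a 5-fold axis in the xz
  plane, generated by closure of the two corresponding rotations) and
  ordered deterministically.

Two choices deserve emphasis because the published description leaves
them open. First, the Euler convention (intrinsic Z-Y-Z, degrees) and
the operation order (Euler → translate → λ → expansion) are this
package's definitions; parameter equivalence with any other
implementation is defined only up to regeneration of the same assembly,
which is how `extract_params()` is tested. Second, ZYZ angles double
cover the rotation group — (ψ, ϴ, φ) and (ψ±180°, −ϴ, φ±180°) are the
same rotation — so operations that re-derive angles from a matrix
(Cartesian sliding, symmetry analysis) select the representation nearest
the incoming values to keep the bounded parameters continuous.

## Scoring

The original method scores with the Rosetta REF2015 all-atom energy,
sidechain packing and gradient minimization. Those components are out of
scope here and are replaced by a documented surrogate; every *structural*
element of the algorithm (the six-parameter search, sliding, the memetic
loop, the CloudContactScore, subsystem evaluation, the selection funnel)
is implemented faithfully.

**CloudContactScore (CCS).** A subunit is reduced to a point cloud of
surface backbone and CB atoms: residues with more than 20 Å² SASA
(Shrake–Rupley, probe 1.4 Å, 960 deterministic spiral points — the "20 Å
SASA-value" of the source text is read as Å²) *or* classified as surface
by a sidechain-neighbor-cone rule (fewer than 12 CA→CB vectors inside a
60°/10 Å cone; the OR combination is a package decision, the original
tool's internals being unpublished) are kept, non-glycine surface
residues are reduced to alanine, and a second SASA pass removes buried
atoms. The score is

CCS = n_clashes · penalty + hbond_sr_bb + hbond_lr_bb − n_cb_cb_interactions

with: clashes when two Lennard-Jones spheres overlap by more than 20 %
(formalized as d < 0.8·(r_i + r_j) over the declared radii N 1.75, C/CA
2.0, O 1.55 Å), except N–O pairs which may hydrogen bond (clash below
1.2 Å) and CB spheres reduced to 1.5 Å; CB–CB contacts counted within
12 Å, each weighted by the product of the two connection densities
min(#internal CB neighbors within 12 Å / 20, 1) (the product form is a
package decision — the source says each CB's density weights the bonus);
and a surrogate backbone hydrogen bond (below). The per-clash penalty
(default 1000) makes any clash dominate any contact reward.

**Surrogate hydrogen bond.** REF2015's `hbond_sr_bb`/`hbond_lr_bb` terms
are replaced by a smooth geometric stand-in: a sin² distance window on
the N···O separation over [1.9, 3.2] Å attenuated by cos² of the angle
between the carbonyl C→O direction and the O→N vector, negative
favourable, split short/long range at a residue separation of 5. Only
the terms' role (rewarding backbone hydrogen bonds, split by range) is
preserved; absolute values are not comparable to Rosetta.

**Surrogate interface energy (Iscore).** Selection uses the interface
energy of the main subunit only — intra-subunit energy would bias
selection without improving the assembly. The surrogate is a sum over
main-subunit/neighbor atom pairs (backbone + CB points, all residues) of
a truncated-and-shifted soft Lennard-Jones (ε = 0.2, minimum at
r_i + r_j, capped at +10 per pair, cut at 12 Å), the surrogate hydrogen
bond, a smooth density-weighted CB contact reward (weight 0.5, switched
off between 8 and 12 Å), and 25 per CCS-defined clash. The clash term
exists because the capped soft LJ alone underpenalizes deep overlap, and
it keeps the surrogate's minima clash-free by the same definition the
sliding moves use — without it the two scores disagree about what
"touching" means and local minimization walks into states sliding
refuses to leave. All constants are package choices; only relative
ordering matters for the engine's logic, and all are configurable
(`energy_config()`). The whole-assembly energy of a homomer is
(group order / 2) · Iscore, and the subsystem evaluation is tested to
equal a brute-force sum over the fully expanded assembly exactly,
because every scoring term vanishes beyond 12 Å.

## The optimizer

Each individual carries a backbone index, six parameters and an
orientation flag. One generation applies, per individual: a
DE/rand/1/bin trial (donor a + F·(b−c), F = mutation rate 0.1; binomial
crossover at rate 0.7 with one forced position), symmetric sliding,
Metropolis local search, Iscore selection (ties keep the parent), and an
occasional backbone trial (probability 0.3 — "occasionally" is not
quantified in the source; a swap is kept only if the Iscore improves).

*Sliding* translates the subunits along the symmetry folds from the
highest to the lowest fold order: the whole ring of chains around the
axis nearest the main subunit moves toward the assembly center in 0.3 Å
steps — chains sharing the axis move identically, so that fold's own
interface is kept fixed while the other interfaces approach — stopping
at the first CCS clash (the clashing step is reverted) or after 100
clash-free steps. A fold's slide that leaves the parameter bounds is
reverted; the per-fold (rather than whole-move) revert is a package
choice that preserves in-bounds progress along the other axes. The exact
geometric meaning of the published sliding move is under-described; this
interface-preserving reading is flagged as an interpretation.

*Local search* mirrors the packing–minimization / rigid-body subroutine:
a greedy coordinate-descent pass over the six parameters on the Iscore
(Metropolis-accepted; repeated when the first pass improves by at least
the improvement threshold, default 15 surrogate units, standing in for
the published 15 REU trigger), then exactly 10 random rigid-body moves
scored by the CCS under a Metropolis criterion (temperature 1.0,
configurable; the source names no temperature), then a final descent
pass. The best Iscore state encountered is returned.

*Bounds.* λ is bounded to ±(360/n)/2 in global mode and half that in
local mode; ψ, ϴ, φ to ±40°, x to ±5 Å around the center; z to ±5 Å
(local) or [0, 1000] Å (global). Violations add a square-well penalty of
10⁹ per violated parameter (additivity across parameters is a documented
convention; the source states only the depth).

*Orientation flip.* An oligomer can sit in a cubic frame in two
orientations related by a 180° turn perpendicular to the setup axis. In
global mode half the population starts in each orientation, and the flag
is inherited from the donor base during recombination so the
lower-energy orientation can take over the population by selection — the
source shows the takeover happening but not the mechanism, so the
flag-crossover design is this package's choice (ledgered).

## Ensemble preparation

Monomer predictions are kept at mean pLDDT ≥ 90; multimer predictions
additionally need model confidence 0.8·ipTM + 0.2·pTM ≥ 0.9. Termini are
trimmed by scanning inward for the first residue at which each of three
per-residue profiles crosses its threshold — average pLDDT ≥ 90,
connectivity ≥ 70 % (a residue is connected when its CA is within 8 Å of
a residue at least 10 positions away; CA is the package's contact atom
choice), secondary-structure propensity ≥ 70 % — and cutting at the
innermost crossing ("the last threshold to be crossed"; when profiles
oscillate, the max-of-first-crossings rule used here is one reading and
is flagged). The same cut applies to every model, giving equal lengths.
Secondary structure comes from an internal dihedral-window assigner
(helix φ ∈ [−100, −30], ψ ∈ [−80, −5]; strand φ ∈ [−180, −80],
ψ ∈ [80, 180] ∪ [−180, −170]; 3-residue majority smoothing) instead of
an external DSSP binary — only the ≥ 70 % aggregate matters. Redundancy
is pruned greedily in ascending-RMSD order (order unstated in the
source) below 0.1 Å CA RMSD, keeping the better-scored member, with the
threshold relaxed by 0.005 Å up to 18 times if fewer than 50 models
survive. Internal-loop trimming is not implemented (unnecessary in the
source's benchmark, and here). For global docking, starting ψ, ϴ, φ and
x are extracted from a Cn oligomer prediction via the inter-chain
rotation (tolerance ±10° on 360/n); the two antiparallel axis directions
are disambiguated by choosing the smaller |ϴ| — the residual two-fold
ambiguity is exactly the orientation-flip problem the global optimizer
samples over.

## Selection funnel and evaluation

The 1000 best individuals by Iscore are clustered into 100 sets by
k-means on the raw six-parameter vectors (no scaling or angular
embedding: the bounds keep angles far from wrap-around and the
parameters on comparable ranges; both documented limitations), each
representative is refined — here a bounded L-BFGS-B minimization of the
Iscore plus backbone re-selection, standing in for all-atom relax; the
Iscore never worsens — and the refined set is re-clustered into 5 ranked
models.

Evaluation metrics: symmetric RMSD (CA RMSD after superposition,
minimized over the n rotations about the setup fold — 0/72/144/216/288°
for a 5-fold); DockQ per interface (Fnat at 5 Å heavy-atom contacts,
iRMS over 10 Å interface backbone, LRMS after receptor superposition,
scales 1.5/8.5 Å, class cuts 0.23/0.49/0.80 — constants from the DockQ
literature, declared, not restated in the source); pairwise DockQ as the
ΔSASA-weighted mean over the unique fold interfaces (weights sum to 1;
contact-free folds are skipped with a warning and the weights
renormalized); an internal simplified assembly TM-score
(d0 = 1.24·(L−15)^⅓ − 1.8, iterative-subset superposition, chain
re-mappings restricted to the symmetry-consistent permutations — a full
structural-alignment search is out of scope); and the success-probability
resampler (resampling with replacement — the source does not say which —
100 reps, success when the best RMSD beats 4 Å). A prediction is
*successful* at pairwise DockQ ≥ 0.23 and TM ≥ 0.9, *highly accurate* at
DockQ ≥ 0.80 and TM ≥ 0.9.

## The synthetic world

All tests run on synthetic fixtures built by the `fixtures` module:
poly-alanine subunits with ideal backbone geometry built from φ/ψ
dihedrals (α-helix −57/−47; an antiparallel hairpin with a type-II′-like
turn whose dihedrals were chosen once so the strands pair within the 8 Å
contact distance along their whole length without steric overlap), fake
predictor ensembles with controlled per-residue pLDDT, noise and
disordered termini, and ideal cubic assemblies.

A toy *native* for a (kind, fold) pair is constructed deterministically:
an engineered bundle-like start orientation is inflated until the
setup-axis ring is clash-free, slid along the setup axis to first
contact, locally minimized, and then settled into the reproducible deep
optimum of the surrogate energy by short seeded memetic runs re-centered
until the basin is stable. Defining the native *as* a surrogate-energy
optimum makes the synthetic ground truth self-consistent with the energy
that replaces the (out-of-scope) all-atom refinement: recapitulation
tests then measure exactly what they claim — whether independent
randomized searches re-find a known optimum — rather than the agreement
between two unrelated energy functions.

Scaled-down protocol: recapitulation acceptance runs use population 20
for 15 generations (vs 100/50 in production) on 16-residue subunits, and
start from perturbations of ±8° (angles), ±2 Å (z, x) and ±8° (λ) around
the native — chosen once as the toy-scale analogue of the published
"broad range centered around the native values" (which started capsid
subunits at ~11 Å RMSD; the toy starts several Å away). What a green
recapitulation test establishes is sampling power on a smooth,
single-funnel toy landscape; it does not establish accuracy on real
capsids, rugged all-atom landscapes, flexible backbones, or
quasi-equivalent (T > 1) architectures, none of which the toy world
emulates.

## Numerical choices and degenerate inputs

* Rotation-angle comparisons use a 10⁻³ degree tolerance (acos is
  ill-conditioned near 180°); group closure is verified to 10⁻⁸.
* SASA uses a fixed Fibonacci-spiral point set, so values are
  deterministic across platforms at equal point counts.
* `extract_params()` aligns the observed symmetry frame to the standard
  one by matching fold axes and minimizing the conjugation error of the
  observed chain-relation rotations; candidates are enumerated
  deterministically, so extraction is reproducible, and results are
  unique only up to group equivalence.
* x = 0 makes λ undefined; it is then reported as 0 (or kept from the
  previous state during sliding).
* Ties in DE selection keep the parent; ties in harvesting keep archive
  order; k-means degenerate inputs (fewer distinct parameter vectors
  than clusters) fall back to one-point-per-cluster with a warning, and
  `final_five()` duplicates representatives rather than under-deliver.
* The R global RNG is seeded once per entry point (R has one global
  stream); identical seeds give bitwise-identical logs, which is tested.

## Known limitations

Helical, cyclic/dihedral and crystallographic symmetries and
quasi-equivalent capsids are out of scope. The surrogate energy is not
physical: absolute Iscores are not comparable to any force field, and no
sidechains beyond CB exist anywhere in the pipeline. PDB is the only
structure dialect (two-character chain extensions via the A–Z/a–z/0–9
pool, 62 chains maximum); mmCIF is not read. The TM-score chain mapping
searches only symmetry-consistent permutations, so it can undershoot for
models that are good under an inconsistent relabeling.
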