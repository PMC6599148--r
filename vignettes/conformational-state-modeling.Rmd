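---
title: "Chimeric templates and conformational-state diagnostics for LeuT-fold transporters"
author: "occludeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chimeric templates and conformational-state diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occludeR)
```

## The scientific problem

Neurotransmitter:sodium symporters (NSS) such as the human serotonin
transporter (hSERT) work by alternating access: a mobile four-helix *bundle*
(TM1, TM2, TM6, TM7) rocks against a quasi-static *hash* scaffold
(TM3/TM4/TM8/TM9), opening the orthosteric substrate site alternately to the
synapse and to the cytoplasm.  Experimental structures capture only some
states of this cycle.  A productive modeling strategy for a missing state —
here, the substrate-bound outward-occluded intermediate — is *chimeric
template construction*: take the resolved outward-open structure of the
transporter itself, superpose it onto an outward-occluded homolog on the hash
domain, reposition only the extracellular bundle segments rigidly onto the
homolog's conformation, and hand the composite to a comparative-modeling
engine.  Everything around that engine — building the template, filtering the
resulting models, clustering docked ligand poses, and quantifying what makes
the modeled state distinct (gate distances, rotamers, helix tilts, pathway
hydration) — is ordinary, reproducible computation, and that computation is
what this package implements.

The package deliberately stops at the boundaries of the external engines: it
emits the inputs they need (a PIR alignment, distance-restraint lists) and
analyzes the coordinates they produce, but it does not perform comparative
modeling, energy minimization, docking, or molecular dynamics.

## Coordinate model and conventions

* **Author residue numbering, everywhere.**  Residue numbers are read from
  the coordinate file and never renumbered, so residue symbols used across
  the NSS literature (R104, E493, Y176, F335, D98, ...) address the same
  residues here.
* **Altloc policy.**  On reading, the highest-occupancy alternate location is
  kept per atom (ties broken alphabetically); discarded altlocs are reported.
* **Hydrogens** are retained on read but excluded from all distance and
  contact metrics by default: the crystallographic reference states carry no
  hydrogens, and all printed gate criteria are heavy-atom criteria.
* **Missing side-chain atoms** make a metric *unevaluable* (`NA` with a
  reason), never guessed.
* **Units** are Angstrom internally; series can be emitted in nm, and the
  unit always travels with the data (`distance_series$unit`) — there is no
  silent conversion.
* Distances at the PDB fixed-column precision round-trip to 1e-3 Angstrom;
  tests that pass coordinates through files use tolerances at that scale.

The *role map* (YAML) binds every structural role — the TM helices, the hash
domain, the extracellular gates (R104–E493 salt bridge, Y176–F335 lid), the
intracellular gate network (R79–D452, W82–Y350, Y350–E444, E444–R462), the
binding-site anchors and the vestibule limits — to residue ranges.  The
shipped hSERT map derives its TM boundaries from topology annotation of
UniProt P31645, *not* from any single structure; they are approximate by
construction and meant to be edited per construct.  The map validates two
invariants: all required roles present, and hash = TM3 + TM4 + TM8 + TM9.

## Template construction

`hash_superpose()` computes a Kabsch least-squares fit restricted to the
hash-domain backbone (N, CA, C, O), pairing residues positionally within each
role range (the i-th hash residue of one structure to the i-th of the other).
Sequence-alignment-based pairing is intentionally out of scope: for a given
modeling project the pairing is fixed by the project's alignment, and the
positional rule makes the package's behavior a deterministic function of the
role map.

`segment_fit_table()` evaluates candidate segmentations of the bundle: each
target segment is Kabsch-fitted (backbone) to its donor segment after hash
superposition, the combined RMSD is the atom-count-weighted RMS over
segments, and candidates are ranked by descending total residues, then
ascending combined RMSD — i.e. the best fit is the smallest RMSD achieved by
the largest combination of fragments.  Candidates are user-supplied; the
package does not search boundary space.

`build_template()` then moves each target segment — side chains riding
rigidly with their backbone — onto the donor conformation and leaves every
other atom bit-identical to the input.  The chimera is a *template*, not a
model: junction peptide-bond lengths at provenance boundaries are reported
(`junction_bond_lengths()`) but never repaired, because regularization is the
modeling engine's job.  Provenance is written into the B-factor column
(0 unchanged / 1 repositioned) plus a YAML sidecar with the per-segment
transforms.

Ion transfer (`transfer_ions()`) mirrors the site-local logic used when
composing a starting complex: the coordination site is every residue with a
heavy atom within 4.5 Angstrom of the ion in the source structure; the site
backbone is fitted onto the same-numbered residues of the destination and the
ion copied under that transform.  A tagged crystallographic water can be
moved the same way.  `emit_restraints()` writes pairwise distance restraints
with the conventional defaults of 10 kcal/mol/A^2 for minimization sets and
200 kcal/mol/A^2 for equilibration sets, as a self-describing TSV or a
PLUMED-style text (AT in nm, KAPPA converted to kJ/mol/nm^2).

## Model quality control

`ramachandran()` classifies each evaluable residue as favored / allowed /
disallowed in the standard four-class scheme (general, GLY, PRO, pre-PRO).
The regions ship as a documented table of rectangle unions; "allowed" is a
20-degree dilation of "favored" plus the left-handed alpha region.  These are
coarse approximations of contour-based region art on purpose: the package's
contribution is the *filter logic* operating on the classes, and percentages
from different region definitions are comparable, not bit-identical.  Chain
breaks (CA–CA > 4.5 A) split the dihedral chain rather than erroring.

`clash_report()` lists non-bonded heavy-atom pairs whose van der Waals
overlap reaches 0.4 Angstrom by default.  Bonds are inferred from covalent
radii (d < 1.3 (r_i + r_j)), which uniformly covers intra-residue bonds,
inter-residue peptide bonds and ion coordination without a residue-topology
table; 1–2 and 1–3 pairs are excluded.  `ion_site_check()` compares
coordination distances against reference values with per-entry tolerances.

`filter_models()` applies an ordered cascade of rules — `top_n` (e.g. best
100 by builder objective), `within_sd_of_best` (e.g. within one standard
deviation of the best global quality score), `exclude_if` (e.g. any residue
in a disallowed region) — with an audit trail of set sizes and thresholds.
Two deliberate semantics: the standard deviation is the *sample* sd of the
set entering the rule, and `within_sd_of_best` is not idempotent
(re-application shrinks the sd and raises the threshold), which is why the
audit trail records the threshold actually used.

## Docking-pose clustering

Poses are compared by `rmsd_nofit()` — no superposition — over the ligand
heavy atoms concatenated with the binding-site backbone, so the metric sees
both ligand orientation and induced-fit site motion.  Agglomeration is
unweighted average linkage (UPGMA, via `stats::hclust`).  The number of
clusters is chosen at the minimum of the Kelley–Gardner–Sutcliffe penalty:
the mean intra-cluster spread (clusters of size >= 2; singletons contribute
nothing) is min–max normalized across levels onto [1, N-2] and k is added;
ties go to smaller k.

One property of this penalty is worth knowing: with exactly two
Gaussian-jittered groups, level k = 2 carries the *maximum* spread across
levels, normalization maps it to the top of the scale, and the selected k is
then realization-dependent.  In the tight-group limit — intra-group pose
distances equal, as in the package's deterministic two-group fixtures — all
levels tie on spread and the +k term cleanly selects k = 2.  Three or more
well-separated groups are selected robustly.  The test suite therefore pins
k* to planted group counts only where that is a stable property, and
otherwise verifies the penalty itself against a brute-force recomputation at
every level.

Interaction fingerprints evaluate the four classic serotonin criteria (D98
ionic contact of the cationic amine, C6–A173 proximity, 5-OH–T439 hydrogen
bond, indole N toward F341) as heavy-atom distance criteria with
configurable cutoffs (ionic 4.0, H-bond 3.5, proximity 4.5 Angstrom —
config values, since no published cutoffs accompany the criteria), always
reporting the distances next to the bits.

## State diagnostics

* **Gate distances** are per-frame minimum heavy-atom distances between the
  residues of a pair (`pair_series()`); replicas aggregate as mean and
  standard error at matched times; distributions are reported as normalized
  histograms over the pooled (combined) time.
* **chi1** follows the heavy-atom convention (N–CA–CB–CG for aromatics) and
  reports in (-180, 180].  Because rotamer populations near the branch cut
  produce circular means outside that interval, `chi1(..., branch =
  "unwrapped_minus")` reports the (-360, 0] branch; the package computes
  both and labels them rather than asserting which convention a given mean
  used.
* **Helix tilt** superposes the frame onto the reference on the hash
  backbone, estimates each helix axis, and reports the angle between axes
  folded into [0, 90].  The axis estimator is geometric: second differences
  of the CA trace point radially inward, so their successive cross products
  all point along the helix axis.  This estimator is exact on an ideal
  helix, where the raw dominant principal axis of a finite CA segment
  carries an end-effect tilt of several degrees; the principal-axis variant
  remains available (`axis_method = "principal"`) as a sensitivity
  diagnostic for the axis convention, and near-degenerate (straight) traces
  fall back to it automatically.
* **RMSD series** fit each frame to the reference on one selection and
  report RMSD over another without refitting, which expresses both the
  backbone convention (fit and report on backbone, termini and the large
  extracellular loop EL2 excluded via the role map) and the ligand
  convention (fit on protein backbone, report ligand heavy atoms in-site),
  in nm when requested.

## Hydration

The pathway box is 20 x 15 x 25 Angstrom, split along z (the membrane
normal; membrane alignment of the input frames is the caller's
responsibility) into a 9 A extracellular vestibule, a 7 A orthosteric band
and a 9 A intracellular vestibule.  The site band is centered midway between
the CA z of the extracellular anchors (Y176/F335) and the cytoplasmic anchor
(F341) and padded to exactly 7 A; if the anchors span more than 7 A, strict
mode errors and lenient mode warns.  x,y are centered on the geometric
center of the site anchors.  Waters are located by their O atom — a single
point per water keeps counts stable under rotation of the hydrogens — and a
water exactly on a shared z boundary belongs to the lower-z compartment
(bands are half-open from below), so each water lands in exactly one
compartment or outside and counts conserve.

`occupancy_map()` aligns every frame to the first on all protein backbone
atoms, collects water O atoms within 20 A of any ligand atom, and bins them
on a 2 A grid; a voxel's value is the fraction of frames in which it holds
at least one water.  Grids are written as OpenDX text readable by common
viewers.

## The synthetic fixture generator

All of the above is testable without any deposition because the generator
plants known answers:

* `ideal_helix()` builds a poly-ALA backbone+CB lattice (each atom type on
  its own coaxial helix; offsets frozen from an internal-coordinate helix at
  phi = -57, psi = -47), with rise 1.5 A and twist 100 degrees per residue
  by default, axis exactly +z.
* `toy_transporter()` arranges eight 20-residue helices on a ring: four form
  the hash, and the extracellular halves of the TM1/TM6 analogs are the
  mobile segments.  The occluded state rotates those segments by planted
  angles (defaults 17 and 8 degrees, the tilt regime of the outward-occluded
  transition) about axes perpendicular to the helix axis; an optional planted
  global rigid motion exercises the superposition machinery.  Every
  transform is recorded in a ground-truth ledger.
* `hydration_frame()` plants waters strictly inside each compartment band
  and outside the box; `toy_trajectory()` realizes planted gate-distance and
  chi1 schedules exactly, with optional isotropic Gaussian coordinate noise.

What the toys do *not* emulate: real secondary-structure irregularity,
side-chain chemistry (fixtures are poly-ALA with a PHE-like branch where chi
tests need one), solvent structure, membrane anisotropy, or correlated
dynamics.  Passing the property suite therefore demonstrates the
correctness of the geometry and bookkeeping, not biological realism of any
particular analysis.  Conclusions about the real transporter still require
the deposited structures and trajectories as inputs.

Problem sizes are chosen for exactness and speed: 800-atom toy transporters,
trajectories of at most 60 frames, up to 1000 random waters, pose sets of at
most 12 — large enough that every brute-force oracle (numeric rigid-fit
minimization, naive UPGMA, exhaustive penalty scans, double-loop distance
checks) runs in seconds while remaining fully independent recomputations.

## Validation against deposited coordinates

The printed-value checks (F335 chi1 rotamers in the outward-open and
outward-occluded hSERT structures and their LeuT counterpart; hash-superposed
TM1b/TM6a tilts between the cryo-EM states; the 17-residue paroxetine site;
gate closure in published simulation end states) run against the named wwPDB
entries and the published end-state deposition.  `fetch_pdb()` uses a local
cache directory (option `occludeR.depositions`, default `depositions/`) and
downloads from the wwPDB only when the entry is not cached; in a fully
offline environment those tests fail with an instruction to place the files
in the cache, and the rest of the suite is unaffected.

## Known limitations

* PDB fixed-column input/output and mmCIF input only; no mmCIF writing, no
  XTC/DCD (multi-model PDB is the portable trajectory format here).
* No structure repair, loop building, hydrogen placement, or protonation
  assignment; simulation-setup facts (disulfides, protonation states) belong
  in the user's configuration, not in the coordinates.
* Positional residue pairing assumes the role map encodes the intended
  equivalences; it will not rescue an inconsistent map.
* The Ramachandran regions are coarse rectangles; per-model percentages are
  comparable across models scored by this package, but not interchangeable
  with contour-based programs.
```{r, eval = FALSE}
# a minimal end-to-end tour
toy <- toy_transporter()                       # two states + ground truth
helix_tilt(toy$occluded, toy$open, "TM1b", toy$roles)   # 17
ch <- build_template(toy$open, toy$occluded, toy$segments, toy$roles)
ch                                             # segment rmsd ~ 0
spec <- build_compartments(toy$open, toy$roles)
hf <- hydration_frame(spec, counts = c(3, 2, 4), n_outside = 5)
water_counts(hf$frame, spec)                   # 3 2 4
```
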