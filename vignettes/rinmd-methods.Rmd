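---
title: "Residue interaction networks from MD trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction networks from MD trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinmd)
```

## The model

A residue interaction network (RIN) represents a protein as a graph whose
nodes are amino-acid residues and whose edges are non-covalent
interactions. `rinmd` builds *multigraph* RINs: a residue pair may be
joined by several edges, one per interaction class, so the network retains
the chemistry of each contact instead of collapsing it into a single
distance threshold. Nine interaction classes are detected, each from an
explicit geometric or energetic criterion evaluated on one coordinate
frame:

| class | criterion | defaults |
|---|---|---|
| Cα contact | dist(Cαi, Cαj) ≤ d, sequence separation > 2 | d = 8 Å |
| hydrogen bond | dist(donor, acceptor) ≤ d and D–H···A angle ≥ a | d = 3 Å, a = 120° |
| salt bridge | min dist(basic N, acidic O) ≤ d | d = 6 Å |
| disulfide | dist(SG, SG) ≤ d and \|χSS\| ∈ [a, b] | d = 3 Å, [60°, 90°] |
| π–π | ring centroid–centroid ≤ d | d = 6 Å |
| cation–π | ring centroid–cation ≤ d, normal angle in [0°, 60°] ∪ [120°, 180°] | d = 7 Å |
| Arg–Arg | guanidinium centroid–centroid ≤ d | d = 5 Å |
| Coulomb | \|E\| ≥ t, E = 332.0636 Σ qa qb / (εr rab), rab ≤ 12 Å | t = 1 kcal/mol |
| van der Waals | E ≤ t, E = Σ εab[(Rmin,ab/r)¹² − 2(Rmin,ab/r)⁶] | t = −0.1 kcal/mol |

All distance thresholds are inclusive (`≤`). Units are fixed throughout:
Ångström, degrees, kcal/mol, elementary charges.

For a trajectory, each frame yields an interaction multigraph; the
*consensus RIN* keeps an edge when it is present in at least a chosen
fraction of frames (default 0.75). Its persistence is stored as the exact
fraction, with mean/min/max of every geometric descriptor over the frames
where the edge exists. A static PDB structure is the one-frame special
case: its consensus RIN equals its frame graph.

Coordinated formation and rupture of interactions is measured per class:
each residue is described by the vector of its per-frame interaction
counts, and Pearson's r between two such vectors (over a frame window)
quantifies how concertedly two residues gain and lose contacts. Counting
residue pairs with |r| above a cutoff, window by window, tracks whether a
conformational change is driven by an initial concerted motion that later
dissipates. A strand-resolved collective variable — the mean distance
between per-group centers of mass and the center of mass of the pooled
selection — is provided to delineate such windows; for a closing β-cavity
it decreases as the strands collapse inward.

## Design choices

Several points are genuinely open in how such criteria are usually stated;
the package resolves them as follows.

* **Cation–π versus π–π geometry.** The two rows are assigned the
  chemically coherent reading: π–π compares ring centroids (6 Å);
  cation–π compares a ring centroid with a cationic group (7 Å) and
  requires the centroid→cation direction to lie within 60° of the ring
  normal on either face. Ring normals have an arbitrary sign (they come
  from a best-fit-plane eigendecomposition), so the angle bands are
  symmetric — θ and 180° − θ are equivalent — making every result
  independent of that sign.
* **Hydrogen-bond measurement.** The thresholded distance is
  donor–acceptor (not hydrogen–acceptor); the angle is measured at the
  hydrogen between the bonded heavy atom and the acceptor. Donors are
  N/O/S heavy atoms carrying at least one hydrogen; acceptors are all
  oxygens, nitrogens without hydrogens, and Met/Cys sulfur. Hydrogens are
  paired to heavy atoms through PSF bonds when a topology is given,
  otherwise by nearest-heavy-atom distance (≤ 1.25 Å) within the residue —
  more robust than name conventions for generated or nonstandard
  structures. Hydrogens are never built: structures lacking them simply
  yield no hydrogen bonds, with a warning.
* **Histidine protonation** is inferred from the atom inventory: both HD1
  and HE2 present → cationic (behaves as a cation, not a π-system); one of
  them → a neutral π-system. Explicit HSD/HSE/HSP (or HID/HIE/HIP) names
  are honoured directly, and survive protein-only filtering.
* **Tryptophan** contributes its full 9-atom indole as a single π-system
  (one centroid, one normal).
* **Energy detectors.** Coulomb sums run over inter-residue atom pairs
  within 12 Å at εr = 1 with k = 332.0636 kcal·mol⁻¹·Å·e⁻²; Lennard-Jones
  uses the standard combination rules εab = √(εa εb),
  Rmin,ab = Rmin/2,a + Rmin/2,b. Residue pairs adjacent along the backbone
  are excluded from both (their energies are dominated by the covalent
  link, not a non-bonded contact). The vdW edge criterion
  (E ≤ −0.1 kcal/mol, an attractive contact) and the Coulomb criterion
  (|E| ≥ 1 kcal/mol) are package choices — the energy is stored on every
  edge so users can re-filter.
* **Charges and LJ parameters.** With a PSF topology, partial charges come
  from the file and LJ parameters from a CHARMM-format parameter file
  keyed by the PSF atom types. For a bare PDB, a bundled residue-template
  table (CHARMM-style types and charges for the 20 standard residues and
  His variants, assembled from standard values — see
  `inst/extdata/residue_templates_synthetic.tsv`) fills both; unmatched
  atoms keep zero charge and are reported once.
* **Multigraph centralities.** Standard centralities are ill-defined on
  multigraphs, so they are computed on the simple-graph projection with
  the number of distinct interaction types as the edge weight: degree and
  weighted degree use it directly; betweenness and closeness use
  unweighted shortest paths (multiplicity is an affinity, not a length);
  closeness is computed within each connected component; eigenvector
  centrality uses a dense symmetric eigendecomposition of the weighted
  adjacency matrix, which is deterministic and well-defined on
  disconnected graphs.
* **Within-frame multiplicity** (e.g. two hydrogen bonds between one
  residue pair in one frame) collapses to presence for persistence
  purposes and is kept as a count descriptor — persistence is defined over
  frames, not over individual interactions.
* **Undefined correlations.** A residue whose count series is constant in
  a window has no defined Pearson r; those entries are NA, written as NA,
  and excluded from correlated-pair counts. Silent zeros would corrupt
  window-to-window rate comparisons; a rate whose reference window has a
  zero count is likewise NA, never infinite.

## Numerical behaviour

Angles come from a clamped arccosine, so antiparallel vectors can never
produce NaN. Torsions follow the IUPAC convention (cis = 0, sign from the
right-hand rule); reversing the four atoms preserves the signed value and
mirror reflection negates it. Distance thresholds are inclusive and
machine-exact at representable boundaries (a pair placed at exactly 8 Å is
a Cα contact); angle criteria are also inclusive, but a geometry
constructed *at* an angle boundary carries one-ulp trigonometric round-off,
so boundary behaviour of angles should be probed with a margin rather than
at the exact value. Coordinates are used as stored: no periodic-boundary
minimum-image convention is applied, and trajectories should be wrapped
and centered before analysis.

Parallel trajectory analysis forks one worker per core requested; because
per-frame detection is pure and results are reduced in frame order, every
output file is byte-identical for any worker count.

## The fixture generator

Testing against experimental structures cannot distinguish a detector bug
from a debatable chemical judgement, so the package ships a generator that
*plants* interactions with exactly known geometry:

* `make_dipeptide_pair()` poses two minimal residues so that one requested
  interaction holds at requested descriptor values (or misses a threshold
  by a stated margin, for planted negatives);
* `make_trajectory()` switches each planted pair between a formed and a
  broken geometry according to a per-frame schedule, with optional
  Gaussian coordinate noise that is refused if it exceeds a quarter of any
  planted threshold margin;
* `bernoulli_schedules()` draws presence schedules with known pairwise
  correlation (a shared driver plus independent flips), so that the
  Pearson machinery can be checked against a planted ρ;
* `make_assembly()` builds multi-chain systems with planted intra-chain,
  inter-chain and inter-assembly contacts for edge classification.

The generator emulates controlled pairwise geometry, scheduled
formation/rupture, and multi-chain topology. It does not emulate real
proteins: there is no excluded volume, no backbone connectivity between
planted pairs, no correlated thermal motion, and no force field. Passing
tests therefore demonstrate that the detectors implement their stated
criteria exactly and that the network/correlation layers are correct —
they do not validate the chemical realism of the criteria themselves on
experimental systems.

Problem sizes used by the test-suite and the acceptance script — up to
50-residue random systems for oracle equivalence, 500-frame schedules for
correlation recovery (binomial sampling keeps r̂ within ±0.12 of ρ at that
length), 100 residues × 200 frames for the determinism check — were chosen
to exercise every code path at comfortable desk scale.

## Known limitations

* No hydrogen or missing-atom reconstruction; H-dependent detection needs
  structures with explicit hydrogens.
* No solvent, ion or ligand nodes; heteroatoms are stripped.
* DCD files with fixed-atom blocks are rejected; GRO/XTC/TRR and mmCIF are
  out of scope.
* Secondary-structure node attributes require an external DSSP program and
  are otherwise left empty; solvent accessibility is computed internally
  by the Shrake–Rupley method (92 test points, 1.4 Å probe) when
  requested.
* The Coulomb group criterion is a deliberately simple screened
  point-charge sum; it applies no 1–4 scaling and no reaction-field or
  Ewald correction.

## A worked example

```{r example, eval = FALSE}
library(rinmd)

## a 12-frame trajectory with one scheduled hydrogen bond (9 of 12 frames)
td <- tempfile()
traj <- make_trajectory(list(list(
  type = "HBOND",
  formed = list(distance = 2.9, angle = 180),
  broken = list(distance = 4.2, angle = 180),
  schedule = c(rep(TRUE, 9), rep(FALSE, 3))
)), n_frames = 12, dir = td)
files <- attr(traj, "files")

res <- run_pipeline(list(
  psf = files[["psf"]], dcd = files[["dcd"]],
  types = c("CALPHA", "HBOND"), persistence = 0.75,
  out = file.path(td, "out")
))
res$rin$edges[, c("label_i", "label_j", "type", "persistence")]
```
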