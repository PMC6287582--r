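# rinmd — residue interaction networks from structures and MD trajectories

Molecular-dynamics simulations of proteins produce far more coordinate
data than anyone can inspect directly. A compact, chemically meaningful
summary is the **residue interaction network (RIN)**: a graph whose nodes
are amino-acid residues and whose edges are the non-covalent interactions
between them. `rinmd` builds RINs from a static PDB structure or from a
CHARMM/NAMD trajectory (PSF topology + DCD coordinates), for structural
bioinformaticians who want to ask which contacts hold a fold or an
interface together, how stable each one is over a simulation, and which
residues gain and lose contacts in concert.

Nine interaction classes are detected per frame, each from an explicit
criterion (defaults in parentheses, all `≤` thresholds inclusive):

* **Cα contacts** — dist(Cαᵢ, Cαⱼ) ≤ d (8 Å), |i − j| > 2 within a chain;
* **hydrogen bonds** — dist(D, A) ≤ d (3 Å) and D–H···A angle ≥ a (120°);
* **salt bridges** — basic-N to acidic-O minimum distance ≤ d (6 Å);
* **disulfide bridges** — d(SG, SG) ≤ 3 Å and |χSS| ∈ [60°, 90°];
* **π–π** — aromatic ring centroid distance ≤ 6 Å;
* **cation–π** — ring–cation distance ≤ 7 Å, ring-face angle bands
  [0°, 60°] ∪ [120°, 180°];
* **Arg–Arg** — guanidinium centroid distance ≤ 5 Å;
* **Coulomb** — |E| ≥ 1 kcal/mol with E = 332.0636 Σ qₐq_b/(εᵣ r), r ≤ 12 Å;
* **van der Waals** — 12-6 Lennard-Jones residue-pair energy ≤ −0.1 kcal/mol.

Per-frame multigraphs are aggregated into a **consensus RIN** that keeps
edges present in at least a chosen fraction of frames (default 75%), with
exact persistence fractions and descriptor statistics per edge; networks
are written as GraphML (Cytoscape-ready) and TSV tables, with node
centralities. Per interaction class, the package also computes **Pearson
correlation matrices** over per-residue interaction-count time series,
revealing concerted formation/rupture of contacts, plus a center-of-mass
collective variable for delineating analysis windows. A fixture generator
plants interactions with exactly known geometry and correlation structure,
so the whole pipeline is testable without external data.

## Worked example

Generate a 12-frame trajectory in which one hydrogen bond is present in 9
of 12 frames, then run the full pipeline at a 75% persistence cutoff:

```r
library(rinmd)

td <- tempfile()
traj <- make_trajectory(list(list(
  type     = "HBOND",
  formed   = list(distance = 2.9, angle = 180),
  broken   = list(distance = 4.2, angle = 180),
  schedule = c(rep(TRUE, 9), rep(FALSE, 3))
)), n_frames = 12, dir = td)
files <- attr(traj, "files")

res <- run_pipeline(list(
  psf = files[["psf"]], dcd = files[["dcd"]],
  types = c("CALPHA", "HBOND"), persistence = 0.75,
  out = file.path(td, "out")
))
res$rin
#> consensus_rin: 2 nodes, 2 edges over 12 frame(s) (persistence >= 0.75)
#>   edges by type: CALPHA=1, HBOND=1
res$rin$edges[, c("label_i", "label_j", "type", "persistence",
                  "frame_count", "distance_mean")]
#>    label_i  label_j   type persistence frame_count distance_mean
#> 1 A:ALA:21 A:ALA:30 CALPHA        1.00          12      6.841633
#> 2 A:ALA:21 A:ALA:30  HBOND        0.75           9      2.900000
```

The hydrogen bond survives at exactly its planted persistence (9/12 =
0.75, inclusive at the cutoff) with its planted donor–acceptor distance of
2.9 Å; the Cα contact between the same residues is present in every
frame. The output directory holds the global and per-type GraphML
networks, node/edge TSV tables, centralities, the class-count table and
the correlation matrices, plus a `run.log` with per-stage timings.

The same pipeline runs from a shell via the thin wrapper:

```sh
inst/exec/rinmd run --psf traj.psf --dcd traj.dcd \
    --types CALPHA,HBOND --persistence 0.75 --workers 4 --out out/
```

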