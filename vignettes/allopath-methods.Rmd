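---
title: "Dynamical network analysis of allosteric pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical network analysis of allosteric pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The model

Allosteric communication in large complexes such as the DNA mismatch-repair
protein MutS can proceed without major conformational change, through
correlated residue motions.  `allopath` implements the dynamical-network
description of this idea as a post-processing pipeline for MD trajectories:

1. **Nodes.**  One node per amino acid at its C-alpha; two per nucleotide
   (base node at N1/N9, phosphate node at P, or PA for free nucleotides such
   as ATP/ADP).  This keeps nucleic acids at roughly the same spatial
   granularity as protein residues.
2. **Displacement correlations.**  After rigid-body superposition, the
   dynamic cross-correlation matrix of node displacements is
   $C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
   (\langle \Delta r_i^2\rangle^{1/2}\langle \Delta r_j^2\rangle^{1/2})$,
   with $\Delta r_i$ the representative-atom position minus its time mean
   over the analysed window.
3. **Network.**  A pair of non-neighbouring nodes is an edge when its member
   heavy atoms come within 4.5 Å in more than 75 % of the frames; the edge
   weight is $w_{ij} = -\ln|C_{ij}|$, so strong coupling means short
   graph distance.  Sequence-adjacent residues and the two nodes of one
   nucleotide are excluded: their covalently enforced correlation would
   otherwise dominate every path.
4. **Paths.**  Optimal paths are exact shortest paths (Floyd–Warshall);
   suboptimal ensembles are *all* simple paths within a weight offset of the
   optimum, found by depth-first search pruned with the all-pairs distance
   table (an admissible bound, so the enumeration is exhaustive — which is
   what makes oracle testing against brute force possible).  Paths carry the
   statistics $N$ (hops = edges), $W = -100\sum_k \ln|c_{ij}^k|$ and the
   minimum pairwise correlation; a path is *effective* only when that
   minimum is at least 0.7, since a single weakly coupled link breaks the
   communication chain regardless of total weight.
5. **Communities.**  Girvan–Newman edge removal (betweenness recomputed
   after each removal, shortest paths on the $-\ln|C|$ weights), keeping the
   partition of maximal weighted modularity along the dendrogram.  Edges
   joining different communities, ranked by how many ensemble paths cross
   them, are the candidate switching points of the communication network.
6. **Mutation enrichment.**  Mutation positions mapped onto the structure
   are compared with pathway residues; the expected random overlap is
   $n_\mathrm{mut} \, n_\mathrm{path} / n_\mathrm{total}$, and a
   hypergeometric upper-tail probability is reported as well (the tail
   probability is this package's extension; the expectation is the
   conventional quantity).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 4.5 | Å | heavy-atom contact distance of the established protocol |
| contact occupancy | > 0.75 | fraction of frames | persistence filter; "more than" is strict |
| correlation floor | 1e-6 | — | keeps $-\ln|C|$ finite on essentially uncorrelated contacts |
| effectiveness threshold | 0.7 | correlation | weakest-link criterion for a usable route |
| suboptimal offset | 3 / 5 / 10 | $W$ units (×100) | conventional offsets for MBD–ATPase, ATPase–ATPase, ATPase–clamp ensembles |
| anchor shell radius | 10 | Å | candidate anchors around a functional site |
| frame interval | 1 | ps | sampling density the analysis assumes |

**Log base.**  $W$ uses the natural logarithm.  The choice is pinned by a
consistency argument: on any $N$-hop path with minimum correlation $m$,
$100(-\log m) \le W \le 100\,N(-\log m)$.  Every row of the curated MutS
reference table (`muts_path_table()`) satisfies these bounds under natural
logs, while base-10 fails for several rows — most sharply the ADP-None
chain-B ATPase–clamp path ($N=28$, $W=209$, $m=0.86$: base-10 upper bound
$28 \times 6.55 = 183 < 209$).  `path_table_consistency()` reproduces this
check.

**Offsets are on the ×100 scale.**  A raw $-\ln|C|$ offset of 3–10 would
admit nearly every path in a connected domain (typical edge weights are
0.1–0.7); interpreted on the reported-weight scale (offset 10 ≡ 0.10 raw)
the ensembles stay curated and informative.

**Hops count edges**, not nodes; no curated row contradicts this reading,
but it is not externally verifiable — the convention is stated here once
and used consistently.

## The synthetic generator

MD trajectories of the size needed for converged DCCMs are impractical to
re-run or ship, so the package validates itself on synthetic
correlated-motion trajectories with *planted* ground truth.

**Geometry.**  `make_geometry()` lays out pseudo-residue chains (one atom
per node).  Dense "domain" blocks are triangular bipyramids with 4.0 Å
edges: every pair is a contact except the two apexes (6.53 Å apart), which
keeps every declared non-contact beyond 6 Å — far enough that displacement
noise can neither break a contact (margin 0.5 Å below the 4.5 Å cutoff)
nor fabricate one.  Bipyramid nodes carry odd residue numbers so that no
intra-block contact is lost to the sequence-neighbour exclusion.  The
geometry verifier recomputes all pairwise distances and rejects layouts
violating the <4.5 / >6 Å separation, e.g. line chains with spacings that
push neighbours past the cutoff or pull second neighbours inside the
clearance.

**Covariance.**  `make_covariance()` builds the exact node-displacement
correlation matrix from a latent Gaussian factor model: one unit-variance
factor per block, block factors mutually correlated by
$\gamma = \rho_{bg}/\rho_{block}$ (so between-block correlations are
exactly $\rho_{bg}$), and a nonstationary AR(1) latent chain along the
planted path.  A path node mixes the chain (85 % of its variance by
default) with its block factor; the chain step coefficients are solved so
consecutive path-edge correlations equal $\rho_{path}$ exactly wherever
attainable.  The construction is a Gram matrix, hence positive
semi-definite *by design* — a property the obvious alternatives lack: a
target matrix with block values plus overwritten path edges has negative
eigenvalues already at the default 0.9/0.6/0.1 settings, and per-edge
factor loadings followed by correlation normalisation cap interior
path-edge correlations at 0.5 (an interior node carries two edge factors).
The only step that saturates is a block-crossing bridge, which peaks at
$a^2 + c^2\gamma \approx 0.875$ under the defaults; all achieved values
are exact model quantities exposed by `ground_truth()`, and the planted
margin over block edges (≥ 0.27) still exceeds the 0.2 the recovery suite
assumes.

**Sampling.**  Displacements are isotropic Gaussians with the same
node–node correlation applied independently per Cartesian axis, scaled by
a per-node amplitude (default 0.35 Å).  This makes the sample DCCM
converge to the model correlation matrix analytically (closed-form
recovery target) and keeps the contact graph stable: a contact at 4.0 Å
with background-level correlation stays within the cutoff in ≈ 90 % of
frames, comfortably above the 75 % occupancy bar, while the nearest
non-contact (6.5 Å) essentially never crosses it.  The amplitude is
deliberately below typical protein RMSF values — the generator emulates
the *contact-persistence regime* of a folded complex at this coarse node
spacing, not the absolute fluctuation scale.

**What the generator does not emulate:** anisotropic and collective
rigid-body-like motions, fat-tailed displacement distributions,
time-autocorrelation between frames (frames are i.i.d.), conformational
substates, and solvent-mediated correlations.  Passing the recovery suite
therefore shows the *pipeline* is correct, not that real trajectories of
any particular system are converged.

**Canonical benchmark** (`synthetic_model()`): two 5-node bipyramid blocks
(chains A, B) joined by one bridge contact; planted path
apex–base–apex–bridge–apex–base–apex (`A:1 A:3 A:9 B:1 B:3 B:9`), planted
partition = the two chains, $\rho$ = 0.9/0.6/0.1.  On the exact
expected-weight graph the planted path is the unique minimum-weight route
(verified by brute-force enumeration), and the planted two-block split is
the modularity-maximal Girvan–Newman partition, with the bridge as the
first-removed, highest-betweenness edge and the top critical
inter-community edge.

## Numerical choices

- **Ties** break lexicographically everywhere (lowest node id, lowest edge
  pair), so outputs are bit-reproducible; reports contain no timestamps,
  making reruns byte-identical.
- **Path reconstruction tolerance** is $10^{-9}(1 + d)$ relative on
  distances; the DFS bound uses the same tolerance so boundary paths
  (offset 0, exact ties) are included deterministically.
- **Superposition** fits every frame to the ensemble mean and re-iterates
  until coordinates stabilise (at least two passes, tolerance $10^{-8}$ Å);
  this makes the operation a fixed point, so superposing an
  already-superposed ensemble is a no-op to within $10^{-6}$ Å.  The
  fitting selection defaults to all representative atoms, fitted globally;
  per-domain fitting is deliberately not attempted.
- **Degenerate inputs**: trajectories need ≥ 2 frames (≥ 8 for convergence
  windows; shorter windows are skipped with a warning); zero-variance
  nodes get NA correlations and may not carry network edges; a
  disconnected anchor pair is an explicit "no path" result, not an error;
  an edgeless graph partitions into singletons with modularity 0.
- **Suboptimal search cap** (default $10^6$ paths) turns combinatorial
  blow-ups into an instructive error rather than an out-of-memory.

## Design choices where the protocol is genuinely open

- **DCCM frames** are pooled over the analysed window (all frames, no
  decimation), with the displacement reference being the window mean.
  Per-trajectory averaging of DCCMs is not implemented; for the stationary
  synthetic ensembles the two coincide in expectation.
- **Contact distances** use member heavy atoms (minimum over atom pairs);
  a representative-atom ("point") mode exists behind a flag for
  sensitivity checks.  Occupancy is computed over all pooled frames, also
  when several files are concatenated.
- **Anchor shells** are evaluated on a caller-supplied reference frame
  (conventionally the first analysed frame).
- **Modularity weights:** betweenness during Girvan–Newman uses the
  $-\ln|C|$ *distances* (consistent with the path machinery), while
  modularity uses $|C|$ as an *affinity* — a distance in the modularity
  sum would invert the meaning of "densely connected".
- **Mutation adjacency** is sequence adjacency (±1 residue on the same
  chain); spatial adjacency would need a structure-specific contact
  threshold and is left out.
- **Altloc / missing residues:** highest-occupancy conformer wins;
  missing residues are absent nodes, never imputed.

## Problem sizes used by the test-suite

The suite validates on: 1000 random graphs of ≤ 9 nodes against exhaustive
path enumeration; 100 seeded synthetic models with 20 000 frames each for
planted-path and community recovery; 50 000 frames for DCCM parameter
recovery on 2- and 20-node models.  These sizes give sampling errors an
order of magnitude below the decision margins involved (e.g.
$\mathrm{sd}(\hat C) \approx (1-\rho^2)/\sqrt{n} \approx 0.0013$ for
$\rho = 0.9$ at $n = 20\,000$, against a planted margin of 0.27).

## Known limitations

- Girvan–Newman recomputes betweenness after every removal
  ($O(E^2 V \log V)$ with weights): adequate for single complexes
  (hundreds of nodes), slow beyond that.  Louvain/Leiden alternatives are
  intentionally out of scope.
- The Floyd–Warshall implementation is dense ($O(V^3)$, vectorised per
  $k$); for very large systems a sparse Johnson variant would be
  preferable.
- Suboptimal enumeration is exhaustive by design; for offsets far above
  the conventional 3–10 the ensemble grows combinatorially and the cap
  will trigger.
- No time-lagged or mutual-information correlations; no flow-based
  path models; no trajectory production or solvent handling — inputs are
  assumed whole-molecule and aligned-ready.

## A complete worked run

```{r, eval = FALSE}
m <- synthetic_model()                       # planted benchmark
res <- run_pipeline(m, n_frames = 20000, seed = 1, offset = 10)
res$optimal                                  # recovered planted path
res$partition                                # recovered planted communities
res$critical_edges                           # the bridge tops the ranking
ground_truth(m)$path_edges                   # what the run should recover
```
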