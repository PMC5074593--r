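# allopath

Dynamical network analysis of allosteric communication pathways from
molecular dynamics trajectories.

## The problem

Large multi-domain machines — the motivating case is the DNA
mismatch-repair protein MutS and its eukaryotic homologs MSH2–MSH6/MSH3 —
couple events at sites 70 Å apart (mismatch recognition at one end,
ATPase activity at the other) with almost no visible conformational
change.  The dynamical-network picture explains this through chains of
locally correlated residue motions: persistent contacts whose
displacement correlations are strong enough to relay a signal.
`allopath` turns a structure plus a coordinate trajectory into that
network and extracts its communication pathways.  It is written for
computational structural biologists post-processing MD ensembles, and for
methodologists who need a pipeline whose every stage can be validated
against planted ground truth.

## The method

From a superposed trajectory, the package computes the dynamic
cross-correlation matrix of coarse-grained node displacements (one node
per residue at the Cα, two per nucleotide at N1/N9 and P/Pα),

    C_ij = ⟨Δr_i · Δr_j⟩ / (⟨Δr_i²⟩^½ ⟨Δr_j²⟩^½),

keeps node pairs whose member heavy atoms are within 4.5 Å in more than
75 % of frames (sequence neighbours excluded), and weights those edges by

    w_ij = −ln |C_ij|.

Optimal communication paths between anchored functional sites are exact
shortest paths (Floyd–Warshall); suboptimal ensembles are **all** simple
paths within a fixed offset of the optimum (exhaustive bounded search).
Each path is summarised by N (hops), W = −100 Σ ln|c| (overall weight) and
min (weakest pairwise correlation along the path; a route is *effective*
only if min ≥ 0.7).  Girvan–Newman community detection and path-ensemble
edge betweenness identify the critical inter-community edges where
communication can be switched.  A mutation-enrichment module compares
mutation positions with pathway residues against the random expectation
n_mut · n_path / n_total (plus a hypergeometric tail probability).

Because trajectories of the required length are rarely shippable, the
package includes a synthetic correlated-motion generator
(`synthetic_model()`, `make_geometry()`, `make_covariance()`,
`sample_trajectory()`) producing pseudo-structures with an exactly known
contact graph and an exactly known correlation matrix containing planted
community blocks and a planted optimal pathway — the ground truth every
downstream stage is tested against.

## Worked example

```r
library(allopath)

m   <- synthetic_model()                  # planted two-domain benchmark
res <- run_pipeline(m, n_frames = 20000, seed = 1, offset = 10)

res$network
#> dynamic_network: 10 nodes, 19 edges; w_ij = -ln|C_ij| on contacts (cutoff 4.5 A, occupancy > 0.75 )
res$optimal
#> comm_path: N=5  W=56  min=0.88  [A:1 - A:3 - A:9 - B:1 - B:3 - B:9]
res$partition
#> community_partition: 2 communities, modularity 0.4058
res$critical_edges
#>   i j label_i label_j community_i community_j       cor    weight path_count
#> 1 5 6     A:9     B:1           1           2 0.8750682 0.1334535          1
```

The recovered optimal path is exactly the planted one; its statistics say
it takes N = 5 hops with overall weight W = 56 (on the ×100 scale, i.e.
Σ −ln|c| ≈ 0.56) and never relies on a correlation below 0.88, so it is an
effective route.  The network splits into the two planted domain
communities, and the single edge joining them (`A:9–B:1`, the planted
bridge) is the top-ranked critical inter-community edge — the bottleneck a
perturbation would have to hit to re-route communication.  Compare with
the exact expectations:

```r
ground_truth(m)$path_edges
#>   i  j   cor       phi expected_weight
#> 1 1  2 0.900 0.8823529       0.1053605
#> ...                                       # 5 edges, min cor 0.875
```

Mutation enrichment on the MutS numbers (16 mapped MSH6 mutations, 97
pathway residues, 800 residues, 4 observed hits):

```r
overlap_expectation(16, 97, 800, observed = 4)
#> expected 1.94 (rounded 2), observed 4, P(X >= 4) = 0.118
```

Real structures enter through `load_topology()` (PDB),
`load_trajectory()` (multi-model PDB), `superpose_trajectory()`,
`compute_dccm()`, `compute_contacts()`, `build_network()`, then the same
path/community machinery; `candidate_nodes_near_site()` and
`select_anchor_pair()` implement the 10 Å-shell anchor selection.
See `vignettes/allopath-methods.Rmd` for the full method description,
parameter rationale and design decisions.

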