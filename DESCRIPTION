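Package: allopath
Title: Dynamical Network Analysis of Allosteric Communication Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular dynamics trajectories into dynamical
    residue networks for the study of long-range allosteric communication.
    Builds coarse-grained node models from PDB structures (one node per amino
    acid at the C-alpha, two per nucleotide at the base and phosphate),
    computes dynamic cross-correlation matrices (DCCM) of node displacements,
    constructs contact-filtered networks with edge weights -ln|C_ij|, extracts
    optimal and exhaustively enumerated suboptimal communication pathways
    between anchored functional sites together with hop count, overall weight
    and minimum-correlation statistics, partitions networks into communities
    by the Girvan-Newman algorithm, and tests mutation sets for enrichment on
    pathway residues. Includes a synthetic correlated-motion trajectory
    generator with planted pathways and planted community structure so that
    every stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
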