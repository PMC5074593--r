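# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer 'seed' is required for reproducible sampling")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# xyz storage convention (as in bio3d): matrix of n_frames rows and
# 3*n_atoms columns ordered x1,y1,z1,x2,y2,z2,...
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

# coords for a set of atoms in one frame -> m x 3 matrix
frame_coords <- function(xyz_row, atom_idx) {
  matrix(xyz_row[xyz_cols(atom_idx)], ncol = 3L, byrow = TRUE)
}

# per-frame distances between two single atoms, vectorised over frames
atom_pair_dist <- function(xyz, a, b) {
  da <- xyz[, xyz_cols(a), drop = FALSE] - xyz[, xyz_cols(b), drop = FALSE]
  sqrt(rowSums(da * da))
}

node_labels <- function(nodes) {
  lab <- paste0(nodes$chain, ":", nodes$resno)
  two <- nodes$role != "calpha"
  lab[two] <- paste0(lab[two], ".", substr(nodes$role[two], 1L, 1L))
  lab
}

stopifnot_node_model <- function(node_model) {
  if (!inherits(node_model, "node_model"))
    stop("'node_model' must be a node_model object (see load_topology/make_geometry)")
}

stopifnot_trajectory <- function(traj) {
  if (!inherits(traj, "traj_ensemble"))
    stop("'traj' must be a traj_ensemble object")
}
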