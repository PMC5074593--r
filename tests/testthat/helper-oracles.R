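# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's own search code: path
# enumeration is a plain unpruned recursion, distances come from igraph.

# Build a dynamic_network directly from a correlation matrix and a logical
# contact matrix (fabricated contact_map + dccm_matrix), exercising
# build_network without a trajectory.
make_net <- function(C, contact, labels = NULL) {
  n <- nrow(C)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  dimnames(C) <- dimnames(contact) <- list(labels, labels)
  cm <- structure(list(contact = contact,
                       fraction = ifelse(contact, 1, 0),
                       excluded = diag(n) > 0,
                       cutoff = 4.5, fraction_threshold = 0.75,
                       mode = "point", node_model = NULL),
                  class = "contact_map")
  dm <- structure(C, class = c("dccm_matrix", "matrix"))
  build_network(cm, dm)
}

# Random weighted graph: contact probability p, |cor| uniform in
# [0.15, 0.95] with random signs.
rand_net <- function(n, p, seed) {
  set.seed(seed)
  contact <- matrix(FALSE, n, n)
  contact[upper.tri(contact)] <- runif(n * (n - 1) / 2) < p
  contact <- contact | t(contact)
  C <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2, 0.15, 0.95) *
    sample(c(-1, 1), n * (n - 1) / 2, replace = TRUE)
  C[upper.tri(C)] <- vals
  C <- C + t(C); diag(C) <- 1
  make_net(C, contact)
}

# Exhaustive enumeration of ALL simple paths s -> t (no pruning): the
# brute-force oracle for shortest distances and bounded path sets.
brute_paths <- function(net, s, t) {
  W <- net$W
  n <- nrow(W)
  paths <- list(); lens <- numeric(0)
  visited <- rep(FALSE, n)
  rec <- function(u, cur, len) {
    if (u == t) {
      paths[[length(paths) + 1L]] <<- cur
      lens[length(lens) + 1L] <<- len
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (!visited[v] && is.finite(W[u, v])) {
        visited[v] <<- TRUE
        rec(v, c(cur, v), len + W[u, v])
        visited[v] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  rec(s, s, 0)
  list(paths = paths, lengths = lens)
}

path_key <- function(nodes) paste(nodes, collapse = ",")

# Wrap a covariance into a minimal model accepted by sample_trajectory
# (line geometry, irrelevant for correlation-only tests).
cov_model <- function(cov, amplitude = 1, spacing = 10) {
  n <- nrow(cov$C)
  coords <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  list(geometry = list(coords = coords), covariance = cov,
       amplitude = amplitude, frame_interval_ps = 1)
}

# Direct sample-statistic estimate of the displacement correlation of two
# nodes, computed from raw coordinates without the package's DCCM path.
direct_pair_cor <- function(xyz, i, j) {
  Xi <- xyz[, (3 * i - 2):(3 * i)]; Xj <- xyz[, (3 * j - 2):(3 * j)]
  Di <- sweep(Xi, 2, colMeans(Xi)); Dj <- sweep(Xj, 2, colMeans(Xj))
  mean(rowSums(Di * Dj)) / sqrt(mean(rowSums(Di^2)) * mean(rowSums(Dj^2)))
}

# Minimal in-memory traj_ensemble
as_traj <- function(xyz, superposed = TRUE, interval = 1) {
  structure(list(xyz = xyz, frame_interval_ps = interval,
                 superposed = superposed, source = "fixture"),
            class = "traj_ensemble")
}

# Write a small PDB from an atom table (fixture generator)
write_fixture_pdb <- function(atoms, file) {
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, chain = atoms$chain,
                   resid = atoms$resname, elety = atoms$elety)
  file
}
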