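# Synthetic correlated-motion generator with planted ground truth.
#
# The generator produces coarse-grained pseudo-structures (one atom per node)
# whose contact graph is known exactly by construction, together with a
# node-displacement correlation matrix containing planted community blocks
# and a planted high-correlation chain (the pathway).  Trajectories sampled
# from the model converge to the specified correlations, so every downstream
# stage (DCCM, contact filtering, path search, community detection) can be
# checked against ground truth.

# ---- geometry -------------------------------------------------------------

# Local node coordinates for the supported chain shapes, oriented along +x.
# "line": straight chain, `spacing` between consecutive nodes; only
#   sequence-adjacent pairs fall inside the contact cutoff.
# "bipyramid": triangular bipyramid with edge `contact_distance` (5 nodes:
#   apex, 3 base nodes, apex).  Every pair is a contact except apex-apex
#   (separation 1.633 * edge > 6 A for edges > 3.68 A).  Used to build dense
#   "domain" blocks whose internal contacts are not sequence-adjacent.
shape_coords <- function(shape, n, spacing, contact_distance) {
  if (shape == "line") {
    cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
  } else if (shape == "bipyramid") {
    if (n != 5L) stop("shape 'bipyramid' requires exactly 5 nodes")
    e <- contact_distance
    r <- e / sqrt(3)                  # base-triangle circumradius
    h <- sqrt(e^2 - r^2)              # apex height above base plane
    ang <- c(90, 210, 330) * pi / 180
    rbind(
      c(0, 0, 0),                                    # apex 1 (entry)
      cbind(h, r * cos(ang), r * sin(ang)),          # base triangle
      c(2 * h, 0, 0)                                 # apex 2 (exit)
    )
  } else {
    stop("unknown chain shape: ", shape)
  }
}

#' Construct a synthetic pseudo-structure with a declared contact graph
#'
#' Lays out chains of pseudo-residues (one atom per node) along the x axis
#' and verifies that the realised contact graph is exactly the declared one:
#' declared contact pairs sit below 4.5 A while all other pairs are kept
#' beyond 6 A, so that contacts survive displacement noise and non-contacts
#' never cross the cutoff.
#'
#' @param chains list of chain specifications; each element is a list with
#'   \code{chain} (single-letter id), \code{n} (node count) and optionally
#'   \code{shape} (\code{"line"}, default, or \code{"bipyramid"}) and
#'   \code{resno} (residue numbers; defaults to consecutive for lines and to
#'   odd numbers for bipyramids so that intra-shape contacts are not
#'   sequence-adjacent).
#' @param spacing backbone-like distance between consecutive nodes of a
#'   \code{"line"} chain, in Angstrom.
#' @param contact_distance distance at which declared (non-backbone) contacts
#'   are realised, in Angstrom; must be below the 4.5 A contact cutoff.
#' @param bridges list of 2-element character vectors naming chain pairs to
#'   join by an inter-chain contact.  A bridge is realised between the exit
#'   node of the first chain and the entry node of the second, which must be
#'   consecutive in \code{chains}.
#' @param clearance minimum separation imposed between chains that are not
#'   bridged, in Angstrom.
#'
#' @return An object of class \code{synthetic_geometry}: a list with
#'   \code{node_model}, \code{coords} (n x 3 mean coordinates) and
#'   \code{contacts} (data frame of declared contact pairs with a
#'   \code{sequence_adjacent} flag).
#' @export
make_geometry <- function(chains, spacing = 3.8, contact_distance = 4.0,
                          bridges = NULL, clearance = 12) {
  if (length(chains) == 0L) stop("empty geometry specification: no chains given")
  if (contact_distance >= 4.5)
    stop("contact_distance must be below the 4.5 A contact cutoff")

  info <- lapply(chains, function(ch) {
    if (is.null(ch$chain) || is.null(ch$n)) stop("each chain needs 'chain' and 'n'")
    if (ch$n < 1L) stop("chain ", ch$chain, " has no nodes")
    shape <- if (is.null(ch$shape)) "line" else ch$shape
    xyz <- shape_coords(shape, ch$n, spacing, contact_distance)
    resno <- if (!is.null(ch$resno)) ch$resno
             else if (shape == "line") seq_len(ch$n)
             else seq(1L, by = 2L, length.out = ch$n)
    list(chain = ch$chain, n = ch$n, shape = shape, xyz = xyz, resno = resno)
  })

  bridged <- rep(FALSE, length(info))   # bridge between chain k and k+1?
  if (!is.null(bridges)) {
    ids <- vapply(info, `[[`, "", "chain")
    for (b in bridges) {
      k <- match(b[1], ids)
      if (is.na(k) || k == length(ids) || ids[k + 1] != b[2])
        stop("bridge ", b[1], "-", b[2], " must join consecutive chains; ",
             "bridges between non-consecutive chains cannot be realised ",
             "without violating the 6 A clearance rule")
      bridged[k] <- TRUE
    }
  }

  # place chains along +x
  coords <- NULL; offset <- 0
  for (k in seq_along(info)) {
    xyz <- info[[k]]$xyz
    if (k > 1L) {
      gap <- if (bridged[k - 1L]) contact_distance else clearance
      offset <- offset + gap
    }
    xyz[, 1] <- xyz[, 1] + offset
    offset <- max(xyz[, 1])
    coords <- rbind(coords, xyz)
  }

  nn <- sum(vapply(info, `[[`, 0, "n"))
  chain_id <- unlist(lapply(info, function(i) rep(i$chain, i$n)))
  resno <- unlist(lapply(info, `[[`, "resno"))

  # declared contact set
  exp_pairs <- NULL
  start <- 0L
  starts <- integer(length(info)); ends <- integer(length(info))
  for (k in seq_along(info)) {
    n <- info[[k]]$n
    starts[k] <- start + 1L; ends[k] <- start + n
    if (info[[k]]$shape == "line") {
      if (n > 1L)
        exp_pairs <- rbind(exp_pairs,
                           cbind(start + seq_len(n - 1L), start + 2:n, TRUE))
    } else {                            # bipyramid: all pairs but apex-apex
      cmb <- t(utils::combn(seq_len(n), 2L))
      keep <- !(cmb[, 1] == 1L & cmb[, 2] == n)
      adj <- abs(resno[start + cmb[, 1]] - resno[start + cmb[, 2]]) == 1L
      exp_pairs <- rbind(exp_pairs,
                         cbind(start + cmb[keep, 1], start + cmb[keep, 2], adj[keep]))
    }
    start <- start + n
  }
  for (k in which(bridged))
    exp_pairs <- rbind(exp_pairs, cbind(ends[k], starts[k + 1L], FALSE))

  # exhaustive verification of the realised contact graph
  d <- as.matrix(stats::dist(coords))
  declared <- matrix(FALSE, nn, nn)
  declared[exp_pairs[, 1:2, drop = FALSE]] <- TRUE
  declared <- declared | t(declared)
  up <- upper.tri(d)
  bad_far  <- which(declared & d >= 4.5 & up, arr.ind = TRUE)
  bad_near <- which(!declared & d <= 6.0 & up, arr.ind = TRUE)
  if (nrow(bad_far) + nrow(bad_near) > 0L) {
    fmt <- function(m) paste(apply(m, 1L, function(r)
      sprintf("%s%d-%s%d (%.2f A)", chain_id[r[1]], resno[r[1]],
              chain_id[r[2]], resno[r[2]], d[r[1], r[2]])), collapse = ", ")
    msg <- c(
      if (nrow(bad_far))  paste0("declared contacts beyond 4.5 A: ", fmt(bad_far)),
      if (nrow(bad_near)) paste0("undeclared pairs within 6 A: ",   fmt(bad_near)))
    stop("geometry rejected: ", paste(msg, collapse = "; "))
  }

  atoms <- data.frame(
    atom_id = seq_len(nn), chain = chain_id, resno = resno,
    resname = "ALA", elety = "CA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  nodes <- data.frame(
    node_id = seq_len(nn) - 1L, chain = chain_id, resno = resno,
    role = "calpha", repr_atom = seq_len(nn), stringsAsFactors = FALSE)
  nodes$label <- node_labels(nodes)
  nm <- structure(list(nodes = nodes,
                       members = as.list(seq_len(nn)),
                       atoms = atoms),
                  class = "node_model")

  contacts <- data.frame(i = exp_pairs[, 1], j = exp_pairs[, 2],
                         sequence_adjacent = as.logical(exp_pairs[, 3]))
  contacts$distance <- d[cbind(contacts$i, contacts$j)]

  structure(list(node_model = nm, coords = coords, contacts = contacts),
            class = "synthetic_geometry")
}

# ---- covariance -----------------------------------------------------------

#' Node-displacement correlation matrix with planted blocks and pathway
#'
#' Builds an exact correlation matrix from a latent Gaussian factor model:
#' each block (community) has a unit-variance factor, block factors are
#' mutually correlated by \eqn{\gamma = \rho_{bg}/\rho_{block}} so that
#' between-block correlations equal \eqn{\rho_{bg}}, and the planted pathway
#' is driven by a nonstationary AR(1) latent chain.  A path node mixes the
#' chain (variance fraction \code{path_var_frac}) with its block factor;
#' chain step coefficients are solved so that consecutive path-edge
#' correlations equal \eqn{\rho_{path}} wherever attainable (steps that
#' would require a coefficient above 1 saturate, which affects only
#' block-crossing steps; the exact achieved values are recorded).  The
#' construction is a Gram matrix, hence positive semi-definite by design;
#' an eigenvalue assertion guards the implementation.
#'
#' @param n_nodes number of nodes.
#' @param blocks list of integer vectors (1-based node indices) defining the
#'   planted community blocks; nodes in no block behave as singletons with
#'   background correlation to everything.
#' @param planted_path ordered integer vector of node indices forming the
#'   planted pathway, or NULL.
#' @param rho_path,rho_block,rho_bg target correlations for consecutive
#'   planted-path pairs, within-block pairs and all remaining pairs;
#'   must satisfy \code{0 <= rho_bg < rho_block < rho_path <= 1}.
#' @param path_var_frac fraction of a path node's variance carried by the
#'   latent path chain (the rest couples it to its block factor).
#'
#' @return Object of class \code{synthetic_covariance}: list with the exact
#'   correlation matrix \code{C}, the block assignment, the planted path,
#'   a data frame \code{path_edges} of achieved edge correlations, and the
#'   construction parameters.
#' @export
make_covariance <- function(n_nodes, blocks = NULL, planted_path = NULL,
                            rho_path = 0.9, rho_block = 0.6, rho_bg = 0.1,
                            path_var_frac = 0.85) {
  if (!(rho_bg >= 0 && rho_bg < rho_block && rho_block < rho_path && rho_path <= 1))
    stop("need 0 <= rho_bg < rho_block < rho_path <= 1")
  if (n_nodes < 1L) stop("n_nodes must be positive")

  block_of <- rep(NA_integer_, n_nodes)
  if (!is.null(blocks))
    for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  # singleton pseudo-blocks for unassigned nodes: they inherit loading
  # sqrt(rho_block) on a private factor, giving exactly rho_bg to all others
  nb <- max(c(0L, block_of), na.rm = TRUE)
  solo <- which(is.na(block_of))
  block_of[solo] <- nb + seq_along(solo)

  gamma <- rho_bg / rho_block
  on_path <- rep(FALSE, n_nodes)
  phi <- numeric(0)
  if (!is.null(planted_path)) {
    if (length(planted_path) < 2L) stop("planted_path needs at least 2 nodes")
    if (anyDuplicated(planted_path)) stop("planted_path must be a simple path")
    on_path[planted_path] <- TRUE
    a2 <- path_var_frac; c2 <- 1 - path_var_frac
    steps <- cbind(planted_path[-length(planted_path)], planted_path[-1L])
    same_blk <- block_of[steps[, 1]] == block_of[steps[, 2]]
    phi <- (rho_path - c2 * ifelse(same_blk, 1, gamma)) / a2
    if (any(phi <= 0))
      stop("rho_path too small relative to the block coupling; ",
           "increase rho_path or path_var_frac")
    phi <- pmin(phi, 1)               # saturating steps fall short of rho_path
  }

  a2 <- path_var_frac; c2 <- 1 - path_var_frac
  pos <- match(seq_len(n_nodes), planted_path)   # position along path or NA
  same <- outer(block_of, block_of, "==")
  gfac <- ifelse(same, 1, gamma)                 # block-factor covariance

  C <- matrix(rho_bg, n_nodes, n_nodes)
  C[same] <- rho_block
  if (!is.null(planted_path)) {
    p <- on_path
    # path-nonpath: c * sqrt(rho_block) * gfac
    C[p, !p] <- sqrt(c2) * sqrt(rho_block) * gfac[p, !p, drop = FALSE]
    C[!p, p] <- t(C[p, !p, drop = FALSE])
    # path-path: a^2 * prod(phi) + c^2 * gfac
    idx <- which(p)
    cphi <- c(1, cumprod(phi))                   # cphi[k] = prod(phi[1..k-1])
    for (i in idx) for (j in idx) {
      if (i == j) next
      k1 <- min(pos[i], pos[j]); k2 <- max(pos[i], pos[j])
      C[i, j] <- a2 * cphi[k2] / cphi[k1] + c2 * gfac[i, j]
    }
  }
  diag(C) <- 1

  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("internal error: constructed covariance is not PSD (min eigenvalue ",
         format(min(ev)), ")")

  path_edges <- NULL
  if (!is.null(planted_path)) {
    steps <- cbind(planted_path[-length(planted_path)], planted_path[-1L])
    path_edges <- data.frame(i = steps[, 1], j = steps[, 2],
                             cor = C[steps], phi = phi)
  }
  structure(list(C = C, block_of = block_of, blocks = blocks,
                 planted_path = planted_path, path_edges = path_edges,
                 params = list(rho_path = rho_path, rho_block = rho_block,
                               rho_bg = rho_bg, path_var_frac = path_var_frac,
                               gamma = gamma)),
            class = "synthetic_covariance")
}

# ---- full model -----------------------------------------------------------

#' Canonical synthetic benchmark model
#'
#' Two dense 5-node "domain" blocks (triangular bipyramids, chains A and B)
#' joined by a single inter-domain contact, with a planted communication
#' pathway apex-base-apex-bridge-apex-base-apex (nodes 1, 2, 5, 6, 7, 10)
#' and the two chains as planted communities.  Defaults define the reference
#' study conditions used throughout the package tests: correlations
#' 0.9/0.6/0.1 (path/block/background), isotropic displacement amplitude
#' 0.35 A and a 1 ps frame interval.
#'
#' @param rho_path,rho_block,rho_bg planted correlations (see
#'   \code{\link{make_covariance}}).
#' @param amplitude per-axis displacement standard deviation, in Angstrom;
#'   scalar or per-node vector.
#' @param frame_interval_ps sampling interval attached to generated
#'   trajectories, in picoseconds.
#' @param path_var_frac see \code{\link{make_covariance}}.
#'
#' @return Object of class \code{synthetic_model}: geometry, covariance,
#'   planted path/partition, source and sink anchors, amplitude and frame
#'   interval.
#' @export
synthetic_model <- function(rho_path = 0.9, rho_block = 0.6, rho_bg = 0.1,
                            amplitude = 0.35, frame_interval_ps = 1,
                            path_var_frac = 0.85) {
  geo <- make_geometry(
    chains = list(list(chain = "A", n = 5L, shape = "bipyramid"),
                  list(chain = "B", n = 5L, shape = "bipyramid")),
    bridges = list(c("A", "B")))
  blocks <- list(A = 1:5, B = 6:10)
  path <- c(1L, 2L, 5L, 6L, 7L, 10L)
  cov <- make_covariance(10L, blocks = blocks, planted_path = path,
                         rho_path = rho_path, rho_block = rho_block,
                         rho_bg = rho_bg, path_var_frac = path_var_frac)
  structure(list(geometry = geo, covariance = cov,
                 planted_path = path,
                 planted_partition = rep(c(1L, 2L), each = 5L),
                 source = 1L, sink = 10L,
                 amplitude = amplitude,
                 frame_interval_ps = frame_interval_ps),
            class = "synthetic_model")
}

#' Sample a correlated-motion trajectory from a synthetic model
#'
#' Frames are the mean coordinates plus Gaussian displacements with the
#' model's node-node correlation applied identically and independently per
#' Cartesian axis (unit per-axis variance scaled by the per-node amplitude),
#' so the displacement DCCM of the samples converges to the model
#' correlation matrix exactly.
#'
#' @param model a \code{synthetic_model} (or any list with \code{geometry},
#'   \code{covariance}, \code{amplitude}, \code{frame_interval_ps}).
#' @param n_frames number of frames (at least 2).
#' @param seed integer RNG seed; required, so runs are reproducible.
#'
#' @return A \code{traj_ensemble} (see \code{\link{load_trajectory}}).
#' @export
sample_trajectory <- function(model, n_frames, seed) {
  if (missing(seed)) stop("'seed' is required: sampling must be reproducible")
  if (n_frames < 2L) stop("n_frames must be at least 2 (correlations undefined)")
  C <- model$covariance$C
  n <- nrow(C)
  amp <- rep(model$amplitude, length.out = n)
  eg <- eigen(C, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  mu <- model$geometry$coords
  xyz <- matrix(NA_real_, n_frames, 3L * n)
  with_seed(seed, {
    for (ax in 1:3) {
      Z <- matrix(rnorm(n_frames * n), n_frames, n)
      disp <- Z %*% t(A)
      xyz[, seq(ax, 3L * n, by = 3L)] <-
        sweep(disp, 2L, amp, `*`) + rep(mu[, ax], each = n_frames)
    }
  })
  structure(list(xyz = xyz,
                 frame_interval_ps = model$frame_interval_ps,
                 superposed = TRUE,   # generative model has no rigid-body drift
                 source = sprintf("synthetic (n_frames=%d, seed=%d)",
                                  n_frames, as.integer(seed))),
            class = "traj_ensemble")
}

#' Ground truth of a synthetic model
#'
#' Exposes what downstream recovery tests assert against: the planted path,
#' the planted partition, and the exact expected edge correlations and
#' network weights (\eqn{-\ln \rho}) of the planted-path edges.
#'
#' @param model a \code{synthetic_model}.
#' @return list with \code{planted_path}, \code{planted_partition},
#'   \code{path_edges} (data frame with exact expected correlation and
#'   weight per planted edge), \code{min_corr} and the declared contact
#'   pairs.
#' @export
ground_truth <- function(model) {
  pe <- model$covariance$path_edges
  pe$expected_weight <- -log(pe$cor)
  list(planted_path = model$planted_path,
       planted_partition = model$planted_partition,
       path_edges = pe,
       min_corr = min(pe$cor),
       contacts = model$geometry$contacts)
}

#' Write a synthetic system to disk
#'
#' Writes the topology as a PDB file (one pseudo-atom per node), optionally
#' a sampled trajectory as a multi-model PDB, and the ground truth as a JSON
#' sidecar (planted path, partition labels, covariance parameters, seed).
#'
#' @param model a \code{synthetic_model}.
#' @param prefix output path prefix.
#' @param trajectory optional \code{traj_ensemble} to write.
#' @param seed seed recorded in the sidecar (if known).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_system <- function(model, prefix, trajectory = NULL, seed = NULL) {
  nm <- model$geometry$node_model
  top <- paste0(prefix, "_topology.pdb")
  write_trajectory_pdb(
    structure(list(xyz = matrix(t(model$geometry$coords), nrow = 1L),
                   frame_interval_ps = model$frame_interval_ps,
                   superposed = TRUE, source = "synthetic mean structure"),
              class = "traj_ensemble"),
    nm, top)
  files <- top
  if (!is.null(trajectory)) {
    trj <- paste0(prefix, "_traj.pdb")
    write_trajectory_pdb(trajectory, nm, trj)
    files <- c(files, trj)
  }
  gt <- ground_truth(model)
  side <- paste0(prefix, "_truth.json")
  jsonlite::write_json(
    list(planted_path = gt$planted_path,
         planted_partition = gt$planted_partition,
         path_edge_cor = gt$path_edges$cor,
         params = model$covariance$params,
         amplitude = model$amplitude,
         frame_interval_ps = model$frame_interval_ps,
         seed = seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(files, side))
}
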