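# Structure / trajectory input, node-model construction, superposition and
# per-pair distance series.

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
         "MSE","HSD","HSE","HSP","HIE","HID","HIP")
NT_DNA    <- c("DA","DC","DG","DT","DI")
NT_RNA    <- c("A","C","G","U","I","RA","RC","RG","RU")
NT_FREE   <- c("ATP","ADP","AMP","ANP","AGS","GTP","GDP","GNP")
PURINE    <- c("DA","DG","DI","A","G","I","RA","RG","ATP","ADP","AMP","ANP",
               "AGS","GTP","GDP","GNP")
# base-side heavy atoms: ring system plus exocyclic substituents and the
# glycosidic C1'; everything else (phosphate + sugar) goes to the P node
BASE_ATOMS <- c("N1","C2","N3","C4","C5","C6","N7","C8","N9",
                "O2","O4","O6","N2","N4","N6","C7","C5M","C1'")

norm_elety <- function(x) gsub("\\*", "'", toupper(x))
is_hydrogen <- function(elety) grepl("^[0-9]?H", elety)

#' Build the coarse-grained node model from a PDB structure
#'
#' One node per amino-acid residue at the C-alpha; two nodes per nucleotide
#' residue, a base node (representative N9 for purines, N1 for pyrimidines)
#' and a phosphate node (representative PA for free nucleotides such as
#' ATP/ADP, P for the nucleic-acid backbone).  Base-side member atoms are
#' the ring system plus C1'; the phosphate node takes the phosphate group
#' and the remaining sugar atoms.  Hydrogens are excluded from member
#' lists; alternate locations keep the highest-occupancy conformer; residue
#' types that are neither protein nor nucleotide are skipped with a warning.
#'
#' @param structure_file path to a PDB file.
#' @return Object of class \code{node_model}: list with \code{nodes}
#'   (data frame: 0-based \code{node_id}, \code{chain}, \code{resno} as
#'   authored in the file, \code{role} = \code{"calpha"}, \code{"base"} or
#'   \code{"phosphate"}, \code{repr_atom}, \code{label}), \code{members}
#'   (heavy-atom index list per node) and \code{atoms} (the atom table the
#'   indices refer to).
#' @export
load_topology <- function(structure_file) {
  pdb <- bio3d::read.pdb(structure_file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$elety <- norm_elety(at$elety)
  at <- at[!is_hydrogen(at$elety), , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per (chain, resno, name)
  if (any(!(at$alt %in% c("", " ", NA)))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(at$chain, at$resno, at$elety, -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(at[, c("chain", "resno", "elety")]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  atoms <- data.frame(atom_id = seq_len(nrow(at)),
                      chain = at$chain, resno = at$resno,
                      resname = toupper(at$resid), elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)

  res_key <- paste(atoms$chain, atoms$resno, sep = "\r")
  res_idx <- split(seq_len(nrow(atoms)), factor(res_key, levels = unique(res_key)))

  nodes <- list(); members <- list(); skipped <- character(0)
  for (ri in res_idx) {
    rn <- atoms$resname[ri[1]]; ch <- atoms$chain[ri[1]]; no <- atoms$resno[ri[1]]
    if (rn %in% AA3) {
      ca <- ri[atoms$elety[ri] == "CA"]
      if (length(ca) == 0L)
        stop("residue ", ch, ":", no, " (", rn, ") lacks its representative CA atom")
      nodes[[length(nodes) + 1L]] <-
        list(chain = ch, resno = no, role = "calpha", repr = ca[1])
      members[[length(members) + 1L]] <- ri
    } else if (rn %in% c(NT_DNA, NT_RNA, NT_FREE)) {
      base_repr_name <- if (rn %in% PURINE) "N9" else "N1"
      p_repr_name <- if (rn %in% NT_FREE) "PA" else "P"
      b_mem <- ri[atoms$elety[ri] %in% BASE_ATOMS]
      p_mem <- setdiff(ri, b_mem)
      b_repr <- ri[atoms$elety[ri] == base_repr_name]
      p_repr <- ri[atoms$elety[ri] == p_repr_name]
      if (length(b_repr) == 0L)
        stop("nucleotide ", ch, ":", no, " (", rn, ") lacks its representative ",
             base_repr_name, " atom")
      if (length(p_repr) == 0L)
        stop("nucleotide ", ch, ":", no, " (", rn, ") lacks its representative ",
             p_repr_name, " atom")
      nodes[[length(nodes) + 1L]] <-
        list(chain = ch, resno = no, role = "base", repr = b_repr[1])
      members[[length(members) + 1L]] <- b_mem
      nodes[[length(nodes) + 1L]] <-
        list(chain = ch, resno = no, role = "phosphate", repr = p_repr[1])
      members[[length(members) + 1L]] <- p_mem
    } else {
      skipped <- c(skipped, rn)
    }
  }
  if (length(skipped))
    warning("skipped residues of unknown type: ",
            paste(unique(skipped), collapse = ", "))
  if (length(nodes) == 0L) stop("no protein or nucleotide residues found")

  nd <- data.frame(
    node_id = seq_along(nodes) - 1L,
    chain = vapply(nodes, `[[`, "", "chain"),
    resno = vapply(nodes, function(x) as.integer(x$resno), 0L),
    role  = vapply(nodes, `[[`, "", "role"),
    repr_atom = vapply(nodes, function(x) as.integer(x$repr), 0L),
    stringsAsFactors = FALSE)
  nd$label <- node_labels(nd)
  structure(list(nodes = nd, members = members, atoms = atoms),
            class = "node_model")
}

#' @export
print.node_model <- function(x, ...) {
  cat("node_model:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "calpha"), "C-alpha,",
      sum(x$nodes$role != "calpha"), "nucleotide ) over",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Load coordinate frames for a node model
#'
#' Reads one or more multi-model PDB trajectory files and concatenates the
#' frames in the given order.  The atom count of every file must match the
#' topology.
#'
#' @param files character vector of multi-model PDB files.
#' @param node_model the topology the frames belong to.
#' @param frame_interval_ps sampling interval of the frames, in picoseconds.
#' @return Object of class \code{traj_ensemble}: list with \code{xyz}
#'   (frames x 3*atoms matrix, bio3d ordering), \code{frame_interval_ps},
#'   \code{superposed} flag and a \code{source} description.
#' @export
load_trajectory <- function(files, node_model, frame_interval_ps = 1) {
  stopifnot_node_model(node_model)
  if (frame_interval_ps <= 0) stop("frame_interval_ps must be positive")
  natoms <- nrow(node_model$atoms)
  xyz <- NULL
  for (f in files) {
    p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
    m <- p$xyz
    if (ncol(m) != 3L * natoms)
      stop("atom-count mismatch in ", f, ": trajectory has ", ncol(m) / 3,
           " atoms, topology has ", natoms)
    xyz <- rbind(xyz, m)
  }
  if (is.null(xyz) || nrow(xyz) == 0L) stop("no frames read")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  structure(list(xyz = unclass(xyz), frame_interval_ps = frame_interval_ps,
                 superposed = FALSE,
                 source = paste(files, collapse = "+")),
            class = "traj_ensemble")
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a \code{traj_ensemble}.
#' @param node_model matching topology (provides chain/residue/atom names).
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_trajectory_pdb <- function(traj, node_model, file) {
  stopifnot_trajectory(traj); stopifnot_node_model(node_model)
  a <- node_model$atoms
  if (ncol(traj$xyz) != 3L * nrow(a))
    stop("atom-count mismatch between trajectory and topology")
  bio3d::write.pdb(file = file, xyz = traj$xyz, resno = a$resno,
                   chain = a$chain, resid = a$resname, elety = a$elety)
  invisible(file)
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("traj_ensemble:", nrow(x$xyz), "frames x", ncol(x$xyz) / 3, "atoms;",
      "interval", x$frame_interval_ps, "ps;",
      if (isTRUE(x$superposed)) "superposed" else "not superposed", "\n")
  invisible(x)
}

#' Remove rigid-body motion by iterated least-squares superposition
#'
#' Each frame is fitted to the ensemble mean structure by a proper rigid-body
#' rotation/translation (Kabsch); the mean is then recomputed from the
#' fitted frames and the fit repeated until the coordinates stabilise, so
#' that displacements entering the DCCM contain no residual global rotation
#' or translation and the operation is a fixed point (superposing an
#' already-superposed ensemble leaves it unchanged).
#'
#' @param traj a \code{traj_ensemble}.
#' @param node_model optional topology; its representative atoms are the
#'   default fitting selection.
#' @param selection atom indices used for the fit (default: representative
#'   atoms of \code{node_model}, or all atoms); at least 3.
#' @param iterations maximum number of fit-to-mean passes; iteration stops
#'   early once coordinates change by less than \code{tol}.
#' @param tol convergence threshold on the largest coordinate change
#'   between passes, in Angstrom.
#' @return the superposed \code{traj_ensemble}.
#' @export
superpose_trajectory <- function(traj, node_model = NULL, selection = NULL,
                                 iterations = 10L, tol = 1e-8) {
  stopifnot_trajectory(traj)
  natoms <- ncol(traj$xyz) / 3L
  if (is.null(selection))
    selection <- if (!is.null(node_model)) node_model$nodes$repr_atom
                 else seq_len(natoms)
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selection atoms")
  sel3 <- xyz_cols(selection)
  xyz <- traj$xyz
  for (i in seq_len(iterations)) {
    mref <- colMeans(xyz)
    prev <- xyz
    xyz <- bio3d::fit.xyz(fixed = mref, mobile = xyz,
                          fixed.inds = sel3, mobile.inds = sel3)
    if (max(abs(xyz - prev)) < tol) break
  }
  out <- traj
  out$xyz <- unclass(xyz)
  out$superposed <- TRUE
  out
}

#' Per-frame distance series between two nodes
#'
#' Distances are measured between the representative atoms of the two nodes
#' in every frame (the analysis behind distance-distribution panels such as
#' an inter-residue C-alpha distance histogram).
#'
#' @param traj a \code{traj_ensemble}.
#' @param node_model the topology.
#' @param node_a,node_b node indices (1-based) or node labels
#'   (\code{"chain:resno"}); must differ.
#' @param breaks passed to \code{hist}.
#' @return Object of class \code{distance_series}: list with per-frame
#'   \code{distances}, \code{mean}, \code{sd}, \code{histogram} (a
#'   \code{hist} object, not plotted) and the node labels.
#' @export
pair_distance_series <- function(traj, node_model, node_a, node_b,
                                 breaks = "Sturges") {
  stopifnot_trajectory(traj); stopifnot_node_model(node_model)
  resolve <- function(x) {
    if (is.character(x)) {
      i <- match(x, node_model$nodes$label)
      if (is.na(i)) stop("unknown node label: ", x)
      i
    } else as.integer(x)
  }
  a <- resolve(node_a); b <- resolve(node_b)
  if (a == b) stop("node_a and node_b must differ")
  d <- atom_pair_dist(traj$xyz, node_model$nodes$repr_atom[a],
                      node_model$nodes$repr_atom[b])
  structure(list(distances = d, mean = mean(d), sd = stats::sd(d),
                 histogram = graphics::hist(d, breaks = breaks, plot = FALSE),
                 labels = node_model$nodes$label[c(a, b)],
                 frame_interval_ps = traj$frame_interval_ps),
            class = "distance_series")
}

#' Write a distance series as TSV (frame, distance in Angstrom)
#' @param x a \code{distance_series}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_distance_series <- function(x, file) {
  utils::write.table(
    data.frame(frame = seq_along(x$distances),
               distance_A = sprintf("%.4f", x$distances)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
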