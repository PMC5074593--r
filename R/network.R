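# Contact filtering and construction of the correlation-weighted dynamic
# network.

#' Persistent-contact map of a node model over a trajectory
#'
#' A pair of nodes (excluding neighbouring nodes) is a contact when the
#' minimum distance between their member heavy atoms is within
#' \code{cutoff} in more than \code{fraction} of the frames.  Neighbouring
#' nodes are sequence-adjacent residues of the same chain
#' (|delta resno| = 1) and the two nodes of the same nucleotide, whose
#' trivially correlated covalent coupling would otherwise dominate paths.
#' Distances are frame-internal, so the trajectory need not be superposed.
#'
#' @param traj a \code{traj_ensemble}.
#' @param node_model the topology.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param fraction occupancy threshold; "more than" is strict.
#' @param mode \code{"heavy"}: minimum over member heavy-atom pairs
#'   (default, the established protocol); \code{"point"}: representative
#'   atoms only (sensitivity checks).
#' @param exclude_neighbors apply the neighbour exclusion.
#' @return Object of class \code{contact_map}: list with logical
#'   \code{contact} matrix, per-pair occupancy \code{fraction} matrix, the
#'   exclusion mask and the parameters.
#' @export
compute_contacts <- function(traj, node_model, cutoff = 4.5, fraction = 0.75,
                             mode = c("heavy", "point"),
                             exclude_neighbors = TRUE) {
  stopifnot_trajectory(traj); stopifnot_node_model(node_model)
  mode <- match.arg(mode)
  nd <- node_model$nodes
  n <- nrow(nd)
  if (mode == "heavy" &&
      any(vapply(node_model$members, length, 0L) == 0L))
    stop("node(s) with empty member-atom lists")

  excl <- matrix(FALSE, n, n)
  if (exclude_neighbors) {
    same_chain <- outer(nd$chain, nd$chain, "==")
    dres <- abs(outer(nd$resno, nd$resno, "-"))
    excl <- same_chain & (dres == 1L | dres == 0L)
  }
  diag(excl) <- TRUE

  frac <- matrix(NA_real_, n, n)
  nf <- nrow(traj$xyz)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (excl[i, j]) next
      if (mode == "point") {
        dmin <- atom_pair_dist(traj$xyz, nd$repr_atom[i], nd$repr_atom[j])
      } else {
        dmin <- rep(Inf, nf)
        for (a in node_model$members[[i]])
          for (b in node_model$members[[j]])
            dmin <- pmin(dmin, atom_pair_dist(traj$xyz, a, b))
      }
      frac[i, j] <- frac[j, i] <- mean(dmin <= cutoff)
    }
  }
  contact <- !is.na(frac) & frac > fraction
  dimnames(contact) <- dimnames(frac) <- list(nd$label, nd$label)
  structure(list(contact = contact, fraction = frac, excluded = excl,
                 cutoff = cutoff, fraction_threshold = fraction,
                 mode = mode, node_model = node_model),
            class = "contact_map")
}

#' Build the correlation-weighted dynamic network
#'
#' Every persistent contact becomes an undirected edge weighted by
#' \eqn{w_{ij} = -\ln|C_{ij}|} (natural logarithm), so strongly correlated
#' contacts are short and weakly correlated ones long.  \eqn{|C_{ij}|} is
#' floored at \code{cor_floor} so weights stay finite; the signed
#' correlation is retained on each edge.  The graph may be disconnected.
#'
#' @param contacts a \code{contact_map}.
#' @param dccm a \code{dccm_matrix} over the same node set.
#' @param cor_floor lower bound applied to \eqn{|C_{ij}|} before the log.
#' @return Object of class \code{dynamic_network}: list with \code{edges}
#'   (data frame: i, j, labels, cor, abs_cor, weight, contact_fraction),
#'   the weight matrix \code{W} (Inf for non-edges), the correlation matrix
#'   \code{C}, \code{n} and \code{labels}.
#' @export
build_network <- function(contacts, dccm, cor_floor = 1e-6) {
  if (!inherits(contacts, "contact_map")) stop("'contacts' must be a contact_map")
  C <- unclass(dccm)
  n <- nrow(contacts$contact)
  if (!is.matrix(C) || nrow(C) != n || ncol(C) != n)
    stop("dimension mismatch between contact map (", n, " nodes) and DCCM (",
         nrow(C), ")")
  idx <- which(contacts$contact & upper.tri(contacts$contact), arr.ind = TRUE)
  cor_ij <- C[idx]
  if (any(is.na(cor_ij))) {
    bad <- idx[is.na(cor_ij), , drop = FALSE]
    stop("contact edge(s) touch a node with undefined correlation ",
         "(zero displacement variance): ",
         paste(rownames(contacts$contact)[bad[, 1]],
               colnames(contacts$contact)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  abs_cor <- pmin(pmax(abs(cor_ij), cor_floor), 1)
  w <- -log(abs_cor)
  labels <- rownames(contacts$contact)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      label_i = labels[idx[, 1]], label_j = labels[idx[, 2]],
                      cor = cor_ij, abs_cor = abs_cor, weight = w,
                      contact_fraction = contacts$fraction[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  W <- matrix(Inf, n, n, dimnames = list(labels, labels))
  W[cbind(edges$i, edges$j)] <- edges$weight
  W[cbind(edges$j, edges$i)] <- edges$weight
  structure(list(edges = edges, W = W, C = C, n = n, labels = labels,
                 node_model = contacts$node_model,
                 params = list(cutoff = contacts$cutoff,
                               fraction_threshold = contacts$fraction_threshold,
                               mode = contacts$mode, cor_floor = cor_floor)),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("dynamic_network:", x$n, "nodes,", nrow(x$edges), "edges;",
      "w_ij = -ln|C_ij| on contacts (cutoff", x$params$cutoff, "A, occupancy >",
      x$params$fraction_threshold, ")\n")
  invisible(x)
}

#' Write the network edge list as TSV
#' @param net a \code{dynamic_network}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_edge_list <- function(net, file) {
  e <- net$edges
  out <- data.frame(node_i = e$i, node_j = e$j,
                    label_i = e$label_i, label_j = e$label_j,
                    cor = sprintf("%.6f", e$cor),
                    abs_cor = sprintf("%.6f", e$abs_cor),
                    weight = sprintf("%.6f", e$weight),
                    contact_fraction = sprintf("%.4f", e$contact_fraction))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a network back from an edge-list TSV
#'
#' Enables graph-only workflows and fixtures: reconstructs a
#' \code{dynamic_network} (weight and correlation entries are known for the
#' listed edges only).
#'
#' @param file TSV written by \code{\link{write_edge_list}}.
#' @param n_nodes total node count; defaults to the largest index seen.
#' @return a \code{dynamic_network}.
#' @export
read_edge_list <- function(file, n_nodes = NULL) {
  e <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("node_i", "node_j", "cor", "weight")
  if (!all(need %in% names(e)))
    stop("edge list must contain columns: ", paste(need, collapse = ", "))
  n <- if (is.null(n_nodes)) max(e$node_i, e$node_j) else n_nodes
  labels <- as.character(seq_len(n))
  have_lab <- all(c("label_i", "label_j") %in% names(e))
  if (have_lab) {
    labels[e$node_i] <- e$label_i
    labels[e$node_j] <- e$label_j
  }
  C <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  C[cbind(e$node_i, e$node_j)] <- e$cor
  C[cbind(e$node_j, e$node_i)] <- e$cor
  diag(C) <- 1
  W <- matrix(Inf, n, n, dimnames = list(labels, labels))
  W[cbind(e$node_i, e$node_j)] <- e$weight
  W[cbind(e$node_j, e$node_i)] <- e$weight
  edges <- data.frame(i = e$node_i, j = e$node_j,
                      label_i = labels[e$node_i], label_j = labels[e$node_j],
                      cor = e$cor, abs_cor = abs(e$cor), weight = e$weight,
                      contact_fraction =
                        if ("contact_fraction" %in% names(e)) e$contact_fraction
                        else NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, W = W, C = C, n = n, labels = labels,
                 node_model = NULL,
                 params = list(source = file)),
            class = "dynamic_network")
}
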