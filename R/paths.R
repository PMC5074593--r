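# Optimal and suboptimal communication pathways between anchored sites,
# with the path statistics N (hops), W (overall weight, x100 scale) and
# min (minimum pairwise correlation), and path-ensemble edge betweenness.

PATH_TOL <- 1e-9

#' All-pairs shortest path distances (Floyd-Warshall)
#'
#' Exact shortest-path distances on the dynamic network's nonnegative
#' weights.  Unreachable pairs are Inf; disconnection is a valid outcome.
#'
#' @param net a \code{dynamic_network}.
#' @return Object of class \code{apsp}: list with the distance matrix
#'   \code{D} (raw \eqn{-\ln|C|} scale).
#' @export
all_pairs_optimal <- function(net) {
  D <- net$W
  diag(D) <- 0
  n <- net$n
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  structure(list(D = D, n = n), class = "apsp")
}

new_path <- function(nodes, net) {
  ec <- net$C[cbind(nodes[-length(nodes)], nodes[-1L])]
  w <- net$W[cbind(nodes[-length(nodes)], nodes[-1L])]
  structure(list(nodes = nodes, labels = net$labels[nodes],
                 reachable = TRUE,
                 N = length(nodes) - 1L,
                 W_raw = sum(w), W = 100 * sum(w),
                 min_corr = min(abs(ec)), edge_cor = ec),
            class = "comm_path")
}

no_path <- function(source, sink) {
  structure(list(nodes = NULL, labels = NULL, reachable = FALSE,
                 N = NA_integer_, W_raw = Inf, W = Inf, min_corr = NA_real_,
                 source = source, sink = sink),
            class = "comm_path")
}

#' @export
print.comm_path <- function(x, ...) {
  if (!x$reachable) { cat("comm_path: no path\n"); return(invisible(x)) }
  cat(sprintf("comm_path: N=%d  W=%d  min=%.2f  [%s]\n",
              x$N, round(x$W), x$min_corr, paste(x$labels, collapse = " - ")))
  invisible(x)
}

#' Optimal communication path between two nodes
#'
#' Reconstructs the minimum-weight simple path; among equally short paths
#' the lexicographically smallest node sequence is returned
#' (deterministic tie-break).  A disconnected pair yields an explicit
#' "no path" result, not an error.
#'
#' @param net a \code{dynamic_network}.
#' @param source,sink node indices (1-based) or labels; must differ.
#' @param apsp optional precomputed \code{\link{all_pairs_optimal}} result.
#' @return a \code{comm_path} with fields \code{nodes}, \code{N} (hops =
#'   edges), \code{W} (overall weight on the x100 scale), \code{min_corr}.
#' @export
optimal_path <- function(net, source, sink, apsp = NULL) {
  s <- resolve_node(net, source); t <- resolve_node(net, sink)
  if (s == t) stop("source and sink must differ")
  if (is.null(apsp)) apsp <- all_pairs_optimal(net)
  D <- apsp$D
  if (!is.finite(D[s, t])) return(no_path(s, t))
  nodes <- s
  cur <- s
  visited <- rep(FALSE, net$n)
  visited[s] <- TRUE
  rem <- D[s, t]
  while (cur != t) {
    cand <- which(is.finite(net$W[cur, ]) & !visited)
    ok <- cand[abs(net$W[cur, cand] + D[cand, t] - rem) <=
                 PATH_TOL * (1 + rem)]
    if (length(ok) == 0L)
      stop("internal error: path reconstruction failed")  # nocov
    nxt <- min(ok)
    rem <- rem - net$W[cur, nxt]
    visited[nxt] <- TRUE
    nodes <- c(nodes, nxt)
    cur <- nxt
  }
  new_path(nodes, net)
}

resolve_node <- function(net, x) {
  if (is.character(x)) {
    i <- match(x, net$labels)
    if (is.na(i)) stop("unknown node label: ", x)
    return(i)
  }
  i <- as.integer(x)
  if (i < 1L || i > net$n) stop("node index out of range: ", x)
  i
}

#' All suboptimal paths within a weight offset of the optimal path
#'
#' Exhaustively enumerates every simple path whose overall weight W lies
#' within \code{offset} of the optimal W (offset on the x100 reported-weight
#' scale, e.g. the conventional 3/5/10), by bounded depth-first search with
#' the all-pairs distance table as an admissible pruning bound.  The number
#' of suboptimal paths is the path degeneracy; per-edge traversal counts
#' give the edge betweenness of the ensemble.
#'
#' @param net a \code{dynamic_network}.
#' @param source,sink node indices or labels.
#' @param offset nonnegative weight offset on the x100 scale; 0 returns
#'   exactly the set of minimum-weight paths (ties included).
#' @param cap maximum ensemble size; exceeding it is an error advising a
#'   smaller offset.
#' @param apsp optional precomputed distance table.
#' @return Object of class \code{path_ensemble}: list with \code{paths}
#'   (all \code{comm_path}s, sorted by W then lexicographically),
#'   \code{optimal}, \code{degeneracy}, \code{offset}, \code{betweenness}
#'   (per-edge traversal counts) and the anchors.
#' @export
suboptimal_paths <- function(net, source, sink, offset, cap = 1e6,
                             apsp = NULL) {
  if (offset < 0) stop("offset must be nonnegative")
  s <- resolve_node(net, source); t <- resolve_node(net, sink)
  if (s == t) stop("source and sink must differ")
  if (is.null(apsp)) apsp <- all_pairs_optimal(net)
  D <- apsp$D
  if (!is.finite(D[s, t]))
    return(structure(list(paths = list(), optimal = no_path(s, t),
                          degeneracy = 0L, offset = offset,
                          betweenness = NULL, source = s, sink = t),
                     class = "path_ensemble"))
  bound <- D[s, t] + offset / 100
  tol <- PATH_TOL * (1 + bound)
  nbrs <- lapply(seq_len(net$n), function(i) which(is.finite(net$W[i, ])))

  found <- vector("list", 64L); nfound <- 0L
  visited <- rep(FALSE, net$n)
  stack_nodes <- integer(net$n + 1L)

  dfs <- function(u, depth, len) {
    if (u == t) {
      nfound <<- nfound + 1L
      if (nfound > cap)
        stop("suboptimal ensemble exceeds cap (", cap,
             "); use a smaller offset")
      if (nfound > length(found)) length(found) <<- 2L * nfound
      found[[nfound]] <<- stack_nodes[seq_len(depth)]
      return(invisible())
    }
    for (v in nbrs[[u]]) {
      if (visited[v]) next
      nl <- len + net$W[u, v]
      if (nl + D[v, t] > bound + tol) next
      visited[v] <<- TRUE
      stack_nodes[depth + 1L] <<- v
      dfs(v, depth + 1L, nl)
      visited[v] <<- FALSE
    }
  }
  visited[s] <- TRUE
  stack_nodes[1L] <- s
  dfs(s, 1L, 0)

  paths <- lapply(found[seq_len(nfound)], new_path, net = net)
  ord <- order(vapply(paths, `[[`, 0, "W_raw"),
               vapply(paths, function(p) paste(sprintf("%06d", p$nodes),
                                               collapse = ","), ""))
  paths <- paths[ord]

  bet <- ensemble_edge_counts(paths)
  structure(list(paths = paths, optimal = paths[[1L]],
                 degeneracy = length(paths), offset = offset,
                 betweenness = bet, source = s, sink = t),
            class = "path_ensemble")
}

ensemble_edge_counts <- function(paths) {
  if (length(paths) == 0L) return(NULL)
  ee <- do.call(rbind, lapply(paths, function(p) {
    cbind(pmin(p$nodes[-length(p$nodes)], p$nodes[-1L]),
          pmax(p$nodes[-length(p$nodes)], p$nodes[-1L]))
  }))
  key <- paste(ee[, 1], ee[, 2], sep = "-")
  tb <- table(key)
  ij <- do.call(rbind, strsplit(names(tb), "-", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    count = as.integer(tb))
  out$in_all <- out$count == length(paths)
  out[order(-out$count, out$i, out$j), , drop = FALSE]
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat("path_ensemble:", x$degeneracy, "path(s) within offset", x$offset,
      "of W_opt =", if (x$degeneracy) round(x$optimal$W, 1) else Inf, "\n")
  invisible(x)
}

#' Path statistics (N, W, min)
#'
#' N is the hop count (number of edges), W the overall weight
#' \eqn{100 \sum_k -\ln|c_{ij}^k|} over consecutive pairs, and min the
#' minimum pairwise correlation magnitude along the path.  W is
#' conventionally printed rounded to an integer; full precision is kept
#' here.
#'
#' @param path a \code{comm_path} or an integer/label node sequence.
#' @param net the network the path lives in; every consecutive pair must be
#'   an edge.
#' @return list with \code{N}, \code{W}, \code{min_corr}.
#' @export
path_statistics <- function(path, net) {
  nodes <- if (inherits(path, "comm_path")) path$nodes
           else vapply(path, resolve_node, 0L, net = net)
  if (length(nodes) < 2L) stop("a path needs at least 2 nodes")
  w <- net$W[cbind(nodes[-length(nodes)], nodes[-1L])]
  if (any(!is.finite(w))) {
    k <- which(!is.finite(w))[1]
    stop("missing edge in network: ", net$labels[nodes[k]], " - ",
         net$labels[nodes[k + 1L]])
  }
  p <- new_path(nodes, net)
  list(N = p$N, W = p$W, min_corr = p$min_corr)
}

#' Classify a path as an effective communication route
#'
#' A path is effective when its minimum pairwise correlation is at least
#' \code{threshold} (default 0.7): a route with even one poorly coupled
#' link is unlikely to communicate regardless of its overall weight.
#'
#' @param path a \code{comm_path}.
#' @param threshold minimum correlation required.
#' @return list with \code{effective}, \code{min_corr}, \code{threshold}
#'   and \code{limiting_edge} (labels and correlation of the weakest link).
#' @export
classify_effective <- function(path, threshold = 0.7) {
  if (!inherits(path, "comm_path")) stop("'path' must be a comm_path")
  if (!path$reachable)
    return(list(effective = FALSE, min_corr = NA_real_,
                threshold = threshold, limiting_edge = NULL))
  k <- which.min(abs(path$edge_cor))
  list(effective = path$min_corr >= threshold,
       min_corr = path$min_corr, threshold = threshold,
       limiting_edge = list(labels = path$labels[c(k, k + 1L)],
                            cor = path$edge_cor[k]))
}

#' Candidate anchor nodes within a radius of a site
#'
#' Returns the nodes any of whose member heavy atoms lie within
#' \code{radius} of any site atom on the reference frame (the conventional
#' 10 A shell around a functional site such as a mismatch, a bound
#' nucleotide or a DNA contact region).
#'
#' @param node_model the topology.
#' @param ref_xyz reference-frame coordinates: a length 3*atoms vector or
#'   one row of a trajectory.
#' @param site site definition: atom indices into the topology, or an
#'   m x 3 coordinate matrix.
#' @param radius shell radius in Angstrom.
#' @return integer vector of node indices (1-based); empty shells are an
#'   error (anchoring impossible).
#' @export
candidate_nodes_near_site <- function(node_model, ref_xyz, site, radius = 10) {
  stopifnot_node_model(node_model)
  ref_xyz <- as.numeric(ref_xyz)
  site_xyz <- if (is.matrix(site) && ncol(site) == 3L) site
              else frame_coords(ref_xyz, as.integer(site))
  if (nrow(site_xyz) == 0L) stop("site atom set is empty")
  hits <- which(vapply(node_model$members, function(mem) {
    mc <- frame_coords(ref_xyz, mem)
    d2 <- outer(rowSums(mc^2), rowSums(site_xyz^2), "+") -
      2 * mc %*% t(site_xyz)
    sqrt(max(min(d2), 0)) <= radius
  }, logical(1)))
  if (length(hits) == 0L)
    stop("no node within ", radius, " A of the site: anchoring impossible")
  hits
}

#' Select the anchor pair with the shortest optimal path
#'
#' Over all pairs from two candidate sets, returns the pair minimising the
#' optimal path length (the representative-residue rule); ties break to the
#' lowest node-id pair.
#'
#' @param net a \code{dynamic_network}.
#' @param setA,setB non-empty candidate node sets (indices or labels).
#' @param apsp optional precomputed distance table.
#' @return list with \code{source}, \code{sink}, \code{distance} (raw
#'   scale) and the optimal \code{path}; if every pair is disconnected,
#'   \code{path$reachable} is FALSE.
#' @export
select_anchor_pair <- function(net, setA, setB, apsp = NULL) {
  if (length(setA) == 0L || length(setB) == 0L)
    stop("candidate sets must be non-empty")
  a <- vapply(setA, resolve_node, 0L, net = net)
  b <- vapply(setB, resolve_node, 0L, net = net)
  if (is.null(apsp)) apsp <- all_pairs_optimal(net)
  Dab <- apsp$D[a, b, drop = FALSE]
  if (!any(is.finite(Dab)))
    return(list(source = NA_integer_, sink = NA_integer_, distance = Inf,
                path = no_path(NA_integer_, NA_integer_)))
  best <- Inf; bi <- NA_integer_; bj <- NA_integer_
  for (i in order(a)) for (j in order(b)) {
    if (a[i] == b[j] || !is.finite(Dab[i, j])) next
    if (!is.finite(best) || Dab[i, j] < best - PATH_TOL * (1 + best)) {
      best <- Dab[i, j]; bi <- a[i]; bj <- b[j]
    }
  }
  list(source = bi, sink = bj, distance = best,
       path = optimal_path(net, bi, bj, apsp = apsp))
}

#' Ranked edge betweenness of a path ensemble
#'
#' Counts how many ensemble paths traverse each edge; edges present in all
#' (or most) paths are the communication bottlenecks.
#'
#' @param ensemble a \code{path_ensemble}.
#' @return data frame with i, j, count and \code{in_all}, ranked by count.
#' @export
path_ensemble_betweenness <- function(ensemble) {
  if (!inherits(ensemble, "path_ensemble"))
    stop("'ensemble' must be a path_ensemble")
  if (ensemble$degeneracy == 0L) stop("empty path ensemble")
  ensemble$betweenness
}
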