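# Girvan-Newman community detection on the dynamic network and critical
# inter-community edges.

#' Girvan-Newman community partition of a dynamic network
#'
#' Iteratively removes the edge with the highest edge betweenness
#' (recomputed after every removal; shortest paths use the network's
#' \eqn{-\ln|C|} distance weights) and returns the partition along the
#' resulting dendrogram that maximises weighted modularity.  Modularity is
#' evaluated on the original graph with \eqn{|C_{ij}|} as the affinity
#' weight (a distance is not an affinity).  Ties in betweenness break to
#' the lexicographically smallest edge, so the result is deterministic.
#' An edgeless graph yields one community per node with modularity 0.
#'
#' @param net a \code{dynamic_network}.
#' @return Object of class \code{community_partition}: list with
#'   \code{membership} (community id per node, numbered by first
#'   occurrence), \code{n_communities}, \code{modularity},
#'   \code{removed_edges} (removal order up to the selected partition and
#'   beyond) and method notes.
#' @export
girvan_newman <- function(net) {
  if (!inherits(net, "dynamic_network")) stop("'net' must be a dynamic_network")
  n <- net$n
  e <- net$edges
  if (nrow(e) == 0L)
    return(structure(list(membership = seq_len(n), n_communities = n,
                          modularity = 0, removed_edges = NULL,
                          method = "girvan-newman"),
                     class = "community_partition"))

  g0 <- igraph::make_empty_graph(n, directed = FALSE)
  g0 <- igraph::add_edges(g0, rbind(e$i, e$j))
  igraph::E(g0)$weight <- pmax(e$weight, 1e-12)
  igraph::E(g0)$affinity <- e$abs_cor

  canon <- function(mem) match(mem, unique(mem))
  score <- function(mem)
    igraph::modularity(g0, mem, weights = igraph::E(g0)$affinity)

  g <- g0
  best_mem <- canon(igraph::components(g)$membership)
  best_q <- score(best_mem)
  removed <- NULL
  repeat {
    m <- igraph::ecount(g)
    if (m == 0L) break
    bt <- igraph::edge_betweenness(g, directed = FALSE,
                                   weights = igraph::E(g)$weight)
    top <- which(bt >= max(bt) - 1e-10 * (1 + abs(max(bt))))
    ends <- igraph::ends(g, igraph::E(g)[top], names = FALSE)
    ends <- cbind(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    pick <- top[order(ends[, 1], ends[, 2])[1L]]
    rm_ends <- sort(igraph::ends(g, igraph::E(g)[pick], names = FALSE)[1, ])
    removed <- rbind(removed, rm_ends)
    g <- igraph::delete_edges(g, igraph::E(g)[pick])
    mem <- canon(igraph::components(g)$membership)
    q <- score(mem)
    if (q > best_q + 1e-12) { best_q <- q; best_mem <- mem }
  }
  structure(list(membership = best_mem,
                 n_communities = max(best_mem),
                 modularity = best_q,
                 removed_edges = data.frame(i = removed[, 1], j = removed[, 2],
                                            row.names = NULL),
                 method = "girvan-newman (betweenness on -ln|C| distances, modularity on |C|)"),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities, modularity",
      round(x$modularity, 4), "\n")
  invisible(x)
}

#' Critical inter-community edges
#'
#' Edges whose endpoints lie in different communities, ranked by how many
#' ensemble paths traverse them: the communication bottlenecks between
#' communities.  Without ensembles the ranking falls back to ascending
#' edge weight (strongest coupling first).
#'
#' @param partition a \code{community_partition}.
#' @param net the \code{dynamic_network} the partition belongs to.
#' @param ensembles a \code{path_ensemble} or list of them (optional).
#' @return data frame: i, j, labels, communities, cor, weight,
#'   \code{path_count}; ranked by path count (desc) then weight (asc).
#'   Empty for a single-community partition.
#' @export
critical_intercommunity_edges <- function(partition, net, ensembles = NULL) {
  if (!inherits(partition, "community_partition"))
    stop("'partition' must be a community_partition")
  mem <- partition$membership
  if (length(mem) != net$n)
    stop("partition and network have different node counts")
  e <- net$edges
  cross <- mem[e$i] != mem[e$j]
  out <- data.frame(i = e$i[cross], j = e$j[cross],
                    label_i = e$label_i[cross], label_j = e$label_j[cross],
                    community_i = mem[e$i[cross]], community_j = mem[e$j[cross]],
                    cor = e$cor[cross], weight = e$weight[cross],
                    path_count = rep(0L, sum(cross)), stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  if (!is.null(ensembles)) {
    if (inherits(ensembles, "path_ensemble")) ensembles <- list(ensembles)
    for (ens in ensembles) {
      b <- ens$betweenness
      if (is.null(b)) next
      key_out <- paste(out$i, out$j)
      key_b <- paste(b$i, b$j)
      hit <- match(key_out, key_b)
      add <- ifelse(is.na(hit), 0L, b$count[hit])
      out$path_count <- out$path_count + add
    }
  }
  out[order(-out$path_count, out$weight, out$i, out$j), , drop = FALSE]
}

#' Write community assignments as TSV (label, community id)
#' @param partition a \code{community_partition}.
#' @param net the network (for labels).
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_communities <- function(partition, net, file) {
  utils::write.table(
    data.frame(node = seq_len(net$n), label = net$labels,
               community = partition$membership),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
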