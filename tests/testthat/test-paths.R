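# Optimal / suboptimal path machinery against closed forms and brute force.

chain_net <- function(weights) {
  # path graph with prescribed edge weights (cor = exp(-w))
  n <- length(weights) + 1L
  C <- diag(n); contact <- matrix(FALSE, n, n)
  for (k in seq_along(weights)) {
    C[k, k + 1L] <- C[k + 1L, k] <- exp(-weights[k])
    contact[k, k + 1L] <- contact[k + 1L, k] <- TRUE
  }
  make_net(C, contact)
}

test_that("single edge and forced chain give closed-form statistics", {
  net <- chain_net(0.25)
  ap <- all_pairs_optimal(net)
  expect_equal(ap$D[1, 2], 0.25, tolerance = 1e-12)
  p <- optimal_path(net, 1, 2, apsp = ap)
  expect_equal(p$nodes, 1:2)

  net3 <- chain_net(c(0.1, 0.2))
  p3 <- optimal_path(net3, 1, 3)
  expect_equal(p3$nodes, 1:3)
  expect_equal(p3$N, 2L)
  expect_equal(p3$W, 30, tolerance = 1e-9)          # x100 scale
  expect_equal(p3$min_corr, exp(-0.2), tolerance = 1e-12)
})

test_that("a heavier shortcut loses to the two-step route", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- exp(-0.1)
  C[2, 3] <- C[3, 2] <- exp(-0.1)
  C[1, 3] <- C[3, 1] <- exp(-0.5)       # direct but weak
  contact <- matrix(TRUE, 3, 3); diag(contact) <- FALSE
  net <- make_net(C, contact)
  p <- optimal_path(net, 1, 3)
  expect_equal(p$nodes, c(1, 2, 3))
  # brute-force oracle agrees
  bf <- brute_paths(net, 1, 3)
  expect_equal(min(bf$lengths), p$W_raw, tolerance = 1e-12)
})

test_that("Floyd-Warshall equals single-source relaxation on random graphs", {
  for (seed in 1:100) {
    net <- rand_net(10, 0.4, seed = seed)
    D <- all_pairs_optimal(net)$D
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.finite(net$W), net$W, 0), mode = "undirected",
      weighted = TRUE, diag = FALSE)
    Dref <- igraph::distances(g, algorithm = "dijkstra")
    expect_equal(unname(D), unname(Dref), tolerance = 1e-10)
  }
})

test_that("distances and bounded ensembles match exhaustive enumeration", {
  for (seed in 1:60) {
    n <- 5 + seed %% 5
    net <- rand_net(n, 0.35, seed = 1000 + seed)
    s <- 1L; t <- n
    bf <- brute_paths(net, s, t)
    ap <- all_pairs_optimal(net)
    if (length(bf$lengths) == 0L) {
      expect_false(is.finite(ap$D[s, t]))
      expect_false(optimal_path(net, s, t, apsp = ap)$reachable)
      next
    }
    expect_equal(ap$D[s, t], min(bf$lengths), tolerance = 1e-10)
    ens <- suboptimal_paths(net, s, t, offset = 20, apsp = ap)
    keep <- bf$lengths <= min(bf$lengths) + 0.2 + 1e-9
    expect_setequal(vapply(ens$paths, function(p) path_key(p$nodes), ""),
                    vapply(bf$paths[keep], path_key, ""))
    # optimal is in the ensemble; every member within the offset
    expect_true(path_key(ens$optimal$nodes) %in%
                  vapply(ens$paths, function(p) path_key(p$nodes), ""))
    expect_true(all(vapply(ens$paths, `[[`, 0, "W_raw") <=
                      ens$optimal$W_raw + 0.2 + 1e-9))
    # betweenness counts sum to the total hop count of the ensemble
    expect_equal(sum(ens$betweenness$count),
                 sum(vapply(ens$paths, `[[`, 0L, "N")))
  }
})

test_that("offset 0 returns exactly the tied minimum-weight paths", {
  # diamond: two equal-length routes 1-2-4 and 1-3-4
  C <- diag(4)
  w <- exp(-0.3)
  C[1, 2] <- C[2, 1] <- w; C[2, 4] <- C[4, 2] <- w
  C[1, 3] <- C[3, 1] <- w; C[3, 4] <- C[4, 3] <- w
  contact <- abs(C - diag(4)) > 0
  net <- make_net(C, contact)
  ens <- suboptimal_paths(net, 1, 4, offset = 0)
  expect_equal(ens$degeneracy, 2L)
  expect_setequal(vapply(ens$paths, function(p) path_key(p$nodes), ""),
                  c("1,2,4", "1,3,4"))
  # deterministic lexicographic tie-break for the optimal representative
  expect_equal(ens$optimal$nodes, c(1, 2, 4))
  expect_equal(optimal_path(net, 1, 4)$nodes, c(1, 2, 4))
})

test_that("hourglass bottleneck edge is traversed by every path", {
  # two routes into node 3, shared edge 3-4, two routes out of 4
  C <- diag(6); contact <- matrix(FALSE, 6, 6)
  add <- function(i, j, w) {
    C[i, j] <<- C[j, i] <<- exp(-w)
    contact[i, j] <<- contact[j, i] <<- TRUE
  }
  add(1, 2, 0.1); add(1, 3, 0.2); add(2, 3, 0.1)
  add(3, 4, 0.1)
  add(4, 5, 0.1); add(4, 6, 0.2); add(5, 6, 0.1)
  net <- make_net(C, contact)
  ens <- suboptimal_paths(net, 1, 6, offset = 15)
  expect_gt(ens$degeneracy, 1L)
  b <- path_ensemble_betweenness(ens)
  mid <- b[b$i == 3 & b$j == 4, ]
  expect_equal(mid$count, ens$degeneracy)
  expect_true(mid$in_all)
  # edge-disjoint two-path case: all counts 1
  ens0 <- suboptimal_paths(chain_net(c(0.1, 0.2)), 1, 3, offset = 0)
  expect_true(all(path_ensemble_betweenness(ens0)$count == 1L))
})

test_that("path statistics and effectiveness classification", {
  net <- chain_net(c(-log(0.9), -log(0.8)))
  st <- path_statistics(c(1, 2, 3), net)
  expect_equal(st$N, 2L)
  expect_equal(st$W, 100 * (-log(0.9) - log(0.8)), tolerance = 1e-9)
  expect_equal(st$min_corr, 0.8, tolerance = 1e-12)

  one <- chain_net(0)                      # single edge, |c| = 1
  s1 <- path_statistics(c(1, 2), one)
  expect_equal(unlist(s1), c(N = 1, W = 0, min_corr = 1))

  expect_error(path_statistics(c(1, 3), net), "missing edge")

  p <- optimal_path(net, 1, 3)
  expect_true(classify_effective(p, 0.7)$effective)          # min 0.8
  expect_false(classify_effective(p, 0.81)$effective)
  lim <- classify_effective(p)$limiting_edge
  expect_equal(abs(lim$cor), 0.8, tolerance = 1e-12)

  # boundary: "at least 0.7" admits exactly 0.7; just below fails
  mk <- function(mc) structure(list(reachable = TRUE, min_corr = mc,
                                    edge_cor = c(0.9, mc),
                                    labels = c("a", "b", "c"), N = 2L),
                               class = "comm_path")
  expect_true(classify_effective(mk(0.73))$effective)
  expect_true(classify_effective(mk(0.7))$effective)
  expect_false(classify_effective(mk(0.52))$effective)
})

test_that("disconnected pairs give explicit no-path results", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[3, 4] <- C[4, 3] <- 0.9
  contact <- abs(C - diag(4)) > 0
  net <- make_net(C, contact)
  p <- optimal_path(net, 1, 4)
  expect_false(p$reachable)
  ens <- suboptimal_paths(net, 1, 4, offset = 10)
  expect_equal(ens$degeneracy, 0L)
})

test_that("anchor shells and anchor-pair selection", {
  m <- synthetic_model()
  nm <- m$geometry$node_model
  ref <- as.vector(t(m$geometry$coords))
  # a site on node 1's atom includes node 1
  expect_true(1L %in% candidate_nodes_near_site(nm, ref, site = 1L, radius = 1))
  # exhaustive check of a 10 A shell around the source apex
  shell <- candidate_nodes_near_site(nm, ref, site = 1L, radius = 10)
  d <- sqrt(colSums((t(m$geometry$coords) - m$geometry$coords[1, ])^2))
  expect_setequal(shell, which(d <= 10))
  # a site far from every node yields an empty shell
  expect_error(candidate_nodes_near_site(nm, ref,
                                         site = matrix(c(500, 500, 500), 1),
                                         radius = 10),
               "anchoring impossible")

  # singleton sets force the pair
  net <- chain_net(c(0.2, 0.3))
  sel <- select_anchor_pair(net, 1, 3)
  expect_equal(c(sel$source, sel$sink), c(1L, 3L))
  expect_equal(sel$distance, 0.5, tolerance = 1e-12)

  # random graphs: selection matches brute force over all pairs
  for (seed in 1:20) {
    net <- rand_net(8, 0.45, seed = 2000 + seed)
    ap <- all_pairs_optimal(net)
    A <- c(1L, 2L, 3L); B <- c(6L, 7L, 8L)
    sel <- select_anchor_pair(net, A, B, apsp = ap)
    grid <- expand.grid(a = A, b = B)
    dd <- ap$D[cbind(grid$a, grid$b)]
    if (!any(is.finite(dd))) {
      expect_false(sel$path$reachable)
    } else {
      expect_equal(sel$distance, min(dd), tolerance = 1e-10)
      # deterministic tie-break: lowest node-id pair among minima
      minima <- grid[dd <= min(dd) + 1e-12, ]
      minima <- minima[order(minima$a, minima$b), ]
      expect_equal(c(sel$source, sel$sink),
                   c(minima$a[1], minima$b[1]), ignore_attr = TRUE)
    }
  }
})

test_that("ensemble size cap triggers a helpful error", {
  net <- rand_net(9, 0.8, seed = 99)
  expect_error(suboptimal_paths(net, 1, 9, offset = 200, cap = 5),
               "smaller offset")
})
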