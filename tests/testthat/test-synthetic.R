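# Synthetic correlated-motion generator: geometry, covariance, sampling,
# ground truth.

test_that("geometry realises exactly the declared contact graph", {
  geo <- make_geometry(
    chains = list(list(chain = "A", n = 10), list(chain = "B", n = 10)),
    bridges = list(c("A", "B")))
  expect_equal(nrow(geo$node_model$nodes), 20L)
  # exhaustive pairwise oracle: pairs below cutoff = sequence-adjacent + bridge
  d <- as.matrix(dist(geo$coords))
  close <- which(d < 4.5 & upper.tri(d), arr.ind = TRUE)
  expected <- rbind(cbind(1:9, 2:10), cbind(11:19, 12:20), c(10, 11))
  expect_equal(close[order(close[, 1], close[, 2]), , drop = FALSE],
               expected[order(expected[, 1], expected[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
  # and nothing else sneaks inside the 6 A clearance
  far <- d[upper.tri(d)][!(d[upper.tri(d)] < 4.5)]
  expect_true(all(far > 6))
})

test_that("degenerate geometries: 2-node chain, empty spec, bad spacing", {
  geo <- make_geometry(chains = list(list(chain = "A", n = 2)))
  expect_equal(nrow(geo$contacts), 1L)
  expect_equal(geo$contacts$distance, 3.8)

  expect_error(make_geometry(chains = list()), "empty")
  # spacing that pushes sequence neighbours past the cutoff is rejected
  expect_error(make_geometry(chains = list(list(chain = "A", n = 3)),
                             spacing = 5),
               "rejected")
  # spacing that pulls undeclared pairs inside the clearance is rejected
  expect_error(make_geometry(chains = list(list(chain = "A", n = 3)),
                             spacing = 2),
               "rejected")
})

test_that("covariance construction is PSD with correct closed-form cases", {
  # two blocks, no path: eigendecomposition oracle
  cv <- make_covariance(10, blocks = list(1:5, 6:10), rho_block = 0.6,
                        rho_bg = 0.05)
  ev <- eigen(cv$C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)

  # equicorrelation spectrum: one all-node block, rho_bg = 0
  cv2 <- make_covariance(8, blocks = list(1:8), rho_block = 0.5, rho_bg = 0)
  ev2 <- eigen(cv2$C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev2), 0.5, tolerance = 1e-12)
  expect_equal(max(ev2), 1 + 7 * 0.5, tolerance = 1e-12)

  # perfectly correlated 2-node path
  cv3 <- make_covariance(2, planted_path = 1:2, rho_path = 1,
                         path_var_frac = 1)
  expect_equal(cv3$C[1, 2], 1)

  expect_error(make_covariance(4, rho_bg = 0.7, rho_block = 0.6), "rho_bg")
})

test_that("PSD holds across random block/path layouts", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:15, 1)
    k <- sample(1:3, 1)
    blocks <- split(seq_len(n), sort(rep_len(seq_len(k), n)))
    path <- sample(n, min(n, sample(2:5, 1)))
    cv <- make_covariance(n, blocks = blocks, planted_path = path)
    ev <- eigen(cv$C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("sampled displacement correlation converges to the planted value", {
  cv <- make_covariance(2, blocks = list(1:2), rho_block = 0.8, rho_bg = 0.1)
  m <- cov_model(cv)
  n <- 50000
  traj <- sample_trajectory(m, n, seed = 11)
  rho_hat <- direct_pair_cor(traj$xyz, 1, 2)
  expect_lt(abs(rho_hat - 0.8), 3 * (1 - 0.8^2) / sqrt(n))

  # perfectly correlated pair
  cv1 <- make_covariance(2, planted_path = 1:2, rho_path = 1, path_var_frac = 1)
  t1 <- sample_trajectory(cov_model(cv1), 1000, seed = 3)
  expect_equal(direct_pair_cor(t1$xyz, 1, 2), 1, tolerance = 1e-12)
})

test_that("20-node block model: max DCCM error small at 50k frames", {
  cv <- make_covariance(20, blocks = list(1:10, 11:20))
  m <- cov_model(cv)
  traj <- sample_trajectory(m, 50000, seed = 7)
  nm <- make_geometry(chains = list(list(chain = "A", n = 20)),
                      spacing = 3.8)$node_model
  C_hat <- compute_dccm(traj, nm)
  expect_lt(max(abs(unclass(C_hat) - cv$C)), 0.05)
})

test_that("sampling is deterministic given the seed and errors without one", {
  m <- synthetic_model()
  t1 <- sample_trajectory(m, 50, seed = 5)
  t2 <- sample_trajectory(m, 50, seed = 5)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- sample_trajectory(m, 50, seed = 6)
  expect_false(identical(t1$xyz, t3$xyz))
  expect_error(sample_trajectory(m, 50), "seed")
  expect_error(sample_trajectory(m, 1, seed = 1), "at least 2")
})

test_that("ground truth exposes exact expected weights and a unique planted optimum", {
  m <- synthetic_model()
  gt <- ground_truth(m)
  # interior planted edges hit rho_path exactly: expected weight -ln(0.9)
  expect_equal(gt$path_edges$expected_weight[1], -log(0.9), tolerance = 1e-12)
  expect_equal(gt$path_edges$cor[c(1, 2, 4, 5)], rep(0.9, 4), tolerance = 1e-12)
  # the bridge saturates below rho_path but stays above the effectiveness bar
  expect_gte(gt$min_corr, 0.7)
  expect_gte(gt$min_corr - m$covariance$params$rho_block, 0.2)

  # perfect-correlation edge has zero expected weight
  cv1 <- make_covariance(2, planted_path = 1:2, rho_path = 1, path_var_frac = 1)
  m1 <- cov_model(cv1); m1$planted_path <- 1:2; m1$planted_partition <- c(1L, 1L)
  m1$geometry$contacts <- data.frame(i = 1, j = 2, sequence_adjacent = FALSE)
  expect_equal(ground_truth(m1)$path_edges$expected_weight, 0)

  # brute-force oracle on the expected-weight graph: planted path is the
  # unique minimum-weight route between the anchors
  ct <- gt$contacts
  contact <- matrix(FALSE, 10, 10)
  contact[cbind(ct$i, ct$j)] <- TRUE; contact <- contact | t(contact)
  net <- make_net(m$covariance$C, contact)
  bf <- brute_paths(net, m$source, m$sink)
  best <- which(bf$lengths <= min(bf$lengths) + 1e-12)
  expect_length(best, 1L)
  expect_equal(bf$paths[[best]], m$planted_path)
})

test_that("synthetic system round-trips through PDB within format precision", {
  m <- synthetic_model()
  traj <- sample_trajectory(m, 4, seed = 2)
  pre <- file.path(tempdir(), "systest")
  files <- write_synthetic_system(m, pre, trajectory = traj, seed = 2)
  nm <- load_topology(paste0(pre, "_topology.pdb"))
  expect_equal(nrow(nm$nodes), 10L)
  t2 <- load_trajectory(paste0(pre, "_traj.pdb"), nm)
  expect_lt(max(abs(t2$xyz - traj$xyz)), 1e-3)   # PDB stores 3 decimals
  truth <- jsonlite::read_json(paste0(pre, "_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$planted_path, m$planted_path)
  unlink(files)
})
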