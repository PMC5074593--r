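# End-to-end pipeline driver and tabular report rendering.

#' Run the full dynamical-network pipeline on a synthetic model
#'
#' Samples a trajectory, computes the DCCM, the persistent-contact map and
#' the weighted network, extracts the optimal and suboptimal paths between
#' the model's anchors, partitions the network into communities and ranks
#' critical inter-community edges.  Every stochastic step derives from
#' \code{seed}, so a rerun with the same configuration is bit-identical.
#'
#' @param model a \code{synthetic_model}.
#' @param n_frames frames to sample.
#' @param seed integer seed.
#' @param offset suboptimal path offset on the x100 weight scale.
#' @param effective_threshold minimum path correlation for the effective
#'   flag.
#' @param cutoff,contact_fraction contact criterion parameters.
#' @param state label used in the report table.
#' @param out_dir if non-NULL, reports are written there (see
#'   \code{\link{render_reports}}).
#' @return list with all intermediate objects (\code{traj}, \code{dccm},
#'   \code{contacts}, \code{network}, \code{apsp}, \code{optimal},
#'   \code{ensemble}, \code{partition}, \code{critical_edges}), the
#'   one-row \code{report} data frame and the \code{config} echo.
#' @export
run_pipeline <- function(model, n_frames, seed, offset = 10,
                         effective_threshold = 0.7,
                         cutoff = 4.5, contact_fraction = 0.75,
                         state = "synthetic", out_dir = NULL) {
  nm <- model$geometry$node_model
  traj <- sample_trajectory(model, n_frames, seed)
  dccm <- compute_dccm(traj, nm)
  contacts <- compute_contacts(traj, nm, cutoff = cutoff,
                               fraction = contact_fraction)
  net <- build_network(contacts, dccm)
  apsp <- all_pairs_optimal(net)
  opt <- optimal_path(net, model$source, model$sink, apsp = apsp)
  ens <- suboptimal_paths(net, model$source, model$sink, offset, apsp = apsp)
  part <- girvan_newman(net)
  crit <- critical_intercommunity_edges(part, net, ens)
  eff <- classify_effective(opt, effective_threshold)

  report <- data.frame(
    state = state,
    pair = paste(net$labels[model$source], net$labels[model$sink], sep = "-"),
    path_class = 1L,
    N = opt$N, W = round(opt$W), min_corr = opt$min_corr,
    effective = eff$effective,
    degeneracy = ens$degeneracy,
    nodes = paste(opt$labels, collapse = ","),
    stringsAsFactors = FALSE)

  config <- list(n_frames = n_frames, seed = as.integer(seed),
                 offset = offset, effective_threshold = effective_threshold,
                 cutoff = cutoff, contact_fraction = contact_fraction,
                 covariance = model$covariance$params,
                 amplitude = model$amplitude,
                 frame_interval_ps = model$frame_interval_ps,
                 superposition = "fit-to-iterated-mean, representative atoms",
                 log_base = "natural")

  res <- list(traj = traj, dccm = dccm, contacts = contacts, network = net,
              apsp = apsp, optimal = opt, ensemble = ens, partition = part,
              critical_edges = crit, report = report, config = config)
  if (!is.null(out_dir)) render_reports(res, out_dir)
  res
}

#' Render pipeline results as table files plus a run manifest
#'
#' Writes \code{paths.tsv} (one row per state/path class: N,
#' integer-rounded W, min correlation, effective flag, node list),
#' \code{communities.tsv}, \code{intercommunity_edges.tsv},
#' \code{edges.tsv} and \code{manifest.json} (every parameter and seed of
#' the run; no timestamps, so identical runs produce byte-identical
#' output).
#'
#' @param results result list from \code{\link{run_pipeline}}, or any list
#'   with \code{report}, \code{network}, \code{partition},
#'   \code{critical_edges} and \code{config}.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
render_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rp <- results$report
  rp$min_corr <- sprintf("%.2f", rp$min_corr)
  f <- file.path(dir, "paths.tsv")
  utils::write.table(rp, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(results$network)) {
    f <- file.path(dir, "edges.tsv")
    write_edge_list(results$network, f); files <- c(files, f)
    if (!is.null(results$partition)) {
      f <- file.path(dir, "communities.tsv")
      write_communities(results$partition, results$network, f)
      files <- c(files, f)
    }
  }
  if (!is.null(results$critical_edges)) {
    f <- file.path(dir, "intercommunity_edges.tsv")
    ce <- results$critical_edges
    ce$cor <- sprintf("%.6f", ce$cor); ce$weight <- sprintf("%.6f", ce$weight)
    utils::write.table(ce, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$config, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
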