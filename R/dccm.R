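# Dynamic cross-correlation matrices of node displacements and their
# convergence over growing trajectory windows.

#' Compute the dynamic cross-correlation matrix (DCCM)
#'
#' For every node pair the normalised covariance of displacement vectors
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   (\langle \Delta r_i^2 \rangle^{1/2} \langle \Delta r_j^2 \rangle^{1/2})}
#' where \eqn{\Delta r_i} is the representative-atom position minus its
#' time average over the analysed window.  All frames are used; the
#' trajectory should be superposed first so displacements exclude
#' rigid-body motion.
#'
#' @param traj a superposed \code{traj_ensemble} with at least 2 frames.
#' @param node_model the topology.
#' @return Object of class \code{dccm_matrix}: the n x n correlation matrix
#'   with node labels as dimnames and attributes \code{frames_used} and
#'   \code{window_label}.  Nodes with zero displacement variance get NA
#'   rows/columns and a warning (using such a node in a network is an
#'   error).
#' @export
compute_dccm <- function(traj, node_model) {
  stopifnot_trajectory(traj); stopifnot_node_model(node_model)
  if (nrow(traj$xyz) < 2L) stop("need at least 2 frames to compute a DCCM")
  if (!isTRUE(traj$superposed))
    warning("trajectory is not superposed; DCCM will mix internal and rigid-body motion")
  dccm_core(traj$xyz, node_model$nodes$repr_atom, node_model$nodes$label,
            window_label = sprintf("frames 1-%d", nrow(traj$xyz)))
}

dccm_core <- function(xyz, repr, labels, window_label = "") {
  f <- nrow(xyz)
  n <- length(repr)
  num <- matrix(0, n, n)
  for (ax in 1:3) {
    X <- xyz[, 3L * repr - (3L - ax), drop = FALSE]
    X <- X - rep(colMeans(X), each = f)
    num <- num + crossprod(X)
  }
  num <- num / f
  msf <- diag(num)
  zero <- msf <= .Machine$double.eps * 100
  if (any(zero)) {
    warning("node(s) with zero displacement variance: ",
            paste(labels[zero], collapse = ", "),
            "; their correlations are undefined (NA)")
    msf[zero] <- NA_real_
  }
  C <- num / sqrt(outer(msf, msf))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- ifelse(zero, NA_real_, 1)
  dimnames(C) <- list(labels, labels)
  structure(C, class = c("dccm_matrix", "matrix"),
            frames_used = f, window_label = window_label)
}

#' DCCM convergence over cumulative trajectory windows
#'
#' Computes DCCMs on cumulative prefixes of the trajectory (by default the
#' first 1/4, 1/2, 3/4 and all frames) and reports, for each pair of
#' consecutive windows, (a) the RMS difference of matrix elements and (b)
#' the Pearson correlation of off-diagonal elements.  A stationary,
#' well-sampled trajectory shows differences shrinking towards the later
#' windows.
#'
#' @param traj a superposed \code{traj_ensemble} with at least 8 frames.
#' @param node_model the topology.
#' @param window_fractions increasing fractions of the trajectory to use.
#' @return list with \code{dccms} (one \code{dccm_matrix} per usable
#'   window), \code{similarity} (data frame comparing consecutive windows)
#'   and \code{frames} (frames per window).  Windows with fewer than 2
#'   frames are skipped with a warning.
#' @export
dccm_convergence <- function(traj, node_model,
                             window_fractions = c(0.25, 0.5, 0.75, 1)) {
  stopifnot_trajectory(traj); stopifnot_node_model(node_model)
  f <- nrow(traj$xyz)
  if (f < 8L) stop("need at least 8 frames for a convergence analysis")
  nf <- floor(window_fractions * f)
  usable <- nf >= 2L
  if (any(!usable))
    warning("window(s) with fewer than 2 frames skipped: fraction ",
            paste(window_fractions[!usable], collapse = ", "))
  nf <- nf[usable]
  labs <- sprintf("frames 1-%d", nf)
  dccms <- lapply(seq_along(nf), function(k)
    dccm_core(traj$xyz[seq_len(nf[k]), , drop = FALSE],
              node_model$nodes$repr_atom, node_model$nodes$label,
              window_label = labs[k]))
  names(dccms) <- labs

  sim <- NULL
  if (length(dccms) >= 2L) {
    up <- upper.tri(dccms[[1]])
    sim <- do.call(rbind, lapply(seq_len(length(dccms) - 1L), function(k) {
      a <- unclass(dccms[[k]]); b <- unclass(dccms[[k + 1L]])
      data.frame(window_a = labs[k], window_b = labs[k + 1L],
                 rms_diff = sqrt(mean((a - b)^2, na.rm = TRUE)),
                 pearson_offdiag = stats::cor(a[up], b[up],
                                              use = "complete.obs"))
    }))
  }
  list(dccms = dccms, similarity = sim, frames = nf)
}

#' Write a DCCM as a dense TSV matrix
#' @param dccm a \code{dccm_matrix}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_dccm <- function(dccm, file) {
  m <- as.data.frame(unclass(dccm))
  utils::write.table(cbind(node = rownames(m), round(m, 6)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Heatmap of a DCCM
#' @param x a \code{dccm_matrix}.
#' @param ... passed to \code{image}.
#' @export
plot.dccm_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  zlim = c(-1, 1), xlab = "node", ylab = "node",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  main = attr(x, "window_label"), ...)
  invisible(x)
}
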