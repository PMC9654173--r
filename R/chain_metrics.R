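#' Per-chain brush characterizations
#'
#' Three scalar characterizations per grafted chain over a snapshot
#' window: topography height from the marker carbons, root-mean-square
#' fluctuation of the side-group atoms, and the hydration-shell water
#' count around the ester/sulfonate oxygens.
#'
#' @name chain_metrics
NULL

chain_marker_rows <- function(topology, chain_id) {
  idx <- vapply(MARKER_ROLES, function(r) {
    i <- role_idx(topology, r, chain_id = chain_id)
    if (length(i) != 1L)
      stop(sprintf("chain %s: missing marker role %s", chain_id, r))
    i
  }, integer(1))
  names(idx) <- MARKER_ROLES
  idx
}

#' Brush height of one chain over a window
#'
#' Per frame, two candidate heights are formed from the marker carbons:
#' `h1 = z(C_TR, R0) - z(C_TR, R3)` and `h2 = z(C_IN, R1) - z(C_TR, R3)`.
#' Negative candidates are clamped to zero and the larger of the two is
#' the frame's chain height; the returned value is the mean over the
#' window.
#'
#' @param traj A `brush_trajectory`.
#' @param topology The matching `brush_topology`.
#' @param chain_id Chain identifier.
#' @param window Frame indices (default: all frames).
#' @return Mean height in Angstrom (scalar).
#' @export
chain_height <- function(traj, topology, chain_id, window = NULL) {
  window <- resolve_window(traj, window)
  mk <- chain_marker_rows(topology, chain_id)
  z0 <- traj$coords[mk["marker_CTR_R0"], 3, window]
  z1 <- traj$coords[mk["marker_CIN_R1"], 3, window]
  z3 <- traj$coords[mk["marker_CTR_R3"], 3, window]
  h1 <- pmax(z0 - z3, 0)
  h2 <- pmax(z1 - z3, 0)
  mean(pmax(h1, h2))
}

#' Root-mean-square fluctuation of one chain over a window
#'
#' For every non-anchored side-group atom of the chain, the RMS of its
#' displacement from its own window-mean position (no superposition: the
#' chain is grafted, so fluctuations are taken in the lab frame); the
#' chain value is the unweighted mean over those atoms.
#'
#' @inheritParams chain_height
#' @return Mean RMSF in Angstrom (scalar).
#' @export
chain_rmsf <- function(traj, topology, chain_id, window = NULL) {
  window <- resolve_window(traj, window)
  if (length(window) < 2L)
    stop("RMSF needs a window of at least 2 frames")
  sel <- !is.na(topology$atoms$chain_id) &
    topology$atoms$chain_id == chain_id & !topology$atoms$anchored &
    !is.na(topology$atoms$group_id)
  idx <- which(sel)
  if (!length(idx)) stop("chain ", chain_id, " has no side-group atoms")
  x <- traj$coords[idx, , window, drop = FALSE]
  mu <- apply(x, c(1, 2), mean)
  dev2 <- sweep(x, c(1, 2), mu)^2
  mean(sqrt(apply(dev2, 1, mean) * 3))  # mean over frames of |d|^2 = 3 * grand mean
}

#' Hydration-shell water count of one chain over a window
#'
#' Per frame, counts water hydrogen atoms whose minimum-image distance to
#' any ester or sulfonate oxygen of the chain is at or below the cutoff
#' (3 Angstrom by default). A hydrogen near several oxygens of the same
#' chain counts once for the chain; the per-side-group breakdown counts
#' it once per group. Returns the per-frame mean.
#'
#' @inheritParams chain_height
#' @param cutoff Shell radius in Angstrom (default 3).
#' @param per_group If `TRUE`, also return the per-side-group means.
#' @return Mean hydrogen count (scalar), or a list with `chain` and
#'   `by_group` when `per_group = TRUE`.
#' @export
chain_hydration <- function(traj, topology, chain_id, window = NULL,
                            cutoff = 3.0, per_group = FALSE) {
  stopifnot(cutoff > 0)
  window <- resolve_window(traj, window)
  wh <- role_idx(topology, "water_H")
  if (!length(wh))
    stop("topology contains no water hydrogens; hydration undefined")
  ox <- role_idx(topology, c("ester_O", "sulfonate_O"), chain_id = chain_id)
  if (!length(ox)) stop("chain ", chain_id, " has no ester/sulfonate oxygens")
  groups <- topology$atoms$group_id[ox]
  box <- traj$box
  per_frame <- numeric(length(window))
  grp_levels <- c("R0", "R1", "R2", "R3")
  grp_counts <- matrix(0, length(window), length(grp_levels),
                       dimnames = list(NULL, grp_levels))
  for (k in seq_along(window)) {
    f <- window[k]
    d <- min_image_cross(frame_coords(traj, wh, f),
                         frame_coords(traj, ox, f), box)
    inshell <- d <= cutoff
    per_frame[k] <- sum(rowSums(inshell) > 0L)
    if (per_group) {
      for (g in grp_levels) {
        cols <- which(groups == g)
        if (length(cols))
          grp_counts[k, g] <-
            sum(rowSums(inshell[, cols, drop = FALSE]) > 0L)
      }
    }
  }
  if (per_group)
    list(chain = mean(per_frame), by_group = colMeans(grp_counts))
  else mean(per_frame)
}

#' Chain profile: one metric value for every chain
#'
#' Applies one of the per-chain metrics to every grafted chain, producing
#' the per-chain profile the topography maps consume.
#'
#' @param traj A `brush_trajectory`.
#' @param topology The matching `brush_topology`.
#' @param metric `"height"`, `"rmsf"` or `"hydration"`.
#' @param window Frame indices (default: all frames).
#' @param ... Passed to the underlying metric (e.g. `cutoff`).
#' @return A `chain_profile`: data frame with `chain_id`, `grid_i`,
#'   `grid_j`, `value`, with the metric and window as attributes.
#' @export
chain_profile <- function(traj, topology,
                          metric = c("height", "rmsf", "hydration"),
                          window = NULL, ...) {
  metric <- match.arg(metric)
  fun <- switch(metric, height = chain_height, rmsf = chain_rmsf,
                hydration = chain_hydration)
  window <- resolve_window(traj, window)
  pts <- grafting_points(topology$grid)
  pts$value <- vapply(pts$chain_id, function(cid)
    fun(traj, topology, cid, window = window, ...), numeric(1))
  attr(pts, "metric") <- metric
  attr(pts, "window") <- range(window)
  class(pts) <- c("chain_profile", "data.frame")
  pts
}

#' Standard analysis windows
#'
#' Helpers for the three windows the surface maps use: the first `n`
#' converged snapshots, the last `n` snapshots (last 1 ns at 100 frames
#' of 10 ps), and the trailing `last_ns` nanoseconds.
#'
#' @param traj A `brush_trajectory`.
#' @param n Number of frames.
#' @param last_ns Window length in ns.
#' @return Integer frame indices.
#' @export
window_first <- function(traj, n = 100L) {
  n <- min(as.integer(n), n_frames(traj))
  seq_len(n)
}

#' @rdname window_first
#' @export
window_last <- function(traj, n = 100L) {
  nf <- n_frames(traj)
  n <- min(as.integer(n), nf)
  seq.int(nf - n + 1L, nf)
}

#' @rdname window_first
#' @export
window_last_ns <- function(traj, last_ns = 100) {
  nf <- n_frames(traj)
  n <- round(last_ns * 1000 / traj$frame_interval)
  if (n > nf) stop("window longer than trajectory")
  seq.int(nf - n + 1L, nf)
}
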