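#' Foulant tracking and mechanism classification
#'
#' The foulant's vertical fate is summarized by its detachment-height
#' series (lowest C-alpha z per frame, relative to the first frame),
#' component RMSDs after optimal superposition diagnose convergence, and
#' the height series plus the contact occurrence table classify the
#' trajectory into one of the three mechanisms: detached, anchored or
#' penetrated.
#'
#' @name foulant_metrics
NULL

#' Detachment height series of the foulant
#'
#' Per frame, the minimum z among foulant C-alpha atoms minus the same
#' minimum at the reference (first) frame. Positive values mean the
#' foulant recedes from the surface; negative values mean penetration.
#'
#' @param traj A `brush_trajectory`.
#' @param topology The matching `brush_topology`.
#' @param reference_frame Frame defining height zero (default 1).
#' @return A `height_series`: data frame with `frame`, `time_ps`,
#'   `lowest_ca_z`, `height`.
#' @export
detachment_height <- function(traj, topology, reference_frame = 1L) {
  ca <- role_idx(topology, "foulant_CA")
  if (!length(ca)) stop("topology has no foulant C-alpha atoms")
  nf <- n_frames(traj)
  low <- apply(traj$coords[ca, 3, , drop = FALSE], 3, min)
  out <- data.frame(frame = seq_len(nf),
                    time_ps = (seq_len(nf) - 1L) * traj$frame_interval,
                    lowest_ca_z = low,
                    height = low - low[reference_frame])
  attr(out, "reference_frame") <- as.integer(reference_frame)
  class(out) <- c("height_series", "data.frame")
  out
}

# Kabsch: optimal rotation superposing x (n x 3) onto y (n x 3) after
# centring; returns RMSD after the fit.
kabsch_rmsd <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- xc %*% t(R)
  sqrt(mean(rowSums((fit - yc)^2)))
}

#' Component RMSD after optimal superposition
#'
#' RMSD of each frame's atoms onto the reference frame, neglecting rigid
#' translation and rotation (Kabsch least-squares fit per frame), for the
#' foulant, the polymer chains, or the combined system. Each component is
#' fitted on its own atoms.
#'
#' @param traj A `brush_trajectory`.
#' @param topology The matching `brush_topology`.
#' @param component `"foulant"`, `"polymer"` or `"combined"`.
#' @param reference_frame Reference frame index (default 1).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
component_rmsd <- function(traj, topology,
                           component = c("combined", "foulant", "polymer"),
                           reference_frame = 1L) {
  component <- match.arg(component)
  atoms <- topology$atoms
  idx <- switch(component,
    foulant = which(startsWith(atoms$role, "foulant")),
    polymer = which(!is.na(atoms$chain_id)),
    combined = which(startsWith(atoms$role, "foulant") |
                       !is.na(atoms$chain_id)))
  if (!length(idx)) stop("component '", component, "' has no atoms")
  if (n_frames(traj) < 2L) stop("need at least 2 frames for RMSD")
  ref <- traj$coords[idx, , reference_frame]
  if (length(idx) < 3L || qr(scale(ref, scale = FALSE))$rank < 2L)
    stop("superposition degenerate: fewer than 3 non-collinear atoms")
  vapply(seq_len(n_frames(traj)), function(f)
    kabsch_rmsd(traj$coords[idx, , f], ref), numeric(1))
}

#' Flag RMSD convergence by a rolling-mean criterion
#'
#' Convergence is flagged once the rolling mean of the RMSD over a
#' 20-ns-equivalent span changes by less than 5 percent between
#' consecutive spans. Informational only.
#'
#' @param rmsd Per-frame RMSD vector.
#' @param frame_interval Frame spacing in ps.
#' @param span_ns Rolling span in ns (default 20).
#' @return List with `converged` (logical) and `converged_at` (first
#'   frame of the converged span, or `NA`).
#' @export
rmsd_convergence <- function(rmsd, frame_interval = 10, span_ns = 20) {
  w <- max(2L, min(length(rmsd) %/% 2L,
                   round(span_ns * 1000 / frame_interval)))
  n_spans <- length(rmsd) %/% w
  if (n_spans < 2L) return(list(converged = NA, converged_at = NA_integer_))
  means <- vapply(seq_len(n_spans), function(k)
    mean(rmsd[((k - 1L) * w + 1L):(k * w)]), numeric(1))
  rel <- abs(diff(means)) / pmax(abs(means[-length(means)]), 1e-12)
  ok <- which(rel < 0.05)
  if (length(ok))
    list(converged = TRUE, converged_at = ok[1] * w + 1L)
  else list(converged = FALSE, converged_at = NA_integer_)
}

#' Classify a trajectory into a foulant mechanism
#'
#' The terminal mean detachment height (over the last fraction of
#' frames) drives the call: above `detach_threshold` is detached, below
#' `-penetrate_threshold` is penetrated; otherwise the trajectory is
#' anchored if any foulant-polymer contact survives the occurrence
#' neglect floor, else detached. Thresholds are echoed in the result.
#'
#' @param series A `height_series` from [detachment_height()].
#' @param contacts An `occurrence_table` of foulant-polymer contacts over
#'   the same window.
#' @param detach_threshold Height above which the foulant counts as
#'   detached (default +10 Angstrom).
#' @param penetrate_threshold Depth below the start counting as
#'   penetration (default 5 Angstrom).
#' @param terminal_frac Fraction of trailing frames averaged (default
#'   0.1).
#' @param floor Occurrence neglect floor in percent (default 5).
#' @return A `mechanism_call`: list with `label`, `terminal_height`, and
#'   the thresholds used.
#' @export
classify_mechanism <- function(series, contacts,
                               detach_threshold = 10,
                               penetrate_threshold = 5,
                               terminal_frac = 0.1,
                               floor = 5) {
  stopifnot(inherits(series, "height_series"))
  nf <- nrow(series)
  if (nf == 0L) stop("empty height series")
  tail_n <- max(1L, round(nf * terminal_frac))
  term <- mean(series$height[(nf - tail_n + 1L):nf])
  label <- if (term > detach_threshold) {
    "detached"
  } else if (term < -penetrate_threshold) {
    "penetrated"
  } else {
    kept <- apply_neglect_floor(contacts, floor = floor)
    if (nrow(kept) > 0L) "anchored" else "detached"
  }
  out <- list(label = label, terminal_height = term,
              detach_threshold = detach_threshold,
              penetrate_threshold = penetrate_threshold,
              terminal_frac = terminal_frac, floor = floor)
  class(out) <- "mechanism_call"
  out
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("mechanism: %s (terminal height %.2f A; thresholds +%g/-%g A, floor %g%%)\n",
              x$label, x$terminal_height, x$detach_threshold,
              x$penetrate_threshold, x$floor))
  invisible(x)
}
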