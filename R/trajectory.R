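#' Trajectory container
#'
#' Ordered frames of coordinates sharing one topology. Coordinates are an
#' `n_atoms x 3 x n_frames` array in Angstrom; `frame_interval` is the
#' snapshot spacing in picoseconds (default 10 ps, so a 100 ns window
#' holds 10,000 frames). The box is periodic in x and y, aperiodic in z.
#'
#' @name brush_trajectory
NULL

new_brush_trajectory <- function(coords, frame_interval, box,
                                 periodic = c(TRUE, TRUE, FALSE)) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            frame_interval > 0, all(is.finite(coords)))
  traj <- list(coords = coords, frame_interval = frame_interval,
               box = box, periodic = periodic)
  class(traj) <- "brush_trajectory"
  traj
}

#' @export
print.brush_trajectory <- function(x, ...) {
  cat(sprintf("brush_trajectory: %d frames x %d atoms, %g ps/frame (%g ns)\n",
              n_frames(x), dim(x$coords)[1], x$frame_interval,
              n_frames(x) * x$frame_interval / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `brush_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Select the trailing time window of a trajectory
#'
#' Returns the last `last_ns` nanoseconds as a new trajectory: at the
#' default 10 ps frame interval, the last 100 ns are exactly the last
#' 10,000 snapshots.
#'
#' @param traj A `brush_trajectory`.
#' @param last_ns Window length in nanoseconds.
#' @return A `brush_trajectory` with `last_ns * 1000 / frame_interval`
#'   frames.
#' @export
select_window <- function(traj, last_ns) {
  stopifnot(inherits(traj, "brush_trajectory"), last_ns > 0)
  n_want <- round(last_ns * 1000 / traj$frame_interval)
  nf <- n_frames(traj)
  if (n_want > nf)
    stop(sprintf("window of %g ns (%d frames) exceeds trajectory length (%d frames)",
                 last_ns, n_want, nf))
  keep <- seq.int(nf - n_want + 1L, nf)
  new_brush_trajectory(traj$coords[, , keep, drop = FALSE],
                       traj$frame_interval, traj$box, traj$periodic)
}

# Coordinates of selected atoms at one frame, always as an n x 3 matrix.
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3)
}

# Normalize a window argument to frame indices. NULL -> all frames.
resolve_window <- function(traj, window) {
  nf <- n_frames(traj)
  if (is.null(window)) return(seq_len(nf))
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty window")
  if (any(window < 1L | window > nf))
    stop("window indices outside 1..", nf)
  window
}
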