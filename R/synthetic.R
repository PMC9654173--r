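#' Scenario specifications for synthetic trajectories
#'
#' A scenario scripts the mechanism ground truth a synthetic trajectory
#' must realize: the foulant's per-frame vertical offset, the amplitude
#' of Gaussian chain fluctuations, the number of explicit waters, and an
#' optional contact schedule that forces named foulant/polymer atom pairs
#' within an interaction cutoff in chosen frames. With the same seed the
#' generated trajectory is bit-identical.
#'
#' `chain_fluctuation_sigma` is the target per-atom RMS displacement in
#' Angstrom: marker atoms receive z-only noise of that standard deviation
#' (so scripted heights stay analytically known), and the remaining
#' non-anchored polymer atoms receive isotropic noise of per-coordinate
#' standard deviation `sigma / sqrt(3)`, making every atom's 3D RMSF equal
#' to sigma in expectation.
#'
#' @param mechanism One of `"detach"`, `"anchor"`, `"penetrate"`,
#'   `"static"`.
#' @param n_frames Number of snapshots (>= 1).
#' @param frame_interval Snapshot spacing in ps (default 10).
#' @param chain_fluctuation_sigma Per-atom RMS fluctuation in Angstrom.
#' @param foulant_z_schedule Numeric vector, one vertical offset per frame
#'   (Angstrom, relative to the placement position).
#' @param water_count Number of explicit 3-point waters to place.
#' @param contact_schedule Optional list of entries
#'   `list(foulant_role=, polymer_role=, frames=, distance=)` (or explicit
#'   `foulant_atom`/`polymer_atom` serials) forced to the given separation
#'   in the listed frames.
#' @param seed Integer RNG seed.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(mechanism = c("static", "detach", "anchor",
                                        "penetrate"),
                          n_frames = 200L,
                          frame_interval = 10,
                          chain_fluctuation_sigma = 0.8,
                          foulant_z_schedule = numeric(n_frames),
                          water_count = 100L,
                          contact_schedule = list(),
                          seed = 1L) {
  mechanism <- match.arg(mechanism)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (chain_fluctuation_sigma < 0) stop("sigma must be >= 0")
  if (length(foulant_z_schedule) != n_frames)
    stop(sprintf("foulant_z_schedule has length %d, expected n_frames = %d",
                 length(foulant_z_schedule), n_frames))
  for (e in contact_schedule) {
    if (is.null(e$frames) || any(e$frames < 1L | e$frames > n_frames))
      stop("contact_schedule frames must lie within 1..n_frames")
  }
  spec <- list(mechanism = mechanism, n_frames = n_frames,
               frame_interval = frame_interval,
               chain_fluctuation_sigma = chain_fluctuation_sigma,
               foulant_z_schedule = foulant_z_schedule,
               water_count = as.integer(water_count),
               contact_schedule = contact_schedule,
               seed = as.integer(seed))
  class(spec) <- "scenario_spec"
  spec
}

#' Preset scenarios for the three adsorption mechanisms
#'
#' Scripts the qualitative regimes a charged foulant shows on a
#' zwitterionic brush:
#' \describe{
#'   \item{detach}{monotone rise of the foulant, ending 40 Angstrom above
#'     its start, with no scheduled contacts;}
#'   \item{anchor}{the foulant settles at the brush top (terminal offset
#'     within 2 Angstrom of start) while an ammonium-nitrogen /
#'     negative-foulant-atom electrostatic contact persists;}
#'   \item{penetrate}{the foulant sinks below the mean brush height while
#'     a sulfonate-oxygen / positive-foulant-atom contact persists;}
#'   \item{static}{no foulant motion, no noise.}
#' }
#'
#' @param mechanism Mechanism name.
#' @param n_frames Number of frames (default 200; scale up as needed).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
mechanism_preset <- function(mechanism, n_frames = 200L, seed = 1L, ...) {
  n_frames <- as.integer(n_frames)
  t01 <- if (n_frames > 1) (seq_len(n_frames) - 1) / (n_frames - 1) else 0
  contact_frames <- seq.int(max(1L, ceiling(n_frames * 0.1)), n_frames)
  switch(mechanism,
    detach = scenario_spec("detach", n_frames, seed = seed,
                           foulant_z_schedule = 40 * t01, ...),
    anchor = scenario_spec("anchor", n_frames, seed = seed,
                           foulant_z_schedule = 1.5 * exp(-4 * t01),
                           contact_schedule = list(list(
                             foulant_role = "foulant_neg_atom",
                             polymer_role = "ammonium_N",
                             frames = contact_frames, distance = 3.9)), ...),
    penetrate = scenario_spec("penetrate", n_frames, seed = seed,
                              foulant_z_schedule = -25 * t01,
                              contact_schedule = list(list(
                                foulant_role = "foulant_pos_atom",
                                polymer_role = "sulfonate_O",
                                frames = contact_frames, distance = 3.9)), ...),
    static = scenario_spec("static", n_frames, seed = seed,
                           chain_fluctuation_sigma = 0, ...),
    stop("unknown mechanism: ", mechanism))
}

#' Generate a synthetic trajectory for a scenario
#'
#' Produces a trajectory honouring the anchoring contract (anchored atoms
#' immobile in every frame), with Gaussian chain fluctuations, a rigidly
#' translated foulant following the scenario's z-schedule, static explicit
#' waters placed uniformly outside a 2.5 Angstrom clash shell, and any
#' scheduled contacts forced to their scripted separation (the forced
#' foulant atom leaves the rigid body in those frames only).
#'
#' @param topology A `brush_topology` (with a foulant if the scenario
#'   moves one).
#' @param spec A `scenario_spec`.
#' @return A list with `topology` (waters appended) and `trajectory`
#'   (a `brush_trajectory`).
#' @export
generate_trajectory <- function(topology, spec) {
  stopifnot(inherits(topology, "brush_topology"),
            inherits(spec, "scenario_spec"))
  has_foulant <- any(startsWith(topology$atoms$role, "foulant"))
  if (!has_foulant &&
      (any(spec$foulant_z_schedule != 0) || length(spec$contact_schedule)))
    stop("scenario scripts foulant motion but topology has no foulant")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  topo <- add_waters(topology, spec$water_count)
  atoms <- topo$atoms
  nat <- nrow(atoms); nf <- spec$n_frames
  coords <- array(rep(topo$coords, nf), dim = c(nat, 3, nf))

  marker <- atoms$role %in% MARKER_ROLES
  poly <- !is.na(atoms$chain_id)
  noisy3d <- poly & !atoms$anchored & !marker
  sig <- spec$chain_fluctuation_sigma
  fl <- which(startsWith(atoms$role, "foulant"))
  for (f in seq_len(nf)) {
    if (sig > 0) {
      coords[marker, 3, f] <- coords[marker, 3, f] +
        rnorm(sum(marker), 0, sig)
      coords[noisy3d, , f] <- coords[noisy3d, , f] +
        matrix(rnorm(3 * sum(noisy3d), 0, sig / sqrt(3)), ncol = 3)
    }
    if (length(fl))
      coords[fl, 3, f] <- coords[fl, 3, f] + spec$foulant_z_schedule[f]
  }
  for (e in spec$contact_schedule) {
    pair <- resolve_contact_pair(topo, e)
    d <- if (is.null(e$distance)) 3.9 else e$distance
    for (f in e$frames)
      coords[pair$foulant, , f] <- coords[pair$polymer, , f] + c(0, 0, d)
  }
  list(topology = topo,
       trajectory = new_brush_trajectory(coords, spec$frame_interval,
                                         topo$box))
}

# Resolve a contact-schedule entry to atom row indices: explicit serials
# win; otherwise the polymer atom of the role on the chain nearest the
# grid centre, and the first foulant atom of the foulant role.
resolve_contact_pair <- function(topology, e) {
  atoms <- topology$atoms
  if (!is.null(e$foulant_atom) && !is.null(e$polymer_atom)) {
    return(list(foulant = match(e$foulant_atom, atoms$serial),
                polymer = match(e$polymer_atom, atoms$serial)))
  }
  fi <- role_idx(topology, e$foulant_role)
  if (!length(fi)) stop("no foulant atom with role ", e$foulant_role)
  grid <- topology$grid
  ctr <- c(grid$origin[1] + (grid$n_x - 1) * grid$spacing_x / 2,
           grid$origin[2] + (grid$n_y - 1) * grid$spacing_y / 2)
  pts <- grafting_points(grid)
  central <- pts$chain_id[which.min((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)]
  pi_ <- role_idx(topology, e$polymer_role, chain_id = central)
  if (!length(pi_)) stop("no polymer atom with role ", e$polymer_role,
                         " on chain ", central)
  list(foulant = fi[1], polymer = pi_[1])
}

# Place n static 3-point waters uniformly in the box, rejecting positions
# whose oxygen falls within 2.5 A (minimum image, xy-periodic) of any
# existing atom.
add_waters <- function(topology, n, clash = 2.5) {
  if (n <= 0L) return(topology)
  box <- topology$box
  z_top <- max(topology$coords[, 3]) + 8
  placed <- matrix(NA_real_, n, 3)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("could not place ", n, " waters outside the clash shell")
    p <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), runif(1, 0.5, z_top))
    dmin <- min(min_image_cross(matrix(p, 1), topology$coords, box))
    if (dmin < clash) next
    got <- got + 1L
    placed[got, ] <- p
  }
  # fixed internal 3-point geometry: O-H 0.9572 A, H-O-H 104.52 degrees
  h1 <- c(0.9572, 0, 0)
  ang <- 104.52 * pi / 180
  h2 <- 0.9572 * c(cos(ang), sin(ang), 0)
  wat_coords <- matrix(NA_real_, 3L * n, 3)
  for (k in seq_len(n)) {
    wat_coords[3 * k - 2, ] <- placed[k, ]
    wat_coords[3 * k - 1, ] <- placed[k, ] + h1
    wat_coords[3 * k, ]     <- placed[k, ] + h2
  }
  wa <- data.frame(
    serial = max(topology$atoms$serial) + seq_len(3L * n),
    role = rep(c("water_O", "water_H", "water_H"), n),
    chain_id = NA_integer_, group_id = NA_character_, anchored = FALSE,
    charge = 0L, donor = rep(c(FALSE, TRUE, TRUE), n), acceptor = FALSE,
    tacticity = NA_character_, stringsAsFactors = FALSE)
  new_brush_topology(rbind(topology$atoms, wa[, colnames(topology$atoms)]),
                     rbind(topology$coords, wat_coords),
                     grid = topology$grid, box = topology$box,
                     foulant_info = topology$foulant_info)
}
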