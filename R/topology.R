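#' Brush topologies
#'
#' A `brush_topology` couples an atom table (serial, role, chain and
#' repeat-unit membership, anchoring flag, charge class, donor/acceptor
#' flags) with reference coordinates, the grafting grid and the periodic
#' box. Roles are the only chemistry the analyses see: marker carbons
#' C_TR/C_IN for the height metrics, ester and sulfonate oxygens for
#' hydration and H-bond acceptors, ammonium nitrogens and sulfonate
#' oxygens as the zwitterion charge sites, and foulant C-alpha, charged
#' and polar-hydrogen atoms.
#'
#' @name brush_topology
NULL

ATOM_ROLES <- c("polymer_backbone", "marker_CTR_R0", "marker_CIN_R1",
                "marker_CTR_R3", "ester_O", "sulfonate_O", "ammonium_N",
                "water_O", "water_H", "foulant_CA", "foulant_neg_atom",
                "foulant_pos_atom", "foulant_polar_H", "other")

MARKER_ROLES <- c("marker_CTR_R0", "marker_CIN_R1", "marker_CTR_R3")

new_brush_topology <- function(atoms, coords, grid = NULL, box = NULL,
                               foulant_info = NULL) {
  stopifnot(nrow(atoms) == nrow(coords), ncol(coords) == 3)
  bad <- setdiff(unique(atoms$role), ATOM_ROLES)
  if (length(bad)) stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  topo <- list(atoms = atoms, coords = unname(coords), grid = grid,
               box = box, foulant_info = foulant_info)
  class(topo) <- "brush_topology"
  topo
}

#' @export
print.brush_topology <- function(x, ...) {
  cat(sprintf("brush_topology: %d atoms, %d chains", nrow(x$atoms), n_chains(x)))
  nw <- sum(x$atoms$role == "water_O")
  if (nw) cat(sprintf(", %d waters", nw))
  if (any(startsWith(x$atoms$role, "foulant"))) cat(", foulant present")
  if (!is.null(x$box))
    cat(sprintf("; box %g x %g x %g A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

#' Default coarse chain template
#'
#' One grafted chain of four repeat units (side groups R0 at the free end
#' down to R3 at the grafted end), represented coarsely: per repeat unit a
#' backbone carbon (the C_TR/C_IN marker where the height metrics need
#' one), a carbonyl ester oxygen, a quaternary ammonium nitrogen and three
#' sulfonate oxygens; plus one buried methylene carbon at the grafting
#' plane that is held fixed in every trajectory. Marker heights default to
#' z = 30 (C_TR of R0), 25 (C_IN of R1) and 10 (C_TR of R3), giving every
#' chain a reference brush height of 20 Angstrom. Chiral backbone carbons
#' alternate side (syndiotactic); the alternation is recorded as the sign
#' of the lateral offset and as metadata, with no other geometric role.
#'
#' @param marker_z Named numeric: reference z of the three markers.
#' @return A list with an `atoms` data frame and an n x 3 `coords` matrix
#'   of offsets relative to the grafting point.
#' @export
chain_template <- function(marker_z = c(R0 = 30, R1 = 25, R3 = 10)) {
  stopifnot(all(c("R0", "R1", "R3") %in% names(marker_z)))
  zb <- c(R0 = unname(marker_z["R0"]), R1 = unname(marker_z["R1"]),
          R2 = unname((marker_z["R1"] + marker_z["R3"]) / 2),
          R3 = unname(marker_z["R3"]))
  rows <- list(); xyz <- list()
  add <- function(role, group, x, y, z, anchored = FALSE, charge = 0L,
                  donor = FALSE, acceptor = FALSE, tacticity = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, group_id = group, anchored = anchored, charge = charge,
      donor = donor, acceptor = acceptor, tacticity = tacticity,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- c(x, y, z)
  }
  # buried methylene carbon, fixed at the grafting plane
  add("polymer_backbone", NA_character_, 0, 0, 0, anchored = TRUE)
  groups <- c("R0", "R1", "R2", "R3")
  marker_role <- c(R0 = "marker_CTR_R0", R1 = "marker_CIN_R1",
                   R2 = "polymer_backbone", R3 = "marker_CTR_R3")
  for (k in seq_along(groups)) {
    g <- groups[k]
    s <- if (k %% 2 == 1) 1 else -1   # syndiotactic alternation
    tac <- if (s > 0) "R" else "S"
    z0 <- zb[g]
    add(marker_role[g], g, 0, 0, z0, tacticity = tac)
    add("ester_O", g, 0.8 * s, 0.5, z0 - 1.0, acceptor = TRUE)
    add("ammonium_N", g, -0.9 * s, -0.6, z0 + 0.5, charge = 1L)
    for (m in 0:2)
      add("sulfonate_O", g, 1.3 * s + 0.4 * cos(2 * pi * m / 3),
          0.4 * sin(2 * pi * m / 3) - 0.6, z0 + 1.2,
          charge = -1L, acceptor = TRUE)
  }
  atoms <- do.call(rbind, rows)
  list(atoms = atoms, coords = do.call(rbind, xyz))
}

#' Instantiate brush chains on a grafting grid
#'
#' Copies the chain template to every grafting point, populating atom
#' roles, chain ids and the anchoring flags. Anchored atoms sit exactly at
#' the grafting plane (z = 0).
#'
#' @param grid A `grafting_grid`.
#' @param template A chain template as from [chain_template()].
#' @param box_z Vertical box length in Angstrom (bulk solvent above the
#'   brush; default leaves ~40 Angstrom headroom over the template top).
#' @return A `brush_topology` with `n_chains(grid)` chains.
#' @export
instantiate_chains <- function(grid, template = chain_template(),
                               box_z = NULL) {
  stopifnot(inherits(grid, "grafting_grid"))
  if (!all(MARKER_ROLES %in% template$atoms$role))
    stop("chain template must provide all three marker roles: ",
         paste(setdiff(MARKER_ROLES, template$atoms$role), collapse = ", "))
  if (!any(template$atoms$anchored))
    stop("chain template must provide at least one anchored atom")
  pts <- grafting_points(grid)
  nat <- nrow(template$atoms)
  atoms_list <- vector("list", nrow(pts))
  coords_list <- vector("list", nrow(pts))
  for (c_idx in seq_len(nrow(pts))) {
    a <- template$atoms
    a$chain_id <- pts$chain_id[c_idx]
    atoms_list[[c_idx]] <- a
    xyz <- template$coords
    xyz[, 1] <- xyz[, 1] + pts$x[c_idx]
    xyz[, 2] <- xyz[, 2] + pts$y[c_idx]
    coords_list[[c_idx]] <- xyz
  }
  atoms <- do.call(rbind, atoms_list)
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "role", "chain_id", "group_id", "anchored",
                     "charge", "donor", "acceptor", "tacticity")]
  coords <- do.call(rbind, coords_list)
  if (is.null(box_z)) box_z <- max(coords[, 3]) + 40
  new_brush_topology(atoms, coords, grid = grid,
                     box = c(grid$box_x, grid$box_y, box_z))
}

#' Synthetic rigid foulant blob
#'
#' A BSA-like rigid foulant stand-in: C-alpha atoms on a sphere, charged
#' surface atoms (positive ammonium-type, negative carboxylate-type) in
#' the exact positive:negative count ratio of the requested adsorption
#' orientation (A 10:16, B 10:19, C 10:20), and polar hydrogens as H-bond
#' donors. Construction is deterministic (Fibonacci sphere placement).
#'
#' @param orientation One of `"A"`, `"B"`, `"C"` — selects the surface
#'   charge composition.
#' @param radius Sphere radius in Angstrom (default 12, a scaled-down
#'   globular protein).
#' @param n_ca Number of C-alpha atoms.
#' @param n_polar_h Number of polar hydrogen donors.
#' @return A list with `atoms` and `coords` (centred on the origin).
#' @export
make_foulant <- function(orientation = c("A", "B", "C"), radius = 12,
                         n_ca = 24L, n_polar_h = 12L) {
  orientation <- match.arg(orientation)
  n_neg <- c(A = 16L, B = 19L, C = 20L)[[orientation]]
  n_pos <- 10L
  fib_sphere <- function(n, r, phase = 0) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    th <- pi * (1 + sqrt(5)) * i + phase
    r * cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  }
  mk <- function(role, n, r, phase, charge = 0L, donor = FALSE) {
    list(atoms = data.frame(
           role = rep(role, n), group_id = NA_character_, anchored = FALSE,
           charge = rep(charge, n), donor = rep(donor, n), acceptor = FALSE,
           tacticity = NA_character_, stringsAsFactors = FALSE),
         coords = fib_sphere(n, r, phase))
  }
  parts <- list(
    mk("foulant_CA", n_ca, radius, 0),
    mk("foulant_pos_atom", n_pos, radius + 0.5, 1.1, charge = 1L),
    mk("foulant_neg_atom", n_neg, radius + 0.5, 2.3, charge = -1L),
    mk("foulant_polar_H", n_polar_h, radius + 0.8, 3.7, donor = TRUE)
  )
  list(atoms = do.call(rbind, lapply(parts, `[[`, "atoms")),
       coords = do.call(rbind, lapply(parts, `[[`, "coords")),
       orientation = orientation,
       charge_ratio = c(positive = 1.0, negative = n_neg / n_pos))
}

#' Place a rigid foulant on top of the brush
#'
#' Applies the orientation preset (A: identity, B: 90 degrees about x,
#' C: 90 degrees about y), centres the foulant over the middle of the
#' grafting grid, and drops it so its lowest atom sits `initial_gap`
#' above the highest brush atom. The positive:negative surface charge
#' ratio is recorded on the returned topology.
#'
#' @param topology A `brush_topology` without a foulant.
#' @param foulant A foulant as from [make_foulant()].
#' @param orientation Orientation label; defaults to the foulant's own.
#' @param initial_gap Starting clearance in Angstrom (default 2.5, the
#'   solvent-clash removal distance).
#' @return A `brush_topology` including the foulant atoms.
#' @export
place_foulant <- function(topology, foulant, orientation = NULL,
                          initial_gap = 2.5) {
  stopifnot(inherits(topology, "brush_topology"))
  if (is.null(foulant) || nrow(foulant$atoms) == 0L)
    stop("foulant is empty")
  if (!any(foulant$atoms$role == "foulant_CA"))
    stop("foulant must contain at least one C-alpha atom")
  if (!any(foulant$atoms$charge > 0) || !any(foulant$atoms$charge < 0))
    stop("foulant must carry charged atoms of both signs")
  if (any(startsWith(topology$atoms$role, "foulant")))
    stop("topology already contains a foulant")
  if (is.null(orientation)) orientation <- foulant$orientation
  R <- switch(orientation,
              A = diag(3), B = rot_x(90), C = rot_y(90),
              stop("unknown orientation: ", orientation))
  xyz <- foulant$coords %*% t(R)
  grid <- topology$grid
  cx <- grid$origin[1] + (grid$n_x - 1) * grid$spacing_x / 2
  cy <- grid$origin[2] + (grid$n_y - 1) * grid$spacing_y / 2
  xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + cx
  xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + cy
  z_top <- max(topology$coords[, 3])
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + z_top + initial_gap
  fa <- foulant$atoms
  fa$chain_id <- NA_integer_
  fa$serial <- max(topology$atoms$serial) + seq_len(nrow(fa))
  fa <- fa[, colnames(topology$atoms)]
  box <- topology$box
  box[3] <- max(box[3], max(xyz[, 3]) + 15)
  new_brush_topology(rbind(topology$atoms, fa),
                     rbind(topology$coords, xyz),
                     grid = grid, box = box,
                     foulant_info = list(
                       orientation = orientation,
                       charge_ratio = c(positive = 1.0,
                                        negative = sum(fa$charge < 0) /
                                          sum(fa$charge > 0)),
                       initial_gap = initial_gap))
}

# Atom indices (0/1-based row numbers) for a role set, optionally per chain.
role_idx <- function(topology, roles, chain_id = NULL) {
  sel <- topology$atoms$role %in% roles
  if (!is.null(chain_id))
    sel <- sel & !is.na(topology$atoms$chain_id) &
      topology$atoms$chain_id == chain_id
  which(sel)
}
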