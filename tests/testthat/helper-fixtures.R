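# Fixtures and independent brute-force oracles. Oracles are deliberately
# naive (scalar loops, explicit image enumeration) and share no code with
# the implementation paths they check.

new_topo <- brushfoul:::new_brush_topology
new_traj <- brushfoul:::new_brush_trajectory

# Small brush + foulant topology. gap = 6 keeps unscheduled foulant atoms
# safely outside the 4 A electrostatic cutoff so scripted contact
# occupancy is the only source of contacts.
tiny_topology <- function(nx = 2, spacing = 10, gap = 6,
                          orientation = "A") {
  g <- brushfoul:::new_grafting_grid(spacing, spacing, nx, nx)
  place_foulant(instantiate_chains(g), make_foulant(orientation),
                initial_gap = gap)
}

# Random small fixture for oracle-equivalence tests: real role structure,
# fully random coordinates each frame.
random_fixture <- function(n_frames = 20, seed = 42, water_count = 6) {
  set.seed(seed)
  g <- brushfoul:::new_grafting_grid(12, 12, 1L, 2L)
  topo <- place_foulant(instantiate_chains(g), make_foulant("A", n_ca = 4L,
                                                            n_polar_h = 4L),
                        initial_gap = 3)
  topo <- brushfoul:::add_waters(topo, water_count)
  nat <- nrow(topo$atoms)
  coords <- array(rnorm(nat * 3 * n_frames, sd = 6), c(nat, 3, n_frames))
  coords <- coords + array(rep(topo$coords, n_frames), c(nat, 3, n_frames))
  anch <- topo$atoms$anchored
  coords[anch, , ] <- array(rep(topo$coords[anch, , drop = FALSE], n_frames),
                            c(sum(anch), 3, n_frames))
  list(topology = topo,
       trajectory = new_traj(coords, 10, topo$box))
}

# Minimal randomized system under 50 atoms: one full chain (25 atoms), a
# 9-atom hand-made foulant, four waters (12 atoms) = 46 atoms.
small_random_system <- function(n_frames = 60, seed = 5) {
  set.seed(seed)
  g <- brushfoul:::new_grafting_grid(15, 15, 1L, 1L)
  topo <- instantiate_chains(g)
  extra <- data.frame(
    serial = max(topo$atoms$serial) + 1:21,
    role = c(rep("foulant_CA", 3), rep("foulant_pos_atom", 2),
             rep("foulant_neg_atom", 2), rep("foulant_polar_H", 2),
             rep(c("water_O", "water_H", "water_H"), 4)),
    chain_id = NA_integer_, group_id = NA_character_, anchored = FALSE,
    charge = c(0, 0, 0, 1, 1, -1, -1, 0, 0, rep(0, 12)),
    donor = c(rep(FALSE, 7), TRUE, TRUE,
              rep(c(FALSE, TRUE, TRUE), 4)),
    acceptor = FALSE, tacticity = NA_character_)
  topo <- new_topo(rbind(topo$atoms, extra),
                   rbind(topo$coords, matrix(runif(21 * 3, 0, 15), 21, 3)),
                   grid = g, box = topo$box)
  nat <- nrow(topo$atoms)
  coords <- array(rnorm(nat * 3 * n_frames, sd = 5), c(nat, 3, n_frames)) +
    array(rep(topo$coords, n_frames), c(nat, 3, n_frames))
  anch <- topo$atoms$anchored
  coords[anch, , ] <- array(rep(topo$coords[anch, , drop = FALSE], n_frames),
                            c(sum(anch), 3, n_frames))
  list(topology = topo, trajectory = new_traj(coords, 10, topo$box))
}

# -- oracles ----------------------------------------------------------------

# Minimum-image distance by explicit image enumeration (range wide enough
# for fixtures whose raw displacements span several box lengths).
oracle_min_image <- function(p, q, box) {
  best <- Inf
  for (ix in -3:3) for (iy in -3:3) {
    d <- p - (q + c(ix * box[1], iy * box[2], 0))
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

oracle_height <- function(traj, topo, chain_id, window) {
  a <- topo$atoms
  row_of <- function(role) which(a$role == role & !is.na(a$chain_id) &
                                   a$chain_id == chain_id)
  hs <- numeric(0)
  for (f in window) {
    z0 <- traj$coords[row_of("marker_CTR_R0"), 3, f]
    z1 <- traj$coords[row_of("marker_CIN_R1"), 3, f]
    z3 <- traj$coords[row_of("marker_CTR_R3"), 3, f]
    h1 <- max(z0 - z3, 0); h2 <- max(z1 - z3, 0)
    hs <- c(hs, max(h1, h2))
  }
  mean(hs)
}

oracle_rmsf <- function(traj, topo, chain_id, window) {
  a <- topo$atoms
  idx <- which(!is.na(a$chain_id) & a$chain_id == chain_id &
                 !a$anchored & !is.na(a$group_id))
  vals <- numeric(0)
  for (i in idx) {
    x <- t(sapply(window, function(f) traj$coords[i, , f]))
    mu <- colMeans(x)
    vals <- c(vals, sqrt(mean(rowSums(sweep(x, 2, mu)^2))))
  }
  mean(vals)
}

oracle_hydration <- function(traj, topo, chain_id, window, cutoff = 3.0) {
  a <- topo$atoms
  wh <- which(a$role == "water_H")
  ox <- which(a$role %in% c("ester_O", "sulfonate_O") &
                !is.na(a$chain_id) & a$chain_id == chain_id)
  counts <- numeric(0)
  for (f in window) {
    n <- 0L
    for (h in wh) {
      near <- FALSE
      for (o in ox)
        if (oracle_min_image(traj$coords[h, , f], traj$coords[o, , f],
                             traj$box) <= cutoff) { near <- TRUE; break }
      if (near) n <- n + 1L
    }
    counts <- c(counts, n)
  }
  mean(counts)
}

# Occurrence percentage for every admissible (i, j) pair, as a data frame
# keyed by atom serials.
oracle_occurrence <- function(traj, topo, idx_a, idx_b, cutoff,
                              window = seq_len(dim(traj$coords)[3]),
                              keep = function(i, j) TRUE) {
  rows <- list()
  for (i in idx_a) for (j in idx_b) {
    if (!keep(i, j)) next
    hits <- 0L
    for (f in window)
      if (oracle_min_image(traj$coords[i, , f], traj$coords[j, , f],
                           traj$box) <= cutoff) hits <- hits + 1L
    if (hits > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        atom_i = topo$atoms$serial[i], atom_j = topo$atoms$serial[j],
        percent = 100 * hits / length(window))
  }
  if (!length(rows)) return(data.frame(atom_i = integer(),
                                       atom_j = integer(),
                                       percent = numeric()))
  do.call(rbind, rows)
}

# Compare an occurrence_table against an oracle table pair-by-pair.
expect_table_matches_oracle <- function(tab, oracle, tol = 1e-10) {
  expect_equal(nrow(tab), nrow(oracle))
  key <- function(d) paste(d$atom_i, d$atom_j)
  m <- match(key(tab), key(oracle))
  expect_false(anyNA(m))
  expect_equal(tab$percent, oracle$percent[m], tolerance = tol)
}

oracle_cavity_matrix <- function(vals, nx, ny) {
  wrap <- function(i, n) ((i - 1) %% n) + 1
  cav <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    cav[i, j] <- mean(c(vals[i, j],
                        vals[wrap(i + 1, nx), j],
                        vals[i, wrap(j + 1, ny)],
                        vals[wrap(i + 1, nx), wrap(j + 1, ny)]))
  cav
}

# Constant-coordinate trajectory over a topology.
static_traj <- function(topo, n_frames = 1, frame_interval = 10) {
  nat <- nrow(topo$atoms)
  new_traj(array(rep(topo$coords, n_frames), c(nat, 3, n_frames)),
           frame_interval, topo$box)
}
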