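#' Interaction occurrence statistics
#'
#' Contact and hydrogen-bond occurrence tables over an analysis window.
#' A pair is "in contact" in a frame when its minimum-image distance is
#' at or below the cutoff (inclusive); its occurrence is the percentage
#' of window frames in contact. Pairs below the 5 percent neglect floor
#' are dropped by [apply_neglect_floor()] but kept in raw tables.
#'
#' @name interactions
NULL

# Core occurrence machinery over two atom index sets. pair_keep is an
# optional length(a) x length(b) logical matrix of admissible pairs.
occurrence_core <- function(traj, topology, idx_a, idx_b, window, cutoff,
                            type, pair_keep = NULL) {
  window <- resolve_window(traj, window)
  na <- length(idx_a); nb <- length(idx_b)
  counts <- matrix(0L, na, nb)
  per_frame_total <- integer(length(window))
  for (k in seq_along(window)) {
    f <- window[k]
    d <- min_image_cross(frame_coords(traj, idx_a, f),
                         frame_coords(traj, idx_b, f), traj$box)
    hit <- d <= cutoff
    if (!is.null(pair_keep)) hit <- hit & pair_keep
    counts <- counts + hit
    per_frame_total[k] <- sum(hit)
  }
  keep <- which(counts > 0L, arr.ind = TRUE)
  atoms <- topology$atoms
  tab <- data.frame(
    atom_i = atoms$serial[idx_a[keep[, 1]]],
    atom_j = atoms$serial[idx_b[keep[, 2]]],
    role_i = atoms$role[idx_a[keep[, 1]]],
    role_j = atoms$role[idx_b[keep[, 2]]],
    chain_i = atoms$chain_id[idx_a[keep[, 1]]],
    chain_j = atoms$chain_id[idx_b[keep[, 2]]],
    type = rep(type, nrow(keep)),
    frames = counts[keep],
    percent = 100 * counts[keep] / length(window),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$percent, tab$atom_i, tab$atom_j), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_frames") <- length(window)
  attr(tab, "cutoff") <- cutoff
  attr(tab, "per_frame_total") <- per_frame_total
  class(tab) <- c("occurrence_table", "data.frame")
  tab
}

#' Electrostatic contacts between foulant and polymer charge sites
#'
#' Contacts between oppositely charged atoms — foulant carboxylate-type
#' oxygens and ammonium-type nitrogens versus the brush's quaternary
#' ammonium nitrogens and sulfonate oxygens — within the cutoff
#' (4 Angstrom default, inclusive). Alongside the per-pair occurrence
#' percentages, the per-snapshot contact total normalized by the number
#' of polymer chains is averaged into the `mean_contacts_per_chain`
#' attribute (a per-surface statistic).
#'
#' @param traj A `brush_trajectory`.
#' @param topology The matching `brush_topology`.
#' @param window Frame indices (default: all frames).
#' @param cutoff Contact cutoff in Angstrom (default 4).
#' @return An `occurrence_table` (raw; apply the neglect floor with
#'   [apply_neglect_floor()]).
#' @export
electrostatic_contacts <- function(traj, topology, window = NULL,
                                   cutoff = 4.0) {
  atoms <- topology$atoms
  fi <- which(startsWith(atoms$role, "foulant") & atoms$charge != 0L)
  pi_ <- which(!is.na(atoms$chain_id) & atoms$charge != 0L)
  if (!length(fi)) stop("no charged foulant atoms in topology")
  if (!length(pi_)) stop("no charged polymer atoms in topology")
  opposite <- outer(atoms$charge[fi], atoms$charge[pi_],
                    function(a, b) a * b < 0)
  tab <- occurrence_core(traj, topology, fi, pi_, window, cutoff,
                         "electrostatic", pair_keep = opposite)
  nch <- n_chains(topology)
  attr(tab, "mean_contacts_per_chain") <-
    mean(attr(tab, "per_frame_total")) / nch
  tab
}

#' Hydrogen bonds from foulant donors to polymer acceptors
#'
#' Distance-only criterion: a foulant polar hydrogen within the cutoff
#' (2.4 Angstrom default, inclusive) of a polymer carbonyl or sulfonate
#' oxygen. An optional donor-H...acceptor angle filter exists but is off
#' by default, matching the distance-only convention of the occupancy
#' analysis this mirrors.
#'
#' @inheritParams electrostatic_contacts
#' @param cutoff H...acceptor cutoff in Angstrom (default 2.4).
#' @return An `occurrence_table`.
#' @export
hydrogen_bonds <- function(traj, topology, window = NULL, cutoff = 2.4) {
  atoms <- topology$atoms
  don <- which(atoms$role == "foulant_polar_H" & atoms$donor)
  acc <- which(!is.na(atoms$chain_id) & atoms$acceptor)
  if (!length(don)) stop("no foulant polar-hydrogen donors in topology")
  if (!length(acc)) stop("no polymer acceptor oxygens in topology")
  occurrence_core(traj, topology, don, acc, window, cutoff, "hbond")
}

#' Inter-chain electrostatic contacts within the brush
#'
#' Ammonium-nitrogen / sulfonate-oxygen pairs across distinct polymer
#' chains, same contact and occurrence rules as
#' [electrostatic_contacts()]; same-chain pairs are excluded.
#'
#' @inheritParams electrostatic_contacts
#' @return An `occurrence_table`.
#' @export
interchain_contacts <- function(traj, topology, window = NULL,
                                cutoff = 4.0) {
  if (n_chains(topology) < 2L)
    stop("inter-chain contacts need at least 2 chains")
  atoms <- topology$atoms
  nn <- which(atoms$role == "ammonium_N")
  so <- which(atoms$role == "sulfonate_O")
  cross_chain <- outer(atoms$chain_id[nn], atoms$chain_id[so], "!=")
  occurrence_core(traj, topology, nn, so, window, cutoff,
                  "interchain_electrostatic", pair_keep = cross_chain)
}

#' Drop occurrence rows below the neglect floor
#'
#' Removes rows whose occurrence percentage is strictly below the floor
#' (default 5 percent); rows at exactly the floor are retained.
#'
#' @param table An `occurrence_table`.
#' @param floor Neglect floor in percent (default 5).
#' @return The filtered `occurrence_table` (attributes preserved).
#' @export
apply_neglect_floor <- function(table, floor = 5) {
  stopifnot(inherits(table, "data.frame"))
  out <- table[table$percent >= floor, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(table)),
                    c("names", "row.names", "class")))
    attr(out, a) <- attr(table, a)
  class(out) <- class(table)
  out
}

#' Aggregate an occurrence table to residue level
#'
#' Collapses atom pairs to (foulant atom group, partner chain) records,
#' keeping the maximum occurrence among the constituent atom pairs — the
#' convention for reporting contact residues.
#'
#' @param table An `occurrence_table`.
#' @return Data frame with `role_i`, `atom_i`, `chain_j`, `type`,
#'   `percent`.
#' @export
aggregate_by_residue <- function(table) {
  if (nrow(table) == 0L)
    return(data.frame(role_i = character(), atom_i = integer(),
                      chain_j = integer(), type = character(),
                      percent = numeric()))
  key <- interaction(table$role_i, table$atom_i, table$chain_j,
                     table$type, drop = TRUE)
  idx <- vapply(split(seq_len(nrow(table)), key),
                function(i) i[which.max(table$percent[i])], integer(1))
  out <- table[idx, c("role_i", "atom_i", "chain_j", "type", "percent")]
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
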