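#' Trajectory I/O: multi-model PDB plus role-annotation sidecar
#'
#' Trajectories are exchanged as multi-model PDB files (one MODEL block
#' per snapshot, fixed columns, Angstrom) with a delimited sidecar that
#' maps atom serials to analysis roles. The PDB carries a CRYST1 record
#' with the periodic box; anchored atoms are written with occupancy and
#' temperature factor 0.00, mirroring the beta-zero convention used to
#' fix the buried methylene carbons during simulation.
#'
#' @name trajectory_io
NULL

role_pdb_fields <- function(role) {
  tab <- list(
    polymer_backbone = c(" C  ", "SPE", " C"),
    marker_CTR_R0    = c(" CTR", "SPE", " C"),
    marker_CIN_R1    = c(" CIN", "SPE", " C"),
    marker_CTR_R3    = c(" CTR", "SPE", " C"),
    ester_O          = c(" OE ", "SPE", " O"),
    sulfonate_O      = c(" OS ", "SPE", " O"),
    ammonium_N       = c(" N  ", "SPE", " N"),
    water_O          = c(" OW ", "HOH", " O"),
    water_H          = c(" HW ", "HOH", " H"),
    foulant_CA       = c(" CA ", "FLN", " C"),
    foulant_neg_atom = c(" ON ", "FLN", " O"),
    foulant_pos_atom = c(" NP ", "FLN", " N"),
    foulant_polar_H  = c(" HP ", "FLN", " H"),
    other            = c(" X  ", "UNK", " X"))
  do.call(rbind, tab[role])
}

#' Write a topology and trajectory to PDB + annotation files
#'
#' @param topology A `brush_topology`.
#' @param trajectory A `brush_trajectory` over the same atoms (or `NULL`
#'   to write the reference coordinates as a single model).
#' @param pdb_file Path for the multi-model PDB.
#' @param annotation_file Path for the tab-delimited role sidecar.
#' @return Invisibly, the two paths.
#' @export
write_trajectory <- function(topology, trajectory, pdb_file,
                             annotation_file) {
  stopifnot(inherits(topology, "brush_topology"))
  atoms <- topology$atoms
  if (is.null(trajectory)) {
    coords <- array(topology$coords, dim = c(nrow(atoms), 3, 1))
    frame_interval <- 10
  } else {
    stopifnot(inherits(trajectory, "brush_trajectory"),
              dim(trajectory$coords)[1] == nrow(atoms))
    coords <- trajectory$coords
    frame_interval <- trajectory$frame_interval
  }
  dir.create(dirname(pdb_file), recursive = TRUE, showWarnings = FALSE)
  dir.create(dirname(annotation_file), recursive = TRUE,
             showWarnings = FALSE)
  fields <- role_pdb_fields(atoms$role)
  chain_char <- ifelse(is.na(atoms$chain_id),
                       ifelse(startsWith(atoms$role, "water"), "W",
                              ifelse(startsWith(atoms$role, "foulant"),
                                     "F", "X")),
                       LETTERS[(atoms$chain_id - 1L) %% 26L + 1L])
  resseq <- ifelse(is.na(atoms$chain_id), 1L, atoms$chain_id)
  occ_b <- ifelse(atoms$anchored, 0, 1)
  box <- topology$box
  con <- file(pdb_file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90), con)
  nf <- dim(coords)[3]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d%4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$serial, fields[, 1], fields[, 2], chain_char, resseq,
      coords[, 1, f], coords[, 2, f], coords[, 3, f],
      occ_b, occ_b, fields[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  write_annotation(topology, frame_interval, annotation_file)
  invisible(c(pdb = pdb_file, annotation = annotation_file))
}

write_annotation <- function(topology, frame_interval, path) {
  con <- file(path, "w")
  on.exit(close(con))
  grid <- topology$grid
  if (!is.null(grid))
    writeLines(sprintf("# grid\t%d\t%d\t%.6f\t%.6f\t%.6f\t%.6f",
                       grid$n_x, grid$n_y, grid$spacing_x, grid$spacing_y,
                       grid$origin[1], grid$origin[2]), con)
  writeLines(sprintf("# box\t%.6f\t%.6f\t%.6f",
                     topology$box[1], topology$box[2], topology$box[3]), con)
  writeLines(sprintf("# frame_interval_ps\t%.6f", frame_interval), con)
  fi <- topology$foulant_info
  if (!is.null(fi))
    writeLines(sprintf("# foulant\t%s\t%.6f\t%.6f", fi$orientation,
                       fi$charge_ratio[["negative"]], fi$initial_gap), con)
  a <- topology$atoms
  writeLines("serial\trole\tchain_id\tgroup_id\tanchored\tcharge\tdonor\tacceptor\ttacticity", con)
  writeLines(sprintf("%d\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s",
                     a$serial, a$role,
                     ifelse(is.na(a$chain_id), "NA", a$chain_id),
                     ifelse(is.na(a$group_id), "NA", a$group_id),
                     as.integer(a$anchored), a$charge,
                     as.integer(a$donor), as.integer(a$acceptor),
                     ifelse(is.na(a$tacticity), "NA", a$tacticity)), con)
}

#' Read a multi-model PDB trajectory and its annotation sidecar
#'
#' MODEL blocks become frames in order. Atoms whose serial has no row in
#' the annotation file get role `"other"`. Malformed coordinate fields
#' are reported with their line number; a frame whose atom count differs
#' from the first frame's is an error naming the frame.
#'
#' @param pdb_file Multi-model PDB path.
#' @param annotation_file Sidecar path (as written by
#'   [write_trajectory()]).
#' @return A list with `topology` and `trajectory`.
#' @export
read_trajectory <- function(pdb_file, annotation_file) {
  if (!file.exists(pdb_file)) stop("no such coordinate file: ", pdb_file)
  if (!file.exists(annotation_file))
    stop("no such annotation file: ", annotation_file)
  lines <- readLines(pdb_file)
  box <- c(100, 100, 100)
  cr <- grep("^CRYST1", lines)
  if (length(cr))
    box <- as.numeric(c(substr(lines[cr[1]], 7, 15),
                        substr(lines[cr[1]], 16, 24),
                        substr(lines[cr[1]], 25, 33)))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L)
    stop("zero MODEL blocks in ", pdb_file)
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records in ", pdb_file)
  frames <- vector("list", length(starts))
  serial0 <- NULL
  for (f in seq_along(starts)) {
    idx <- (starts[f] + 1L):(ends[f] - 1L)
    idx <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
    ln <- lines[idx]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    bad <- which(!stats::complete.cases(xyz))
    if (length(bad))
      stop("malformed coordinate fields at line(s) ",
           paste(idx[bad], collapse = ", "), " of ", pdb_file)
    serial <- as.integer(substr(ln, 7, 11))
    if (f == 1L) {
      serial0 <- serial
    } else if (length(serial) != length(serial0)) {
      stop(sprintf("frame %d: expected %d atoms, found %d",
                   f, length(serial0), length(serial)))
    }
    frames[[f]] <- xyz
  }
  ann <- read_annotation(annotation_file)
  atoms <- data.frame(serial = serial0, role = "other",
                      chain_id = NA_integer_, group_id = NA_character_,
                      anchored = FALSE, charge = 0L, donor = FALSE,
                      acceptor = FALSE, tacticity = NA_character_,
                      stringsAsFactors = FALSE)
  m <- match(serial0, ann$table$serial)
  hit <- !is.na(m)
  for (col in c("role", "chain_id", "group_id", "anchored", "charge",
                "donor", "acceptor", "tacticity"))
    atoms[[col]][hit] <- ann$table[[col]][m[hit]]
  if (!is.null(ann$box)) box <- ann$box
  coords <- array(unlist(frames), dim = c(length(serial0), 3,
                                          length(frames)))
  topo <- new_brush_topology(atoms, frames[[1]], grid = ann$grid,
                             box = box, foulant_info = ann$foulant_info)
  list(topology = topo,
       trajectory = new_brush_trajectory(coords, ann$frame_interval, box))
}

read_annotation <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  grid <- NULL; box <- NULL; frame_interval <- 10; foulant_info <- NULL
  for (h in hdr) {
    p <- strsplit(sub("^# ", "", h), "\t")[[1]]
    if (p[1] == "grid")
      grid <- new_grafting_grid(as.numeric(p[4]), as.numeric(p[5]),
                                as.integer(p[2]), as.integer(p[3]),
                                origin = as.numeric(p[6:7]))
    else if (p[1] == "box") box <- as.numeric(p[2:4])
    else if (p[1] == "frame_interval_ps") frame_interval <- as.numeric(p[2])
    else if (p[1] == "foulant")
      foulant_info <- list(orientation = p[2],
                           charge_ratio = c(positive = 1.0,
                                            negative = as.numeric(p[3])),
                           initial_gap = as.numeric(p[4]))
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           na.strings = "NA")
  tab$anchored <- as.logical(tab$anchored)
  tab$donor <- as.logical(tab$donor)
  tab$acceptor <- as.logical(tab$acceptor)
  tab$chain_id <- as.integer(tab$chain_id)
  list(table = tab, grid = grid, box = box,
       frame_interval = frame_interval, foulant_info = foulant_info)
}
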