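#' @importFrom stats coef cor predict rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

ROLE_LEVELS <- c("RECEPTOR", "LIGAND")

TOPOLOGY_COLUMNS <- c("serial", "name", "element", "residue_name", "residue_id",
                      "role", "mass", "charge", "lj_rmin_half", "lj_epsilon",
                      "vdw_radius")

#' Read a per-atom parameter sidecar table
#'
#' The sidecar carries the force-field-derived per-atom quantities that a PDB
#' file cannot: partial charge (elementary-charge units), Lennard-Jones
#' parameters in Rmin/2 (Angstrom) and epsilon (kcal/mol) form, mass (amu),
#' van der Waals radius (Angstrom) and the receptor/ligand role of every atom.
#' Roles come from this table, not from chain identifiers, because glycan
#' residue naming conventions vary between force fields.
#'
#' @param path Path to a CSV (or JSON array-of-objects) file with columns
#'   `serial`, `name`, `element`, `residue_name`, `residue_id`, `role`,
#'   `mass`, `charge`, `lj_rmin_half`, `lj_epsilon`, `vdw_radius`.
#' @return A data frame of validated atom records, one row per atom, ordered
#'   by `serial`.
#' @export
read_topology_sidecar <- function(path) {
  if (!file.exists(path)) stop("topology sidecar not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    atoms <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    atoms <- read.csv(path, stringsAsFactors = FALSE)
  }
  validate_atoms(atoms)
}

validate_atoms <- function(atoms) {
  if (nrow(atoms) == 0L) stop("no atoms in topology")
  missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(atoms))
  if (length(missing_cols))
    stop("topology missing column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, TOPOLOGY_COLUMNS]
  num_cols <- c("serial", "residue_id", "mass", "charge", "lj_rmin_half",
                "lj_epsilon", "vdw_radius")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(atoms[[cl]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", cl, " in topology at row ", bad[1L])
    atoms[[cl]] <- v
  }
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial(s): ",
         paste(head(unique(atoms$serial[duplicated(atoms$serial)]), 5L),
               collapse = ", "))
  bad_role <- setdiff(unique(atoms$role), ROLE_LEVELS)
  if (length(bad_role))
    stop("unknown role: ", paste(bad_role, collapse = ", "),
         " (expected RECEPTOR or LIGAND)")
  if (any(atoms$mass <= 0)) stop("non-positive mass in topology")
  if (any(atoms$vdw_radius <= 0)) stop("non-positive vdw_radius in topology")
  if (any(atoms$lj_rmin_half < 0) || any(atoms$lj_epsilon < 0))
    stop("negative Lennard-Jones parameter in topology")
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Read a multi-model PDB trajectory with its parameter sidecar
#'
#' One PDB `MODEL` is one trajectory frame; a file without `MODEL` records is
#' read as a single frame.  Coordinates are matched to sidecar atoms by order
#' after both are sorted by serial; every model must contain exactly the
#' sidecar's atom count.  Alternate locations keep the first-listed entry.
#'
#' @param path Multi-model PDB file (standard `MODEL`/`ENDMDL` records).
#' @param topology Sidecar path (see [read_topology_sidecar()]) or an
#'   already-validated atom data frame.
#' @param system_id Identifier stored on the trajectory.
#' @param metadata Optional named list (protein id, GAG type/length, pose).
#' @return A `gag_trajectory`: atoms data frame plus a list of n x 3
#'   coordinate matrices in Angstrom, one per frame.
#' @export
read_pdb_models <- function(path, topology, system_id = basename(path),
                            metadata = list()) {
  atoms <- if (is.character(topology)) read_topology_sidecar(topology)
           else validate_atoms(topology)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_start <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_of <- cumsum(model_start)
  if (!any(model_start)) model_of <- rep(1L, length(lines))
  model_of[!is_atom] <- NA_integer_
  atom_lines <- lines[is_atom]
  atom_model <- model_of[is_atom]
  atom_model[atom_model == 0L] <- 1L   # records before the first MODEL

  # drop non-first altlocs (column 17)
  altloc <- substr(atom_lines, 17, 17)
  keep <- altloc %in% c(" ", "A", "1", "")
  atom_lines <- atom_lines[keep]
  atom_model <- atom_model[keep]

  serial <- as.integer(substr(atom_lines, 7, 11))
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("unparseable coordinates in ", path)

  frames <- split(seq_along(atom_lines), atom_model)
  n_top <- nrow(atoms)
  coords <- vector("list", length(frames))
  model_ids <- as.integer(names(frames))
  for (i in seq_along(frames)) {
    idx <- frames[[i]]
    if (length(idx) != n_top)
      stop("model ", model_ids[i], " has ", length(idx),
           " atoms but topology has ", n_top)
    ord <- order(serial[idx])
    idx <- idx[ord]
    extra <- setdiff(serial[idx], atoms$serial)
    if (length(extra))
      stop("atom serial(s) in PDB absent from sidecar: ",
           paste(head(extra, 10L), collapse = ", "))
    coords[[i]] <- cbind(x = x[idx], y = y[idx], z = z[idx])
  }
  names(coords) <- NULL
  if (!any(grepl("^H", atoms$element)))
    warning("trajectory has no hydrogens; hydrogen-bond counts will be 0")
  new_trajectory(atoms, coords, system_id, metadata)
}

new_trajectory <- function(atoms, coords, system_id = "system",
                           metadata = list()) {
  stopifnot(length(coords) >= 1L)
  for (m in coords) stopifnot(is.matrix(m), nrow(m) == nrow(atoms), ncol(m) == 3L)
  structure(list(atoms = atoms, coords = coords, system_id = system_id,
                 metadata = metadata),
            class = "gag_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `gag_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame of a trajectory
#' @param traj A `gag_trajectory`.
#' @param i Frame number (1-based).
#' @return A `gag_frame` holding the shared atom table, this frame's
#'   coordinates and a 0-based `frame_index`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure(list(atoms = traj$atoms, coords = traj$coords[[i]],
                 frame_index = i - 1L),
            class = "gag_frame")
}

#' @export
print.gag_trajectory <- function(x, ...) {
  cat("gag_trajectory '", x$system_id, "': ", n_frames(x), " frame(s), ",
      nrow(x$atoms), " atoms (",
      sum(x$atoms$role == "RECEPTOR"), " receptor / ",
      sum(x$atoms$role == "LIGAND"), " ligand)\n", sep = "")
  invisible(x)
}

#' @export
print.gag_frame <- function(x, ...) {
  cat("gag_frame ", x$frame_index, ": ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a trajectory as multi-model PDB plus sidecar CSV
#'
#' Coordinates are written at the PDB's fixed 3-decimal precision; the sidecar
#' preserves all per-atom fields exactly, so a write/read round trip
#' reproduces the topology and coordinates to 1e-3 Angstrom.
#'
#' @param traj A `gag_trajectory`.
#' @param pdb_path,sidecar_path Output file paths.
#' @return Invisibly, the trajectory.
#' @export
write_pdb_models <- function(traj, pdb_path, sidecar_path = NULL) {
  a <- traj$atoms
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    m <- traj$coords[[i]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, substr(a$name, 1, 4), substr(a$residue_name, 1, 4),
      a$residue_id, m[, 1], m[, 2], m[, 3], substr(a$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(sidecar_path))
    write.csv(a, sidecar_path, row.names = FALSE, quote = FALSE)
  invisible(traj)
}

role_idx <- function(frame, role) which(frame$atoms$role == role)

is_hydrogen <- function(atoms) toupper(substr(trimws(atoms$element), 1, 1)) == "H"
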