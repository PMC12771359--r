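# In-code fixtures shared across test files.

# minimal atom table: one row per atom with sensible defaults
mk_atoms <- function(n, role = "RECEPTOR", element = "C",
                     residue_name = "ALA", residue_id = seq_len(n),
                     charge = 0, mass = 12.01, rmin = 1.908, eps = 0.1094,
                     vdw = 1.7, name = NULL) {
  data.frame(serial = seq_len(n),
             name = if (is.null(name)) paste0("A", seq_len(n)) else name,
             element = rep_len(element, n),
             residue_name = rep_len(residue_name, n),
             residue_id = rep_len(residue_id, n),
             role = rep_len(role, n),
             mass = rep_len(mass, n),
             charge = rep_len(charge, n),
             lj_rmin_half = rep_len(rmin, n),
             lj_epsilon = rep_len(eps, n),
             vdw_radius = rep_len(vdw, n),
             stringsAsFactors = FALSE)
}

mk_frame <- function(atoms, coords) {
  structure(list(atoms = atoms, coords = as.matrix(coords), frame_index = 0L),
            class = "gag_frame")
}

# two-role frame from separate receptor/ligand specifications
mk_complex_frame <- function(rec_coords, lig_coords, rec_args = list(),
                             lig_args = list()) {
  rec <- do.call(mk_atoms, c(list(n = nrow(rec_coords), role = "RECEPTOR"),
                             rec_args))
  lig <- do.call(mk_atoms, c(list(n = nrow(lig_coords), role = "LIGAND"),
                             lig_args))
  lig$serial <- lig$serial + nrow(rec)
  lig$residue_id <- lig$residue_id + 1000L
  mk_frame(rbind(rec, lig), rbind(rec_coords, lig_coords))
}

# small synthetic regression table with named feature columns
mk_table <- function(X, y, system_id = "s1", frame_index = NULL) {
  tab <- as.data.frame(X)
  tab$system_id <- system_id
  tab$frame_index <- if (is.null(frame_index)) seq_len(nrow(tab)) - 1L
                     else frame_index
  tab$mmgbsa_kcal_mol <- y
  attr(tab, "features") <- colnames(X)
  tab
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# varied toy-complex specifications used by oracle-equivalence checks
varied_toy_spec <- function(seed) {
  poses <- c("front", "back", "top", "bottom", "left", "right")
  toy_complex_spec(
    n_receptor_residues = 8 + seed %% 5,
    ligand_length = 2 + seed %% 7,
    unit_charge = c(-2, -1, -1.5)[1 + seed %% 3],
    pose = poses[1 + seed %% 6],
    com_offset = c(0.5, 1, 2, 4, 8)[1 + seed %% 5],
    n_frames = 1, seed = seed)
}
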