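#' Canonical descriptor names
#'
#' The fixed, ordered feature set computed per frame: formal charges, local
#' charged/polar residue counts at 5 and 10 Angstrom, ligand geometry
#' (end-to-end distance, radius of gyration), complex geometry (center-of-mass
#' distance, principal-axis orientation angle), interface contacts and
#' hydrogen bonds, solvent-accessible surface areas and the two linear
#' interaction energy components.
#' @export
CANONICAL_FEATURES <- c(
  "prot_charge", "gag_charge",
  "n_pos_5A", "n_neg_5A", "net_charge_5A", "net_charge_10A",
  "eed_gag", "radgyr_gag", "com_distance", "orientation_angle",
  "n_phobic_5A", "n_philic_5A", "polarity_5A",
  "n_phobic_10A", "n_philic_10A", "polarity_10A",
  "n_contacts_short", "n_contacts_medium",
  "n_hbonds_gag_donor", "n_hbonds_gag_acceptor",
  "sasa_prot", "sasa_gag", "sasa_complex",
  "lie_elec", "lie_vdw")

#' Descriptor configuration
#'
#' Cutoffs and residue classes used by all descriptors.  The defaults follow
#' common trajectory-analysis conventions: 3.5 / 5.0 Angstrom short/medium
#' contact thresholds, a 3.5 Angstrom donor-acceptor distance with a
#' 135-degree angle cutoff for hydrogen bonds, and 5 / 10 Angstrom
#' neighbourhood radii around the ligand.
#'
#' @param near_radii Two radii (Angstrom) for the residue-neighbourhood counts.
#' @param contact_short,contact_medium Heavy-atom contact cutoffs (Angstrom).
#' @param hbond_da_cutoff Donor-acceptor distance cutoff (Angstrom).
#' @param hbond_angle_cutoff Donor-H-acceptor angle cutoff (degrees).
#' @param positive_residues,negative_residues,hydrophobic_residues,hydrophilic_residues
#'   Residue-name classes; histidine is accepted under both HIS and HIE.
#' @param lie_cutoff Pair cutoff for linear interaction energies (Angstrom).
#' @param sasa_probe Probe radius (Angstrom), water-sized by default.
#' @param sasa_points Sphere lattice points per atom.
#' @param feature_set Ordered subset of [CANONICAL_FEATURES] to compute.
#' @return A `gag_descriptor_config` list.
#' @export
descriptor_config <- function(near_radii = c(5.0, 10.0),
                              contact_short = 3.5,
                              contact_medium = 5.0,
                              hbond_da_cutoff = 3.5,
                              hbond_angle_cutoff = 135,
                              positive_residues = c("LYS", "ARG", "HIS", "HIE"),
                              negative_residues = c("ASP", "GLU"),
                              hydrophobic_residues = c("ALA", "VAL", "LEU",
                                                       "ILE", "PHE", "TRP",
                                                       "MET", "TYR"),
                              hydrophilic_residues = c("SER", "THR", "ASN",
                                                       "GLN", "ASP", "GLU",
                                                       "LYS", "ARG", "HIS",
                                                       "HIE"),
                              lie_cutoff = 12.0,
                              sasa_probe = 1.4,
                              sasa_points = 960,
                              feature_set = CANONICAL_FEATURES) {
  stopifnot(contact_short <= contact_medium, all(near_radii > 0),
            !anyDuplicated(feature_set),
            all(feature_set %in% CANONICAL_FEATURES))
  structure(list(near_radii = near_radii, contact_short = contact_short,
                 contact_medium = contact_medium,
                 hbond_da_cutoff = hbond_da_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 positive_residues = positive_residues,
                 negative_residues = negative_residues,
                 hydrophobic_residues = hydrophobic_residues,
                 hydrophilic_residues = hydrophilic_residues,
                 lie_cutoff = lie_cutoff, sasa_probe = sasa_probe,
                 sasa_points = sasa_points, feature_set = feature_set),
            class = "gag_descriptor_config")
}

# squared cross-distance matrix between coordinate sets A (n x 3), B (m x 3)
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Sum of partial charges for one role
#'
#' @param frame A `gag_frame`.
#' @param role `"RECEPTOR"` or `"LIGAND"`.
#' @return Raw charge sum (elementary charges) with attribute `formal`, the
#'   nearest-integer formal charge used as the feature value.
#' @export
formal_charge <- function(frame, role) {
  idx <- role_idx(frame, role)
  if (!length(idx)) {
    warning("no atoms with role ", role)
    return(structure(0, formal = 0L))
  }
  s <- sum(frame$atoms$charge[idx])
  structure(s, formal = as.integer(round(s)))
}

#' Receptor residues near the ligand
#'
#' A residue is included if any of its atoms lies within `radius` of any
#' ligand atom (minimum atom-atom distance criterion).
#'
#' @param frame A `gag_frame`.
#' @param radius Neighbourhood radius in Angstrom.
#' @return Sorted integer vector of receptor `residue_id`s.
#' @export
residues_near_ligand <- function(frame, radius) {
  stopifnot(radius > 0)
  rec <- role_idx(frame, "RECEPTOR")
  lig <- role_idx(frame, "LIGAND")
  if (!length(rec) || !length(lig)) return(integer(0))
  d2 <- cross_dist2(frame$coords[rec, , drop = FALSE],
                    frame$coords[lig, , drop = FALSE])
  near_atom <- apply(d2, 1, min) <= radius^2
  sort(unique(frame$atoms$residue_id[rec][near_atom]))
}

residue_class_counts <- function(frame, radius, class_a, class_b) {
  ids <- residues_near_ligand(frame, radius)
  if (!length(ids)) return(c(0L, 0L))
  rec <- frame$atoms[frame$atoms$role == "RECEPTOR", ]
  rname <- toupper(rec$residue_name[match(ids, rec$residue_id)])
  c(sum(rname %in% class_a), sum(rname %in% class_b))
}

#' Charged-residue counts near the ligand
#' @inheritParams residues_near_ligand
#' @param config A [descriptor_config()].
#' @return Named vector `(n_pos, n_neg, net)` with `net = n_pos - n_neg`.
#' @export
charged_counts <- function(frame, radius, config = descriptor_config()) {
  ct <- residue_class_counts(frame, radius, toupper(config$positive_residues),
                             toupper(config$negative_residues))
  c(n_pos = ct[1], n_neg = ct[2], net = ct[1] - ct[2])
}

#' Hydrophobic/hydrophilic residue counts near the ligand
#' @inheritParams charged_counts
#' @return Named vector `(n_phobic, n_philic, polarity)` with
#'   `polarity = n_philic - n_phobic`.  Residues in neither class (e.g. GLY)
#'   contribute to neither count.
#' @export
polarity_counts <- function(frame, radius, config = descriptor_config()) {
  ct <- residue_class_counts(frame, radius,
                             toupper(config$hydrophobic_residues),
                             toupper(config$hydrophilic_residues))
  c(n_phobic = ct[1], n_philic = ct[2], polarity = ct[2] - ct[1])
}

ligand_anchor_idx <- function(frame) {
  lig <- role_idx(frame, "LIGAND")
  c(lig[1L], lig[length(lig)])
}

#' Ligand end-to-end distance
#'
#' Distance between the chain-order anchor atoms: by default the first atom of
#' the first ligand residue and the last atom of the last.
#'
#' @param frame A `gag_frame`.
#' @param anchors Optional length-2 vector of atom indices overriding the
#'   default anchors.
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(frame, anchors = NULL) {
  if (is.null(anchors)) anchors <- ligand_anchor_idx(frame)
  if (length(role_idx(frame, "LIGAND")) < 2L)
    stop("end-to-end distance needs a ligand with at least 2 atoms")
  sqrt(sum((frame$coords[anchors[1L], ] - frame$coords[anchors[2L], ])^2))
}

mass_com <- function(coords, mass) colSums(coords * mass) / sum(mass)

#' Mass-weighted radius of gyration of the ligand
#' @param frame A `gag_frame`.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame) {
  lig <- role_idx(frame, "LIGAND")
  m <- frame$atoms$mass[lig]
  if (sum(m) <= 0) stop("ligand has zero total mass")
  xyz <- frame$coords[lig, , drop = FALSE]
  com <- mass_com(xyz, m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' Center-of-mass distance between receptor and ligand
#' @param frame A `gag_frame`.
#' @return Distance in Angstrom.
#' @export
com_distance <- function(frame) {
  rec <- role_idx(frame, "RECEPTOR")
  lig <- role_idx(frame, "LIGAND")
  if (!length(rec) || !length(lig)) stop("empty receptor or ligand role")
  c1 <- mass_com(frame$coords[rec, , drop = FALSE], frame$atoms$mass[rec])
  c2 <- mass_com(frame$coords[lig, , drop = FALSE], frame$atoms$mass[lig])
  sqrt(sum((c1 - c2)^2))
}

principal_axis <- function(coords, mass) {
  com <- mass_com(coords, mass)
  X <- sweep(coords, 2, com)
  C <- crossprod(X * mass, X) / sum(mass)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[1L] < 1e-12) return(NULL)   # all atoms coincident
  ev$vectors[, 1L]
}

#' Angle between the principal axes of receptor and ligand
#'
#' The first principal axis of each role's mass-weighted coordinate
#' covariance; since axes are sign-ambiguous the angle is folded to
#' \[0, 90\] degrees.
#'
#' @param frame A `gag_frame`.
#' @return Angle in degrees, or `NA` for degenerate (coincident) geometry.
#' @export
orientation_angle <- function(frame) {
  rec <- role_idx(frame, "RECEPTOR")
  lig <- role_idx(frame, "LIGAND")
  if (length(rec) < 2L || length(lig) < 2L) return(NA_real_)
  a1 <- principal_axis(frame$coords[rec, , drop = FALSE], frame$atoms$mass[rec])
  a2 <- principal_axis(frame$coords[lig, , drop = FALSE], frame$atoms$mass[lig])
  if (is.null(a1) || is.null(a2)) return(NA_real_)
  cosang <- abs(sum(a1 * a2)) / sqrt(sum(a1^2) * sum(a2^2))
  acos(min(1, cosang)) * 180 / pi
}

#' Receptor-ligand heavy-atom contacts
#'
#' Counts unique (receptor heavy atom, ligand heavy atom) pairs within the
#' cutoff; hydrogens are excluded on both sides.
#'
#' @param frame A `gag_frame`.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Integer pair count.
#' @export
count_contacts <- function(frame, cutoff) {
  stopifnot(cutoff > 0)
  heavy <- !is_hydrogen(frame$atoms)
  rec <- which(frame$atoms$role == "RECEPTOR" & heavy)
  lig <- which(frame$atoms$role == "LIGAND" & heavy)
  if (!length(rec) || !length(lig)) return(0L)
  d2 <- cross_dist2(frame$coords[rec, , drop = FALSE],
                    frame$coords[lig, , drop = FALSE])
  sum(d2 <= cutoff^2)
}

# donors: N/O with a covalently bound hydrogen (H within 1.2 A, same role);
# returns list of (heavy index, h index) pairs
find_donors <- function(frame, idx) {
  elem <- toupper(trimws(frame$atoms$element[idx]))
  no <- idx[elem %in% c("N", "O")]
  hyd <- idx[is_hydrogen(frame$atoms)[idx]]
  if (!length(no) || !length(hyd)) return(NULL)
  d2 <- cross_dist2(frame$coords[no, , drop = FALSE],
                    frame$coords[hyd, , drop = FALSE])
  pairs <- which(d2 <= 1.2^2, arr.ind = TRUE)
  if (!nrow(pairs)) return(NULL)
  cbind(heavy = no[pairs[, 1]], h = hyd[pairs[, 2]])
}

find_acceptors <- function(frame, idx) {
  elem <- toupper(trimws(frame$atoms$element[idx]))
  idx[elem %in% c("N", "O")]
}

#' Interface hydrogen-bond count
#'
#' A hydrogen bond is a (donor, H, acceptor) triple with donor-acceptor
#' distance at most the cutoff and donor-H-acceptor angle at least the angle
#' cutoff.  Donors are N/O atoms with a bound hydrogen (H within 1.2
#' Angstrom); acceptors are N/O atoms on the opposite side.
#'
#' @param frame A `gag_frame`.
#' @param ligand_is_donor If `TRUE`, count ligand-donor to receptor-acceptor
#'   bonds; otherwise the reverse direction.
#' @param config A [descriptor_config()].
#' @return Integer count (0 with a warning when no hydrogens are present on
#'   the donor side).
#' @export
count_hbonds <- function(frame, ligand_is_donor,
                         config = descriptor_config()) {
  don_side <- role_idx(frame, if (ligand_is_donor) "LIGAND" else "RECEPTOR")
  acc_side <- role_idx(frame, if (ligand_is_donor) "RECEPTOR" else "LIGAND")
  if (!any(is_hydrogen(frame$atoms)[don_side])) {
    warning("no hydrogens on donor side; hydrogen-bond count is 0")
    return(0L)
  }
  donors <- find_donors(frame, don_side)
  acceptors <- find_acceptors(frame, acc_side)
  if (is.null(donors) || !length(acceptors)) return(0L)
  n <- 0L
  da2 <- cross_dist2(frame$coords[donors[, "heavy"], , drop = FALSE],
                     frame$coords[acceptors, , drop = FALSE])
  cand <- which(da2 <= config$hbond_da_cutoff^2, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  for (k in seq_len(nrow(cand))) {
    d <- frame$coords[donors[cand[k, 1], "heavy"], ]
    h <- frame$coords[donors[cand[k, 1], "h"], ]
    a <- frame$coords[acceptors[cand[k, 2]], ]
    v1 <- d - h
    v2 <- a - h
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(max(-1, min(1, cosang))) * 180 / pi
    if (ang >= config$hbond_angle_cutoff) n <- n + 1L
  }
  n
}

#' Compute the full descriptor vector for one frame
#'
#' Evaluates every feature in `config$feature_set` (geometry, neighbourhood
#' counts, contacts, hydrogen bonds, SASA, LIE).  Degenerate geometry yields
#' `NA` for the affected feature; rows with any `NA` are dropped before model
#' training.
#'
#' @param frame A `gag_frame`.
#' @param config A [descriptor_config()].
#' @return Named numeric vector over `config$feature_set`, with attribute
#'   `raw_charges` carrying the unrounded charge sums.
#' @export
compute_descriptors <- function(frame, config = descriptor_config()) {
  r1 <- config$near_radii[1L]
  r2 <- config$near_radii[2L]
  cc1 <- charged_counts(frame, r1, config)
  cc2 <- charged_counts(frame, r2, config)
  pc1 <- polarity_counts(frame, r1, config)
  pc2 <- polarity_counts(frame, r2, config)
  qp <- formal_charge(frame, "RECEPTOR")
  qg <- formal_charge(frame, "LIGAND")
  sasa <- sasa_triplet(frame, probe = config$sasa_probe,
                       n_points = config$sasa_points)
  lie <- lie_energy(frame, cutoff = config$lie_cutoff)
  all_feats <- c(
    prot_charge = as.numeric(attr(qp, "formal")),
    gag_charge = as.numeric(attr(qg, "formal")),
    n_pos_5A = unname(cc1["n_pos"]), n_neg_5A = unname(cc1["n_neg"]),
    net_charge_5A = unname(cc1["net"]), net_charge_10A = unname(cc2["net"]),
    eed_gag = end_to_end_distance(frame),
    radgyr_gag = radius_of_gyration(frame),
    com_distance = com_distance(frame),
    orientation_angle = orientation_angle(frame),
    n_phobic_5A = unname(pc1["n_phobic"]), n_philic_5A = unname(pc1["n_philic"]),
    polarity_5A = unname(pc1["polarity"]),
    n_phobic_10A = unname(pc2["n_phobic"]),
    n_philic_10A = unname(pc2["n_philic"]),
    polarity_10A = unname(pc2["polarity"]),
    n_contacts_short = as.numeric(count_contacts(frame, config$contact_short)),
    n_contacts_medium = as.numeric(count_contacts(frame, config$contact_medium)),
    n_hbonds_gag_donor = as.numeric(
      suppressWarnings(count_hbonds(frame, TRUE, config))),
    n_hbonds_gag_acceptor = as.numeric(
      suppressWarnings(count_hbonds(frame, FALSE, config))),
    sasa_prot = sasa[["sasa_prot"]], sasa_gag = sasa[["sasa_gag"]],
    sasa_complex = sasa[["sasa_complex"]],
    lie_elec = lie$elec, lie_vdw = lie$vdw)
  out <- all_feats[config$feature_set]
  attr(out, "raw_charges") <- c(prot = as.numeric(qp), gag = as.numeric(qg))
  out
}

#' Descriptor table for a whole trajectory
#'
#' @param traj A `gag_trajectory`.
#' @param config A [descriptor_config()].
#' @param target Optional numeric vector of per-frame MM-GBSA energies
#'   (kcal/mol) stored as `mmgbsa_kcal_mol`.
#' @return A data frame with metadata columns (`system_id`, `frame_index`,
#'   plus any trajectory metadata), one column per feature, and the optional
#'   target column.
#' @export
compute_feature_table <- function(traj, config = descriptor_config(),
                                  target = NULL) {
  n <- n_frames(traj)
  if (!is.null(target)) stopifnot(length(target) == n)
  rows <- lapply(seq_len(n), function(i)
    compute_descriptors(get_frame(traj, i), config))
  feat <- do.call(rbind, rows)
  meta <- data.frame(system_id = traj$system_id,
                     frame_index = seq_len(n) - 1L,
                     stringsAsFactors = FALSE)
  for (nm in names(traj$metadata)) meta[[nm]] <- traj$metadata[[nm]]
  out <- cbind(meta, as.data.frame(feat))
  if (!is.null(target)) out$mmgbsa_kcal_mol <- target
  attr(out, "features") <- config$feature_set
  out
}
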