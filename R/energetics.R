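#' Coulomb constant in kcal*Angstrom/(mol*e^2)
#' @keywords internal
COULOMB_K <- 332.0522

#' Pairwise linear interaction energy between receptor and ligand
#'
#' Raw receptor-ligand interaction energy summed over all atom pairs within
#' the cutoff: Coulomb term `k q_i q_j / r_ij` at dielectric 1, and a
#' Lennard-Jones term in Rmin/epsilon form,
#' `eps_ij [(R_ij/r)^12 - 2 (R_ij/r)^6]`, with `R_ij` the sum of the two
#' Rmin/2 values and `eps_ij` the geometric mean of the two epsilons
#' (Lorentz-Berthelot-style combining).  No periodic images, no switching:
#' receptor-ligand pairs are never bonded, so every pair inside the cutoff is
#' summed.
#'
#' @param frame A `gag_frame` with charges and Lennard-Jones parameters.
#' @param cutoff Pair-distance cutoff in Angstrom (default 12).
#' @return A list with `elec` and `vdw` (kcal/mol), `n_pairs_evaluated` and
#'   `cutoff`.
#' @export
lie_energy <- function(frame, cutoff = 12.0) {
  stopifnot(cutoff > 0)
  rec <- role_idx(frame, "RECEPTOR")
  lig <- role_idx(frame, "LIGAND")
  if (!length(rec) || !length(lig))
    return(list(elec = 0, vdw = 0, n_pairs_evaluated = 0L, cutoff = cutoff))
  a <- frame$atoms
  d2 <- cross_dist2(frame$coords[rec, , drop = FALSE],
                    frame$coords[lig, , drop = FALSE])
  sel <- d2 <= cutoff^2
  if (any(d2[sel] < 0.1^2))
    stop("atom pair closer than 0.1 Angstrom: clashed or corrupt geometry")
  r <- sqrt(d2[sel])
  qq <- tcrossprod(a$charge[rec], a$charge[lig])[sel]
  elec <- sum(COULOMB_K * qq / r)
  rmin <- outer(a$lj_rmin_half[rec], a$lj_rmin_half[lig], "+")[sel]
  eps <- sqrt(tcrossprod(a$lj_epsilon[rec], a$lj_epsilon[lig]))[sel]
  s6 <- (rmin / r)^6
  vdw <- sum(eps * (s6^2 - 2 * s6))
  list(elec = elec, vdw = vdw, n_pairs_evaluated = sum(sel), cutoff = cutoff)
}

# deterministic quasi-uniform unit-sphere lattice (golden spiral), no RNG
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For every atom, `n_points` lattice points are placed on the sphere of
#' radius `r_i + probe`; a point is accessible if it lies outside every other
#' atom's expanded sphere.  The per-atom area is the accessible fraction of
#' `4 pi (r_i + probe)^2`.  The point lattice is a deterministic golden
#' spiral, so results are bit-reproducible.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom), all positive.
#' @param probe Probe radius (Angstrom), default 1.4.
#' @param n_points Lattice points per atom (at least 50), default 960.
#' @return A list with `per_atom` areas, `total`, `probe_radius` and
#'   `n_sphere_points`.
#' @export
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L,
            length(radii) == nrow(coords), n_points >= 50)
  if (any(radii <= 0)) stop("non-positive atomic radius")
  n <- nrow(coords)
  expanded <- radii + probe
  pts <- sphere_lattice(n_points)
  per_atom <- numeric(n)
  # neighbour prefilter: only atoms whose expanded spheres can overlap
  d2 <- cross_dist2(coords, coords)
  rsum2 <- outer(expanded, expanded, "+")^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ])
    nb <- nb[nb != i]
    sph <- pts * expanded[i]
    sph <- sweep(sph, 2, coords[i, ], "+")
    if (length(nb)) {
      pd2 <- cross_dist2(sph, coords[nb, , drop = FALSE])
      buried <- rowSums(pd2 < matrix(expanded[nb]^2, n_points, length(nb),
                                     byrow = TRUE)) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    per_atom[i] <- acc / n_points * 4 * pi * expanded[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom), probe_radius = probe,
       n_sphere_points = n_points)
}

#' SASA of receptor, ligand and complex
#'
#' The receptor and ligand surfaces are computed on each role's atoms alone
#' (the partner removed); the complex surface on the union.  The difference
#' `sasa_prot + sasa_gag - sasa_complex` is the buried interface area.
#'
#' @param frame A `gag_frame`.
#' @param probe Probe radius (Angstrom).
#' @param n_points Lattice points per atom.
#' @return Named vector `(sasa_prot, sasa_gag, sasa_complex)` in Angstrom^2.
#' @export
sasa_triplet <- function(frame, probe = 1.4, n_points = 960) {
  rec <- role_idx(frame, "RECEPTOR")
  lig <- role_idx(frame, "LIGAND")
  r <- frame$atoms$vdw_radius
  c(sasa_prot = shrake_rupley(frame$coords[rec, , drop = FALSE], r[rec],
                              probe, n_points)$total,
    sasa_gag = shrake_rupley(frame$coords[lig, , drop = FALSE], r[lig],
                             probe, n_points)$total,
    sasa_complex = shrake_rupley(frame$coords, r, probe, n_points)$total)
}
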