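# Generators for test data with known ground truth: toy receptor-ligand
# complexes whose descriptors are recomputed by an independent brute-force
# oracle, and feature tables drawn from a specified covariance with a known
# feature-to-energy law.

toy_atom_params <- list(
  N = list(element = "N", mass = 14.01, vdw = 1.55, rmin = 1.824, eps = 0.17),
  C = list(element = "C", mass = 12.01, vdw = 1.70, rmin = 1.908, eps = 0.1094),
  O = list(element = "O", mass = 16.00, vdw = 1.52, rmin = 1.661, eps = 0.21),
  S = list(element = "S", mass = 32.06, vdw = 1.80, rmin = 2.000, eps = 0.25),
  H = list(element = "H", mass = 1.008, vdw = 1.20, rmin = 0.600, eps = 0.0157))

#' Specify a toy receptor-ligand complex
#'
#' A coil of four-atom amino-acid residues (N with an amide hydrogen, CA, C,
#' O) and a sulfated-oligosaccharide analogue: a chain of five-atom units
#' (ring carbon, ring oxygen, hydroxyl oxygen + hydrogen, sulfur) each
#' carrying `unit_charge` elementary charges.  Geometry is schematic — it
#' exists to exercise descriptor math, not to mimic a real fold.
#'
#' @param n_receptor_residues Number of receptor residues.
#' @param residue_names Residue-name sequence (recycled); defaults to a mix
#'   of charged, polar, hydrophobic and unclassified residues.
#' @param ligand_length Number of saccharide-analogue units (2-8).
#' @param unit_charge Charge per ligand unit (elementary charges).
#' @param pose Placement label, one of front/back/top/bottom/left/right.
#' @param com_offset Ligand offset from the receptor surface (Angstrom).
#' @param n_frames Frames to generate (coordinate jitter between frames).
#' @param jitter_sd Per-frame coordinate jitter (Angstrom).
#' @param seed Integer seed.
#' @return A `gag_toy_spec`.
#' @export
toy_complex_spec <- function(n_receptor_residues = 10,
                             residue_names = c("LYS", "ASP", "SER", "LEU",
                                               "GLY", "ARG", "GLU", "VAL",
                                               "HIE", "THR"),
                             ligand_length = 4, unit_charge = -2,
                             pose = "front", com_offset = 4,
                             n_frames = 1, jitter_sd = 0.15, seed = 1L) {
  stopifnot(n_receptor_residues >= 2, ligand_length >= 2, com_offset >= 0,
            pose %in% c("front", "back", "top", "bottom", "left", "right"))
  structure(list(n_receptor_residues = n_receptor_residues,
                 residue_names = rep_len(toupper(residue_names),
                                         n_receptor_residues),
                 ligand_length = ligand_length, unit_charge = unit_charge,
                 pose = pose, com_offset = com_offset, n_frames = n_frames,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "gag_toy_spec")
}

pose_direction <- function(pose) {
  switch(pose,
         front = c(0, 1, 0), back = c(0, -1, 0),
         top = c(0, 0, 1), bottom = c(0, 0, -1),
         left = c(-1, 0, 0), right = c(1, 0, 0))
}

toy_receptor_atoms <- function(spec) {
  rows <- list()
  serial <- 0L
  for (i in seq_len(spec$n_receptor_residues)) {
    # residue centers along a gentle arc in the xz plane
    t <- (i - 1) * 0.45
    ctr <- c(3.8 * (i - 1) * 0.9, 0, 2.5 * sin(t))
    offs <- list(N = c(-0.8, 0.4, 0.3), CA = c(0, 0, 0),
                 C = c(1.0, 0.3, -0.2), O = c(1.4, 1.2, -0.4),
                 HN = c(-1.2, 1.2, 0.5))
    kinds <- c(N = "N", CA = "C", C = "C", O = "O", HN = "H")
    # small per-atom charges that sum to the residue class charge
    resq <- 0
    nm <- spec$residue_names[i]
    if (nm %in% c("LYS", "ARG", "HIE", "HIS")) resq <- 1
    if (nm %in% c("ASP", "GLU")) resq <- -1
    qs <- c(N = -0.4, CA = 0.1, C = 0.5, O = -0.5, HN = 0.3)
    qs["CA"] <- qs["CA"] + resq
    for (an in names(offs)) {
      serial <- serial + 1L
      p <- toy_atom_params[[kinds[[an]]]]
      rows[[serial]] <- data.frame(
        serial = serial, name = an, element = p$element, residue_name = nm,
        residue_id = i, role = "RECEPTOR", mass = p$mass, charge = qs[[an]],
        lj_rmin_half = p$rmin, lj_epsilon = p$eps, vdw_radius = p$vdw,
        x = ctr[1] + offs[[an]][1], y = ctr[2] + offs[[an]][2],
        z = ctr[3] + offs[[an]][3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

toy_ligand_atoms <- function(spec, surface_y) {
  rows <- list()
  serial <- 0L
  dirv <- pose_direction(spec$pose)
  base <- c(1.9 * spec$n_receptor_residues, 0, 0) * 0.5 +
    dirv * (surface_y + spec$com_offset)
  along <- if (abs(dirv[1]) > 0.5) c(0, 1, 0) else c(1, 0, 0)
  for (u in seq_len(spec$ligand_length)) {
    ctr <- base + along * 4.6 * (u - 1) + c(0, 0, 0.8 * ((u %% 2) * 2 - 1))
    # hydroxyl hydrogen points back toward the receptor surface so close
    # poses can form ligand-donor hydrogen bonds
    offs <- list(C1 = c(0, 0, 0), O5 = c(1.2, 0.5, 0.3),
                 O3 = c(-1.1, -0.6, -0.4), HO3 = c(-1.1, -1.55, -0.4),
                 S1 = c(0.4, -1.4, 0.9))
    kinds <- c(C1 = "C", O5 = "O", O3 = "O", HO3 = "H", S1 = "S")
    qs <- c(C1 = 0.2, O5 = -0.4, O3 = -0.5, HO3 = 0.35,
            S1 = spec$unit_charge + 0.35)
    for (an in names(offs)) {
      serial <- serial + 1L
      p <- toy_atom_params[[kinds[[an]]]]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = an, element = p$element,
        residue_name = "SGU", residue_id = 1000L + u, role = "LIGAND",
        mass = p$mass, charge = qs[[an]], lj_rmin_half = p$rmin,
        lj_epsilon = p$eps, vdw_radius = p$vdw,
        x = ctr[1] + offs[[an]][1], y = ctr[2] + offs[[an]][2],
        z = ctr[3] + offs[[an]][3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a toy complex with oracle descriptor values
#'
#' Builds the structure deterministically for a fixed seed, then computes
#' every descriptor for every frame with [oracle_descriptors()] — an
#' independent brute-force implementation (explicit pair loops, per-point
#' surface checks) that shares no code with the production descriptor path.
#' Frames whose jitter produces a receptor-ligand clash (pair under 0.8
#' Angstrom) are re-jittered, erroring after 100 attempts.
#'
#' @param spec A [toy_complex_spec()].
#' @param config A [descriptor_config()] used for the oracle's cutoffs.
#' @return List with `trajectory`, per-frame `oracle` descriptor vectors and
#'   `ground_truth` (ligand/receptor charge sums and the spec).
#' @export
gen_toy_complex <- function(spec, config = descriptor_config()) {
  stopifnot(inherits(spec, "gag_toy_spec"))
  rec <- toy_receptor_atoms(spec)
  lig <- toy_ligand_atoms(spec, surface_y = max(rec$y) + 1.2)
  lig$serial <- lig$serial + nrow(rec)
  atoms <- rbind(rec, lig)
  base_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  atoms <- atoms[, TOPOLOGY_COLUMNS]
  coords <- local_seed(spec$seed, lapply(seq_len(spec$n_frames), function(i) {
    if (i == 1L) return(base_xyz)
    for (attempt in 1:100) {
      xyz <- base_xyz + matrix(rnorm(length(base_xyz), sd = spec$jitter_sd),
                               nrow(base_xyz), 3)
      dmin <- min_cross_distance(xyz[atoms$role == "RECEPTOR", , drop = FALSE],
                                 xyz[atoms$role == "LIGAND", , drop = FALSE])
      if (dmin > 0.8) return(xyz)
    }
    stop("could not place frame ", i, " without a clash after 100 attempts")
  }))
  traj <- new_trajectory(atoms, coords,
                         system_id = paste0("toy_", spec$pose, "_",
                                            spec$seed),
                         metadata = list(protein_id = "toy",
                                         gag_type = "SGU",
                                         gag_length = spec$ligand_length,
                                         pose = spec$pose))
  oracle <- lapply(seq_len(spec$n_frames), function(i)
    oracle_descriptors(get_frame(traj, i), config))
  list(trajectory = traj, oracle = oracle,
       ground_truth = list(
         gag_charge = spec$ligand_length * spec$unit_charge,
         gag_charge_sum = sum(atoms$charge[atoms$role == "LIGAND"]),
         prot_charge_sum = sum(atoms$charge[atoms$role == "RECEPTOR"]),
         spec = spec))
}

min_cross_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                (B[, 3] - A[i, 3])^2)
    best <- min(best, min(d))
  }
  best
}

# ---- brute-force oracle ----------------------------------------------------
# Every quantity below is recomputed with explicit loops and direct formulas,
# independently of the descriptors/energetics modules, so agreement between
# the two paths is a meaningful check.

oracle_near_residues <- function(frame, radius) {
  a <- frame$atoms
  xyz <- frame$coords
  near <- integer(0)
  for (rid in unique(a$residue_id[a$role == "RECEPTOR"])) {
    ridx <- which(a$residue_id == rid & a$role == "RECEPTOR")
    found <- FALSE
    for (i in ridx) {
      for (j in which(a$role == "LIGAND")) {
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= radius) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) near <- c(near, rid)
  }
  sort(near)
}

oracle_class_count <- function(frame, ids, classes) {
  a <- frame$atoms
  n <- 0L
  for (rid in ids) {
    nm <- toupper(a$residue_name[a$residue_id == rid & a$role == "RECEPTOR"][1])
    if (nm %in% classes) n <- n + 1L
  }
  n
}

oracle_sasa <- function(xyz, radii, probe, n_points) {
  pts <- sphere_lattice(n_points)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    ri <- radii[i] + probe
    acc <- 0L
    for (k in seq_len(n_points)) {
      p <- xyz[i, ] + pts[k, ] * ri
      free <- TRUE
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        if (sum((p - xyz[j, ])^2) < (radii[j] + probe)^2) {
          free <- FALSE
          break
        }
      }
      if (free) acc <- acc + 1L
    }
    total <- total + acc / n_points * 4 * pi * ri^2
  }
  total
}

#' Brute-force descriptor oracle
#'
#' Recomputes the full canonical descriptor vector for one frame with
#' explicit all-pairs loops and direct formulas.  Intended for validating
#' [compute_descriptors()] on small (toy) complexes; quadratic or worse in
#' atom count.
#'
#' @param frame A `gag_frame`.
#' @param config A [descriptor_config()].
#' @return Named numeric vector over [CANONICAL_FEATURES].
#' @export
oracle_descriptors <- function(frame, config = descriptor_config()) {
  a <- frame$atoms
  xyz <- frame$coords
  rec <- which(a$role == "RECEPTOR")
  lig <- which(a$role == "LIGAND")

  qsum <- function(idx) sum(a$charge[idx])
  r1 <- config$near_radii[1]
  r2 <- config$near_radii[2]
  near1 <- oracle_near_residues(frame, r1)
  near2 <- oracle_near_residues(frame, r2)
  np1 <- oracle_class_count(frame, near1, toupper(config$positive_residues))
  nn1 <- oracle_class_count(frame, near1, toupper(config$negative_residues))
  np2 <- oracle_class_count(frame, near2, toupper(config$positive_residues))
  nn2 <- oracle_class_count(frame, near2, toupper(config$negative_residues))
  phob1 <- oracle_class_count(frame, near1, toupper(config$hydrophobic_residues))
  phil1 <- oracle_class_count(frame, near1, toupper(config$hydrophilic_residues))
  phob2 <- oracle_class_count(frame, near2, toupper(config$hydrophobic_residues))
  phil2 <- oracle_class_count(frame, near2, toupper(config$hydrophilic_residues))

  eed <- sqrt(sum((xyz[lig[1], ] - xyz[lig[length(lig)], ])^2))

  com <- function(idx) {
    s <- c(0, 0, 0)
    for (i in idx) s <- s + a$mass[i] * xyz[i, ]
    s / sum(a$mass[idx])
  }
  cl <- com(lig)
  rg2 <- 0
  for (i in lig) rg2 <- rg2 + a$mass[i] * sum((xyz[i, ] - cl)^2)
  radgyr <- sqrt(rg2 / sum(a$mass[lig]))
  comd <- sqrt(sum((com(rec) - cl)^2))

  axis_of <- function(idx) {
    c0 <- com(idx)
    C <- matrix(0, 3, 3)
    for (i in idx) {
      v <- xyz[i, ] - c0
      C <- C + a$mass[i] * tcrossprod(v)
    }
    eigen(C / sum(a$mass[idx]), symmetric = TRUE)$vectors[, 1]
  }
  ax1 <- axis_of(rec)
  ax2 <- axis_of(lig)
  ang <- acos(min(1, abs(sum(ax1 * ax2)))) * 180 / pi

  heavy <- !is_hydrogen(a)
  n_short <- 0L
  n_med <- 0L
  for (i in rec[heavy[rec]]) for (j in lig[heavy[lig]]) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= config$contact_short) n_short <- n_short + 1L
    if (d <= config$contact_medium) n_med <- n_med + 1L
  }

  count_hb <- function(don_idx, acc_idx) {
    n <- 0L
    elems <- toupper(trimws(a$element))
    for (d in don_idx[elems[don_idx] %in% c("N", "O")]) {
      for (h in don_idx[is_hydrogen(a)[don_idx]]) {
        if (sqrt(sum((xyz[d, ] - xyz[h, ])^2)) > 1.2) next
        for (acc in acc_idx[elems[acc_idx] %in% c("N", "O")]) {
          da <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
          if (da > config$hbond_da_cutoff) next
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[acc, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          if (acos(max(-1, min(1, cosang))) * 180 / pi >=
                config$hbond_angle_cutoff)
            n <- n + 1L
        }
      }
    }
    n
  }

  elec <- 0
  vdw <- 0
  for (i in rec) for (j in lig) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > config$lie_cutoff) next
    elec <- elec + COULOMB_K * a$charge[i] * a$charge[j] / r
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }

  c(prot_charge = round(qsum(rec)), gag_charge = round(qsum(lig)),
    n_pos_5A = np1, n_neg_5A = nn1, net_charge_5A = np1 - nn1,
    net_charge_10A = np2 - nn2,
    eed_gag = eed, radgyr_gag = radgyr, com_distance = comd,
    orientation_angle = ang,
    n_phobic_5A = phob1, n_philic_5A = phil1, polarity_5A = phil1 - phob1,
    n_phobic_10A = phob2, n_philic_10A = phil2,
    polarity_10A = phil2 - phob2,
    n_contacts_short = n_short, n_contacts_medium = n_med,
    n_hbonds_gag_donor = count_hb(lig, rec),
    n_hbonds_gag_acceptor = count_hb(rec, lig),
    sasa_prot = oracle_sasa(xyz[rec, , drop = FALSE], a$vdw_radius[rec],
                            config$sasa_probe, config$sasa_points),
    sasa_gag = oracle_sasa(xyz[lig, , drop = FALSE], a$vdw_radius[lig],
                           config$sasa_probe, config$sasa_points),
    sasa_complex = oracle_sasa(xyz, a$vdw_radius, config$sasa_probe,
                               config$sasa_points),
    lie_elec = elec, lie_vdw = vdw)
}

# ---- synthetic feature tables ----------------------------------------------

#' Specify a synthetic feature table
#'
#' Features are drawn from a multivariate normal with the given correlation
#' matrix (Cholesky construction) in standardized latent units, then mapped
#' to display units by `feature_means + feature_scales * z`.  The target is
#' `intercept + w . z + interaction terms + noise`: Gaussian noise of
#' marginal standard deviation `noise_sd`, optionally AR(1)-correlated along
#' frames within a trajectory, plus an independent per-trajectory offset.
#' The attainable R-squared ceiling, Var(signal) / (Var(signal) + Var(noise)),
#' follows in closed form from the covariance (Isserlis' theorem for the
#' interaction terms).
#'
#' With a `proxy` specification the generator instead emulates how an
#' energetic descriptor relates to the energy it approximates: the weights
#' and interactions define a structural signal core, one feature (e.g.
#' `lie_elec`) is overwritten with `lambda * core + sqrt(1 - lambda^2) * eta`
#' (unit variance, correlation `lambda` with the standardized core), and the
#' target becomes `scale * core + unique_weight * eta + noise` — so the proxy
#' column carries both a redundant readout of the core (including its
#' non-linear part, which linear models cannot otherwise reach) and a unique
#' signal component `eta` lost by every model when the column is removed.
#'
#' @param n_rows Number of rows.
#' @param features Feature names.
#' @param correlation Feature correlation matrix (default identity).
#' @param weights Linear weights on the standardized latent features.
#' @param interactions List of `list(f1, f2, coef)` product terms.
#' @param proxy `NULL`, or `list(feature, lambda, scale, unique_weight)` as
#'   described above; `weights`/`interactions` must not load on the proxy
#'   feature.
#' @param noise_sd Marginal noise standard deviation (kcal/mol).
#' @param intercept Target offset (kcal/mol).
#' @param feature_means,feature_scales Affine display transform per feature.
#' @param groups Development group labels cycled over trajectories.
#' @param validation_group Label of the held-out group; `validation_fraction`
#'   of trajectories belong to it.
#' @param validation_shift Named vector of latent-unit mean shifts applied to
#'   the validation group's features (a controlled distribution shift).
#' @param validation_fraction Fraction of trajectories in the held-out group.
#' @param frames_per_traj Frames per trajectory (1 = independent rows).
#' @param traj_feature_frac Fraction of each feature's variance placed at the
#'   trajectory level (a shared per-trajectory offset drawn from the same
#'   correlation structure), mimicking systematic descriptor differences
#'   between complexes; 0 gives independent rows.
#' @param ar1 AR(1) coefficient of the within-trajectory noise.
#' @param traj_offset_sd Standard deviation of the per-trajectory offset.
#' @param first_frame_drift Systematic offset added to each trajectory's
#'   frame-0 target (single-structure bias).
#' @param seed Integer seed.
#' @return A `gag_table_spec`.
#' @export
table_spec <- function(n_rows, features, correlation = NULL,
                       weights = NULL, interactions = list(),
                       proxy = NULL, noise_sd = 1, intercept = 0,
                       feature_means = 0, feature_scales = 1,
                       groups = "dev", validation_group = NULL,
                       validation_shift = NULL, validation_fraction = 0.2,
                       frames_per_traj = 1L, traj_feature_frac = 0,
                       ar1 = 0, traj_offset_sd = 0,
                       first_frame_drift = 0, seed = 1L) {
  p <- length(features)
  if (is.null(correlation)) correlation <- diag(p)
  if (is.null(weights)) weights <- rep(0, p)
  stopifnot(nrow(correlation) == p, length(weights) == p,
            ar1 >= 0, ar1 < 1, noise_sd >= 0,
            traj_feature_frac >= 0, traj_feature_frac < 1)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix not positive semi-definite; smallest eigenvalue ",
         format(min(ev)))
  if (!is.null(proxy)) {
    stopifnot(proxy$feature %in% features,
              proxy$lambda >= 0, proxy$lambda <= 1)
    pidx <- match(proxy$feature, features)
    if (weights[pidx] != 0 ||
        any(vapply(interactions, function(t)
          proxy$feature %in% c(t[[1]], t[[2]]), logical(1))))
      stop("weights/interactions must not load on the proxy feature")
  }
  structure(list(n_rows = n_rows, features = features,
                 correlation = correlation,
                 weights = setNames(weights, features),
                 interactions = interactions, proxy = proxy,
                 noise_sd = noise_sd,
                 intercept = intercept,
                 feature_means = rep_len(feature_means, p),
                 feature_scales = rep_len(feature_scales, p),
                 groups = groups, validation_group = validation_group,
                 validation_shift = validation_shift,
                 validation_fraction = validation_fraction,
                 frames_per_traj = as.integer(frames_per_traj),
                 traj_feature_frac = traj_feature_frac, ar1 = ar1,
                 traj_offset_sd = traj_offset_sd,
                 first_frame_drift = first_frame_drift,
                 seed = as.integer(seed)),
            class = "gag_table_spec")
}

#' Closed-form signal variance of a table spec
#' @param spec A [table_spec()].
#' @return Variance of the noise-free target over the unshifted population.
#' @export
signal_variance <- function(spec) {
  if (!is.null(spec$proxy))
    return(spec$proxy$scale^2 + spec$proxy$unique_weight^2)
  core_variance(spec)
}

# variance of the raw weighted core (linear + interaction terms)
core_variance <- function(spec) {
  S <- spec$correlation
  w <- unname(spec$weights)
  v <- drop(t(w) %*% S %*% w)
  ia <- spec$interactions
  if (length(ia)) {
    idx <- lapply(ia, function(t)
      c(match(t[[1]], spec$features), match(t[[2]], spec$features)))
    cf <- vapply(ia, function(t) t[[3]], numeric(1))
    for (s in seq_along(ia)) for (t in seq_along(ia)) {
      i <- idx[[s]][1]; j <- idx[[s]][2]
      k <- idx[[t]][1]; l <- idx[[t]][2]
      # Isserlis: Cov(x_i x_j, x_k x_l) = S_ik S_jl + S_il S_jk
      v <- v + cf[s] * cf[t] * (S[i, k] * S[j, l] + S[i, l] * S[j, k])
    }
  }
  v
}

#' Attainable R-squared ceiling of a table spec
#' @param spec A [table_spec()].
#' @return `Var(signal) / (Var(signal) + Var(noise))` with the noise variance
#'   including the per-trajectory offset.
#' @export
r2_ceiling <- function(spec) {
  vs <- signal_variance(spec)
  vn <- spec$noise_sd^2 + spec$traj_offset_sd^2
  vs / (vs + vn)
}

#' Generate a synthetic feature table
#'
#' @param spec A [table_spec()].
#' @return List with `table` (metadata + features + `mmgbsa_kcal_mol`) and
#'   `truth` (latent weights, display-unit weights, noise, ceiling R-squared,
#'   and the spec itself).
#' @export
gen_feature_table <- function(spec) {
  stopifnot(inherits(spec, "gag_table_spec"))
  p <- length(spec$features)
  n <- spec$n_rows
  fp <- max(1L, spec$frames_per_traj)
  n_traj <- ceiling(n / fp)
  local_seed(spec$seed, {
    ch <- chol(spec$correlation)
    Z <- matrix(rnorm(n * p), n, p) %*% ch
    traj_of <- rep(seq_len(n_traj), each = fp)[seq_len(n)]
    frame_of <- (seq_len(n) - 1L) %% fp
    if (spec$traj_feature_frac > 0) {
      Ztraj <- matrix(rnorm(n_traj * p), n_traj, p) %*% ch
      Z <- sqrt(spec$traj_feature_frac) * Ztraj[traj_of, , drop = FALSE] +
        sqrt(1 - spec$traj_feature_frac) * Z
    }
    colnames(Z) <- spec$features

    n_val_traj <- if (is.null(spec$validation_group)) 0L
                  else max(1L, round(spec$validation_fraction * n_traj))
    val_traj <- if (n_val_traj) seq_len(n_val_traj) + (n_traj - n_val_traj)
                else integer(0)
    group_of_traj <- rep_len(spec$groups, n_traj)
    group_of_traj[val_traj] <- spec$validation_group
    is_val <- traj_of %in% val_traj
    if (!is.null(spec$validation_shift) && any(is_val)) {
      for (f in names(spec$validation_shift))
        Z[is_val, f] <- Z[is_val, f] + spec$validation_shift[[f]]
    }

    core <- drop(Z %*% unname(spec$weights))
    for (t in spec$interactions)
      core <- core + t[[3]] * Z[, t[[1]]] * Z[, t[[2]]]
    if (is.null(spec$proxy)) {
      signal <- spec$intercept + core
    } else {
      core <- core / sqrt(core_variance(spec))
      eta <- rnorm(n)
      Z[, spec$proxy$feature] <- spec$proxy$lambda * core +
        sqrt(1 - spec$proxy$lambda^2) * eta
      signal <- spec$intercept + spec$proxy$scale * core +
        spec$proxy$unique_weight * eta
    }

    eps <- rnorm(n, sd = spec$noise_sd)
    if (spec$ar1 > 0 && fp > 1L) {
      for (i in seq_len(n)) {
        if (frame_of[i] > 0L)
          eps[i] <- spec$ar1 * eps[i - 1L] +
            sqrt(1 - spec$ar1^2) * eps[i]
      }
    }
    offsets <- rnorm(n_traj, sd = spec$traj_offset_sd)
    y <- signal + eps + offsets[traj_of]
    if (spec$first_frame_drift != 0)
      y[frame_of == 0L] <- y[frame_of == 0L] + spec$first_frame_drift

    X <- sweep(sweep(Z, 2, spec$feature_scales, "*"), 2,
               spec$feature_means, "+")
    tab <- data.frame(system_id = sprintf("traj%04d", traj_of),
                      protein_id = group_of_traj[traj_of],
                      gag_type = "synthetic", gag_length = 6L,
                      pose = "front", frame_index = frame_of,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(X))
    tab$mmgbsa_kcal_mol <- y
    tab <- set_features(tab, spec$features)
    proxy_corr <- if (is.null(spec$proxy)) NULL else {
      vy <- signal_variance(spec) + spec$noise_sd^2 + spec$traj_offset_sd^2
      (spec$proxy$lambda * spec$proxy$scale +
         sqrt(1 - spec$proxy$lambda^2) * spec$proxy$unique_weight) / sqrt(vy)
    }
    list(table = tab,
         truth = list(latent_weights = spec$weights,
                      display_weights = spec$weights / spec$feature_scales,
                      noise_sd = spec$noise_sd,
                      signal_variance = signal_variance(spec),
                      r2_ceiling = r2_ceiling(spec),
                      proxy_target_corr = proxy_corr,
                      validation_group = spec$validation_group,
                      spec = spec))
  })
}

#' Correlation-block structure of the study-like preset
#' @keywords internal
paperlike_blocks <- list(
  electrostatic = c("lie_elec", "prot_charge", "gag_charge", "n_pos_5A",
                    "n_neg_5A", "net_charge_5A", "net_charge_10A",
                    "n_hbonds_gag_donor", "n_hbonds_gag_acceptor"),
  interface = c("lie_vdw", "n_contacts_short", "n_contacts_medium",
                "sasa_prot", "sasa_gag", "sasa_complex", "n_phobic_5A",
                "n_philic_5A", "polarity_5A", "n_phobic_10A",
                "n_philic_10A", "polarity_10A"),
  geometry = c("eed_gag", "radgyr_gag", "com_distance",
               "orientation_angle"))

#' Study-like synthetic table specification
#'
#' Encodes the qualitative statistical structure of real
#' protein-glycosaminoglycan descriptor data: three correlated descriptor
#' blocks (electrostatic, interface, geometry; within-block correlation 0.6,
#' 0.1 across blocks, 0.9 between the two contact counts); a structural
#' energy core built from contacts, receptor-donor hydrogen bonds, local net
#' charge, surface area and the van der Waals interaction energy, with mild
#' interaction terms that only non-linear models can exploit; `lie_elec`
#' constructed as a high-correlation proxy of that core plus a unique
#' energetic component — as physically expected, the electrostatic
#' interaction energy is largely a readout of the binding energy itself
#' (target correlation about 0.85), and linear models can reach the core's
#' non-linear part only through it; time-correlated trajectory noise; and a
#' mean-shifted held-out
#' group mimicking an unseen receptor subtype.  Sign conventions follow the
#' correlation pattern seen in such data (electrostatic energy positively,
#' contact counts negatively correlated with the binding energy); magnitudes
#' are not calibrated to any particular dataset.
#'
#' @param n_rows Number of rows.
#' @param seed Integer seed.
#' @param frames_per_traj Frames per trajectory.
#' @return A [table_spec()].
#' @export
table_spec_paperlike <- function(n_rows = 20000, seed = 1L,
                                 frames_per_traj = 50L) {
  feats <- CANONICAL_FEATURES
  p <- length(feats)
  R <- diag(p) * 0 + 0.1
  for (b in paperlike_blocks) {
    idx <- match(b, feats)
    R[idx, idx] <- 0.6
  }
  ij <- match(c("n_contacts_short", "n_contacts_medium"), feats)
  R[ij, ij] <- 0.9
  diag(R) <- 1
  # nudge to the nearest positive-definite correlation if slightly off
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
  }
  w <- setNames(rep(0, p), feats)
  w["lie_vdw"] <- 1.5
  w["n_contacts_short"] <- -2
  w["n_hbonds_gag_acceptor"] <- -1.5   # receptor acts as the donor
  w["net_charge_5A"] <- -1
  w["prot_charge"] <- -1
  w["sasa_gag"] <- 0.8
  table_spec(n_rows = n_rows, features = feats, correlation = R,
             weights = unname(w),
             interactions = list(list("n_contacts_short", "sasa_gag", 1.2),
                                 list("gag_charge", "n_contacts_short", -1.0)),
             proxy = list(feature = "lie_elec", lambda = 0.85, scale = 7,
                          unique_weight = 2.5),
             noise_sd = 4, intercept = -30,
             groups = c("catK", "catL", "catV"),
             validation_group = "catS",
             validation_shift = c(prot_charge = 0.8, sasa_prot = 0.6,
                                  gag_charge = -0.5),
             validation_fraction = 0.2,
             frames_per_traj = frames_per_traj, traj_feature_frac = 0.5,
             ar1 = 0.5, traj_offset_sd = 1, seed = seed)
}
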