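# Kabsch least-squares superposition: rotation+translation moving `mobile`
# onto `ref` (both n x 3), minimising RMSD of the fit atoms
kabsch_fit <- function(ref, mobile) {
  cr <- colMeans(ref)
  cm <- colMeans(mobile)
  H <- crossprod(sweep(mobile, 2, cm), sweep(ref, 2, cr))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, center_mobile = cm, center_ref = cr)
}

apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_mobile) %*% t(fit$R), 2,
        fit$center_ref, "+")
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Ligand RMSD vs the first frame
#'
#' Each frame is superposed on the reference frame using the receptor atoms
#' (least-squares fit), then the ligand RMSD against the reference ligand is
#' taken without further fitting — so the profile captures both internal
#' ligand motion and sliding over the receptor surface.
#'
#' @param traj A `gag_trajectory`.
#' @param reference Reference frame number (default 1).
#' @return Numeric vector of per-frame RMSD (Angstrom), first value 0.
#' @export
ligand_rmsd <- function(traj, reference = 1L) {
  rec <- which(traj$atoms$role == "RECEPTOR")
  lig <- which(traj$atoms$role == "LIGAND")
  ref <- traj$coords[[reference]]
  vapply(seq_len(n_frames(traj)), function(i) {
    fit <- kabsch_fit(ref[rec, , drop = FALSE],
                      traj$coords[[i]][rec, , drop = FALSE])
    moved <- apply_fit(traj$coords[[i]], fit)
    rmsd_of(moved[lig, , drop = FALSE], ref[lig, , drop = FALSE])
  }, numeric(1))
}

#' Mean and spread of ligand RMSD across trajectories
#'
#' Computes [ligand_rmsd()] per trajectory and aggregates per frame index
#' across trajectories (population standard deviation).  Trajectories of
#' unequal length are truncated to the shortest with a warning.
#'
#' @param traj_set List of `gag_trajectory` objects.
#' @param reference Reference frame number used in each trajectory.
#' @return Data frame with `frame_index` (0-based), `mean_rmsd`, `sd_rmsd`.
#' @export
rmsd_profile <- function(traj_set, reference = 1L) {
  stopifnot(length(traj_set) >= 1L)
  lens <- vapply(traj_set, n_frames, integer(1))
  n <- min(lens)
  if (any(lens != n))
    warning("trajectories of unequal length; truncating to ", n, " frames")
  prof <- vapply(traj_set, function(tr) ligand_rmsd(tr, reference)[seq_len(n)],
                 numeric(n))
  prof <- matrix(prof, nrow = n)
  data.frame(frame_index = seq_len(n) - 1L,
             mean_rmsd = rowMeans(prof),
             sd_rmsd = apply(prof, 1, function(v)
               sqrt(mean((v - mean(v))^2))))
}
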