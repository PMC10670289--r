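# Least-squares rigid-body superposition and ensemble fluctuation statistics.

.coords_of <- function(x) {
  if (inherits(x, "md_structure")) x$xyz
  else if (inherits(x, "md_trajectory")) x$coords[, , 1L, drop = TRUE]
  else as.matrix(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the coordinate RMSD
#' of `mobile` onto `reference` (SVD of the covariance of centred coordinate
#' sets; a reflection, if favoured by the SVD, is corrected so that
#' `det(rotation) = +1`). Uniform weights.
#'
#' @param mobile,reference `md_structure` objects or `n x 3` matrices (nm)
#'   with equal atom counts (at least 3, not all collinear).
#' @return A `kabsch_fit`: list with `rotation` (3x3), `translation`
#'   (length-3, nm) such that `fitted = mobile %*% t(rotation) + translation`,
#'   and the post-fit `rmsd` (nm).
#' @export
kabsch_fit <- function(mobile, reference) {
  P <- .coords_of(mobile); Q <- .coords_of(reference)
  if (!all(dim(P) == dim(Q)))
    stop("atom-count mismatch: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3L) stop("underdetermined: need at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)                    # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd), class = "kabsch_fit")
}

#' Apply a superposition fit to coordinates
#' @param x `md_structure` or `n x 3` matrix.
#' @param fit A `kabsch_fit`.
#' @return Same type as `x`, transformed.
#' @export
apply_fit <- function(x, fit) {
  xyz <- .coords_of(x)
  out <- xyz %*% t(fit$rotation) + rep(1, nrow(xyz)) %*% t(fit$translation)
  if (inherits(x, "md_structure")) md_structure(x$atoms, out) else out
}

.rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Per-frame RMSD against a reference structure
#'
#' @param traj An `md_trajectory`.
#' @param reference `md_structure` or matrix with matching atom count;
#'   defaults to the first frame.
#' @param fit Superpose each frame onto the reference first (default TRUE).
#' @return Numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_series <- function(traj, reference = get_frame(traj, 1L), fit = TRUE) {
  ref <- .coords_of(reference)
  if (nrow(ref) != nrow(traj$atoms))
    stop("atom-count mismatch: reference ", nrow(ref), " vs trajectory ",
         nrow(traj$atoms))
  vapply(seq_len(n_frames(traj)), function(f) {
    X <- traj$coords[, , f, drop = TRUE]
    if (fit) kabsch_fit(X, ref)$rmsd else .rmsd_xyz(X, ref)
  }, numeric(1))
}

# Superpose every frame of a trajectory onto a reference coordinate set.
.superpose_frames <- function(coords, ref) {
  out <- coords
  for (f in seq_len(dim(coords)[3]))
    out[, , f] <- apply_fit(coords[, , f, drop = TRUE],
                            kabsch_fit(coords[, , f, drop = TRUE], ref))
  out
}

# Shared alignment used by rmsf() and displacement_covariance(): fit each
# frame to frame 1, take the coordinate-wise mean, refit every frame to that
# mean (one iteration), and return the aligned coordinates with their mean.
.align_to_mean <- function(traj, fit = TRUE) {
  coords <- traj$coords
  if (fit) {
    coords <- .superpose_frames(coords, coords[, , 1L, drop = TRUE])
    mu <- apply(coords, c(1, 2), mean)
    coords <- .superpose_frames(coords, mu)
  }
  list(coords = coords, mean = apply(coords, c(1, 2), mean))
}

#' Ensemble mean structure
#'
#' Coordinate-wise mean over frames, after superposing each frame onto the
#' first when `fit = TRUE`.
#'
#' @param traj An `md_trajectory`.
#' @param fit Superpose frames onto frame 1 before averaging.
#' @return An `md_structure`.
#' @export
mean_structure <- function(traj, fit = TRUE) {
  coords <- traj$coords
  if (fit && n_frames(traj) > 1L)
    coords <- .superpose_frames(coords, coords[, , 1L, drop = TRUE])
  md_structure(traj$atoms, apply(coords, c(1, 2), mean))
}

#' Per-residue root-mean-square fluctuation
#'
#' `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` on a C-alpha (one atom per
#' residue) trajectory. With `fit = "mean"` (default) every frame is first
#' superposed onto frame 1, the mean structure is formed, and all frames are
#' refit onto that mean; `"first"` fits onto frame 1 only; `"none"` uses the
#' coordinates as stored (for generators that produce already-aligned frames).
#'
#' @param traj An `md_trajectory` with at least 2 frames.
#' @param fit One of `"mean"`, `"first"`, `"none"`.
#' @return A `fluctuation_profile`: data.frame with `resseq` and `rmsf` (nm).
#' @export
rmsf <- function(traj, fit = c("mean", "first", "none")) {
  fit <- match.arg(fit)
  if (n_frames(traj) < 2L)
    stop("insufficient frames: RMSF needs at least 2")
  al <- switch(fit,
    mean  = .align_to_mean(traj, TRUE),
    first = { c2 <- .superpose_frames(traj$coords, traj$coords[, , 1L, drop = TRUE])
              list(coords = c2, mean = apply(c2, c(1, 2), mean)) },
    none  = .align_to_mean(traj, FALSE))
  dev2 <- sweep(al$coords, c(1, 2), al$mean)^2
  msf <- apply(dev2, 1, sum) / dim(al$coords)[3]   # mean over frames of |dr|^2
  out <- data.frame(resseq = traj$atoms$resseq, rmsf = sqrt(msf))
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' Highest-fluctuation residues
#'
#' Convenience wrapper reporting the residues whose RMSF falls in the top
#' `fraction` of the profile, the synthetic analogue of picking out flexible
#' regions such as surface loops.
#'
#' @param profile A `fluctuation_profile` from [rmsf()].
#' @param fraction Top fraction to report (default 0.1, the top decile).
#' @return Data frame of the selected residues sorted by decreasing RMSF.
#' @export
flexible_regions <- function(profile, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, ceiling(nrow(profile) * fraction))
  profile[order(-profile$rmsf)[seq_len(k)], , drop = FALSE]
}
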