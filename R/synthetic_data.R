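# Synthetic ensembles with analytically known statistics: a Gaussian network
# model (GNM) whose displacement covariance is the pseudo-inverse of the
# contact Kirchhoff matrix, plus Michaelis-Menten datasets and deterministic
# backbone fixtures. These generators stand in for long production MD runs
# and bench assays so the analysis chain can be validated against closed
# forms at desk scale.

# run code with a private, seeded RNG stream; global RNG state untouched
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Deterministic C-alpha fixture structure
#'
#' An ideal helix (rise 0.15 nm, radius 0.23 nm, 100 degrees per residue) or
#' a straight chain at 0.38 nm spacing. Same arguments always give bitwise
#' identical coordinates.
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry `"helix"` or `"chain"`.
#' @return An `md_structure` of C-alpha atoms.
#' @export
make_fixture_structure <- function(n_residues, geometry = c("helix", "chain")) {
  geometry <- match.arg(geometry)
  if (n_residues < 3L) stop("need at least 3 residues")
  i <- seq_len(n_residues) - 1L
  xyz <- switch(geometry,
    helix = cbind(0.23 * cos(i * 100 * pi / 180),
                  0.23 * sin(i * 100 * pi / 180),
                  0.15 * i),
    chain = cbind(0.38 * i, 0, 0))
  atoms <- .make_atom_table(seq_len(n_residues), rep("CA", n_residues),
                            rep("C", n_residues), rep("GLY", n_residues),
                            seq_len(n_residues))
  md_structure(atoms, xyz)
}

#' Gaussian network model over a C-alpha structure
#'
#' Builds the contact Kirchhoff matrix (off-diagonal -1 for pairs within
#' `contact_cutoff`, diagonal = contact count) and keeps its eigensystem for
#' covariance evaluation and sampling. The contact graph must be connected.
#'
#' @param reference An `md_structure` (C-alpha coordinates, nm).
#' @param contact_cutoff Contact distance, nm (default 0.7, the usual GNM
#'   choice; independent of any downstream network-analysis cutoff).
#' @param spring_constant Uniform spring constant (arbitrary energy/nm^2).
#'   The default of 100 puts per-residue RMSF at roughly 0.1 nm for compact
#'   backbones, the amplitude scale of a folded protein near its stable
#'   temperature range.
#' @param temperature_scale Unitless stand-in for kT; doubling it doubles
#'   every covariance entry, emulating a hotter ensemble.
#' @return A `gnm_model`.
#' @export
gnm_model <- function(reference, contact_cutoff = 0.7, spring_constant = 100,
                      temperature_scale = 1) {
  stopifnot(inherits(reference, "md_structure"),
            contact_cutoff > 0, spring_constant > 0, temperature_scale > 0)
  xyz <- reference$xyz
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  K <- -(D > 0 & D <= contact_cutoff) * 1
  diag(K) <- -colSums(K)
  eg <- eigen(K, symmetric = TRUE)
  nzero <- sum(abs(eg$values) < 1e-9 * max(eg$values))
  if (nzero != 1L)
    stop("model error: contact graph is disconnected at cutoff ",
         contact_cutoff, " nm (", nzero, " zero modes)")
  structure(list(reference = reference, contact_cutoff = contact_cutoff,
                 spring_constant = spring_constant,
                 temperature_scale = temperature_scale,
                 kirchhoff = K, eigen = eg, n = n),
            class = "gnm_model")
}

#' @export
print.gnm_model <- function(x, ...) {
  cat("gnm_model:", x$n, "residues, cutoff", x$contact_cutoff,
      "nm, temperature_scale", x$temperature_scale, "\n")
  invisible(x)
}

#' Analytic GNM displacement covariance
#'
#' `temperature_scale / spring_constant` times the pseudo-inverse of the
#' Kirchhoff matrix: the per-coordinate displacement covariance of the
#' model. With `three_d = TRUE` (default) the matrix is multiplied by 3,
#' giving the exact expectation of the 3-vector dot-product covariance
#' `<dR_i . dR_j>` that [displacement_covariance()] estimates from samples
#' (the three axes are i.i.d.). An optional per-residue `damping` profile d
#' rescales it to `diag(d) C diag(d)`, matching [sample_trajectory()].
#'
#' @param model A `gnm_model`.
#' @param damping Optional per-residue amplitude multipliers (length n).
#' @param three_d Return the 3-D dot-product covariance (default) rather
#'   than the per-coordinate one.
#' @return An `xcorr_matrix` of kind `"raw"`.
#' @export
gnm_covariance <- function(model, damping = NULL, three_d = TRUE) {
  eg <- model$eigen
  keep <- eg$values > 1e-9 * max(eg$values)
  Cinv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  C <- model$temperature_scale / model$spring_constant * Cinv
  if (!is.null(damping)) {
    stopifnot(length(damping) == model$n, all(damping > 0))
    C <- C * outer(damping, damping)
  }
  if (three_d) C <- 3 * C
  C <- (C + t(C)) / 2
  xcorr_matrix(C, "raw", model$reference$atoms$resseq)
}

#' Sample a synthetic trajectory from a GNM
#'
#' Frames are the reference coordinates plus independent Gaussian
#' displacements per axis with the model's per-coordinate covariance
#' (eigen factorization of the positive-semidefinite covariance; the zero
#' translational mode is excluded). A per-residue `damping` profile
#' multiplies displacement amplitudes, planting high-fluctuation "flexible
#' regions" like the loop sites seen in thermally stressed ensembles.
#' Deterministic given `seed`; the seed and temperature scale are recorded
#' as attributes.
#'
#' @param model A `gnm_model`.
#' @param n_frames Number of frames (>= 2).
#' @param seed RNG seed (recorded in the output).
#' @param damping Optional per-residue amplitude multipliers.
#' @return An `md_trajectory` (already aligned: no global tumbling).
#' @export
sample_trajectory <- function(model, n_frames, seed = 1L, damping = NULL) {
  if (n_frames < 2L) stop("need at least 2 frames")
  eg <- model$eigen
  keep <- eg$values > 1e-9 * max(eg$values)
  L <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(model$temperature_scale / (model$spring_constant * eg$values[keep])),
         sum(keep))
  if (!is.null(damping)) {
    stopifnot(length(damping) == model$n, all(damping > 0))
    L <- L * damping   # row-wise rescale
  }
  m <- ncol(L)
  coords <- .with_seed(seed, {
    out <- array(NA_real_, c(model$n, 3L, n_frames))
    for (ax in 1:3) {
      Z <- matrix(rnorm(m * n_frames), m, n_frames)
      out[, ax, ] <- model$reference$xyz[, ax] + L %*% Z
    }
    out
  })
  traj <- md_trajectory(model$reference$atoms, coords,
                        temperature = model$temperature_scale)
  attr(traj, "seed") <- seed
  attr(traj, "temperature_scale") <- model$temperature_scale
  traj
}

#' Synthetic Michaelis-Menten dataset
#'
#' `v = Vmax * S / (Km + S) + N(0, noise_sd)`, clipped at zero; deterministic
#' given `seed`.
#'
#' @param Vmax Maximal rate, uM min^-1 (> 0).
#' @param Km Michaelis constant, mM (> 0).
#' @param concentrations Substrate concentrations, mM (default 12 log-spaced
#'   points spanning 0.01-30 mM, the assayed range).
#' @param noise_sd Gaussian noise SD in rate units (default 0).
#' @param seed RNG seed.
#' @param ... Passed to [kinetics_dataset()] (label, temperature).
#' @return A `kinetics_dataset`.
#' @export
make_mm_dataset <- function(Vmax, Km,
                            concentrations = mm_concentrations(),
                            noise_sd = 0, seed = 1L, ...) {
  stopifnot(Vmax > 0, Km > 0, noise_sd >= 0)
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  v <- Vmax * concentrations / (Km + concentrations)
  if (noise_sd > 0)
    v <- pmax(0, v + .with_seed(seed, rnorm(length(v), 0, noise_sd)))
  kinetics_dataset(concentrations, v, ...)
}

#' Default assay concentration grid
#'
#' Log-spaced substrate concentrations spanning the assayed 0.01-30 mM range.
#'
#' @param n Number of points (default 12).
#' @param from,to Range endpoints, mM.
#' @return Numeric vector, mM.
#' @export
mm_concentrations <- function(n = 12L, from = 0.01, to = 30) {
  exp(seq(log(from), log(to), length.out = n))
}
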