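# Shrake-Rupley solvent-accessible surface area.

#' Quasi-uniform points on the unit sphere (golden spiral)
#'
#' @param n Number of points (>= 1).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Cell-list neighbor search: for each atom, indices of atoms within `cut` nm.
# Exact (27-cell stencil with cell size >= cut).
.neighbor_list <- function(xyz, cut) {
  n <- nrow(xyz)
  cell <- max(cut, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  id <- paste(key[, 1], key[, 2], key[, 3])
  bins <- split(seq_len(n), id)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    cand <- unlist(lapply(seq_len(27), function(o) {
      bins[[paste(key[i, 1] + offs[o, 1], key[i, 2] + offs[o, 2],
                  key[i, 3] + offs[o, 3])]]
    }), use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) == 0L) return(integer(0))
    d2 <- rowSums((xyz[cand, , drop = FALSE] -
                     matrix(xyz[i, ], length(cand), 3, byrow = TRUE))^2)
    cand[d2 < cut^2]
  })
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, places `n_points` quasi-uniform points (golden spiral) on a
#' sphere of radius `r_i + probe_radius` and counts the fraction not buried
#' inside any neighbor's expanded sphere; the accessible fraction times
#' `4*pi*(r_i + probe)^2` is that atom's SASA. Neighbors are found with an
#' exact cell list. Radii come from the atom table (bundled vdW table by
#' element), overridable via `radii`.
#'
#' @param structure An `md_structure`.
#' @param probe_radius Probe (solvent) radius, nm; 0.14 nm by default, the
#'   water-probe convention used by `gmx sasa`.
#' @param n_points Sphere points per atom (>= 64); default 960.
#' @param radii Optional per-atom radius override, nm.
#' @return A `sasa_result`: list with `per_atom` (nm^2), `total` (nm^2),
#'   `probe_radius`, `n_sphere_points`.
#' @export
shrake_rupley <- function(structure, probe_radius = 0.14, n_points = 960,
                          radii = NULL) {
  stopifnot(n_points >= 64, probe_radius >= 0)
  xyz <- structure$xyz
  r <- if (is.null(radii)) structure$atoms$radius else radii
  if (length(r) != nrow(xyz) || anyNA(r) || any(r <= 0))
    stop("configuration error: every atom needs a positive radius for SASA")
  R <- r + probe_radius
  pts <- sphere_points(n_points)
  nb <- .neighbor_list(xyz, 2 * max(R))
  per_atom <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    js <- nb[[i]]
    if (length(js) > 0L)
      js <- js[sqrt(rowSums((xyz[js, , drop = FALSE] -
                matrix(xyz[i, ], length(js), 3, byrow = TRUE))^2)) < R[i] + R[js]]
    P <- pts * R[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    if (length(js) > 0L) {
      Xn <- xyz[js, , drop = FALSE]
      # squared distances point-to-neighbor via the expansion |p|^2+|x|^2-2px
      d2 <- matrix(rowSums(P^2), n_points, length(js)) +
        matrix(rowSums(Xn^2), n_points, length(js), byrow = TRUE) -
        2 * P %*% t(Xn)
      acc <- rowSums(d2 < matrix(R[js]^2, n_points, length(js), byrow = TRUE)) == 0L
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * R[i]^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe_radius, n_sphere_points = n_points),
            class = "sasa_result")
}

#' Total SASA per frame of a trajectory
#'
#' @param traj An `md_trajectory`.
#' @inheritParams shrake_rupley
#' @return Numeric vector of total SASA (nm^2), one per frame.
#' @export
sasa_series <- function(traj, probe_radius = 0.14, n_points = 960,
                        radii = NULL) {
  vapply(seq_len(n_frames(traj)), function(f)
    shrake_rupley(get_frame(traj, f), probe_radius, n_points, radii)$total,
    numeric(1))
}
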