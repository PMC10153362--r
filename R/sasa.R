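## Shrake-Rupley solvent-accessible surface area and ligand burial (DSasa).

#' Deterministic unit sphere point set (golden-spiral)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic for a fixed point count: test points are placed on a
#' golden-spiral lattice on each atom's solvent-expanded sphere and counted
#' accessible when outside every neighbor's expanded sphere.
#'
#' @param xyz n x 3 matrix of atom positions, Angstrom.
#' @param radii per-atom van der Waals radii, Angstrom.
#' @param probe_radius probe radius, Angstrom (default 1.4).
#' @param n_points test points per atom (>= 100; default 960).
#' @return numeric vector of per-atom areas, Angstrom^2 (sum = total SASA).
#' @export
compute_sasa <- function(xyz, radii, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0) stop("empty atom set")
  stopifnot(length(radii) == n, all(radii > 0), probe_radius >= 0, n_points >= 100)
  pts <- sphere_points(n_points)
  R <- radii + probe_radius
  areas <- numeric(n)
  ## neighbor lists from the full distance matrix (fine at the sizes used here)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) { areas[i] <- 4 * pi * R[i]^2; next }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(p, 2, xyz[j, ])
      free <- free & (rowSums(dj * dj) > R[j]^2)
      if (!any(free)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  areas
}

#' Fraction of ligand surface buried in a complex (DSasa)
#'
#' @param ligand_xyz,ligand_radii ligand atoms (must be a subset of the
#'   complex, by position).
#' @param complex_xyz,complex_radii all atoms of the complex, ligand included.
#' @param probe_radius,n_points as in \code{\link{compute_sasa}}.
#' @return burial fraction in [0, 1]:
#'   (SASA_free - SASA_in_complex) / SASA_free.
#' @export
ligand_burial <- function(ligand_xyz, ligand_radii, complex_xyz, complex_radii,
                          probe_radius = 1.4, n_points = 960) {
  ligand_xyz <- as.matrix(ligand_xyz); complex_xyz <- as.matrix(complex_xyz)
  ## locate ligand atoms inside the complex
  idx <- integer(nrow(ligand_xyz))
  for (i in seq_len(nrow(ligand_xyz))) {
    d2 <- rowSums(sweep(complex_xyz, 2, ligand_xyz[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > 1e-12) stop("ligand atom ", i, " not found in complex")
    idx[i] <- j
  }
  free <- sum(compute_sasa(ligand_xyz, ligand_radii, probe_radius, n_points))
  if (free <= 0) stop("ligand has zero free surface area")
  in_cplx <- compute_sasa(complex_xyz, complex_radii, probe_radius, n_points)
  max(0, min(1, (free - sum(in_cplx[idx])) / free))
}
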