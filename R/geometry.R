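## Core kinematics: vectors, internal coordinates (NeRF), residue frames,
## rigid transforms, Kabsch superposition and C2 symmetry operations.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees, right-hand rule.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Bond angle at b (degrees)
#' @param a,b,c 3-vectors.
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d (degrees, IUPAC right-hand rule)
#' @param a,b,c,d 3-vectors.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Internal coordinate triple
#'
#' @param bond_length bond length, Angstrom (> 0).
#' @param bond_angle bond angle, degrees, in (0, 180).
#' @param dihedral dihedral, degrees.
#' @param refs optional integer indices of the three predecessor atoms.
#' @return object of class \code{internal_coordinate}.
#' @export
internal_coordinate <- function(bond_length, bond_angle, dihedral, refs = NULL) {
  stopifnot(is.finite(bond_length), bond_length > 0,
            is.finite(bond_angle), bond_angle > 0, bond_angle < 180,
            is.finite(dihedral))
  structure(list(bond_length = bond_length, bond_angle = bond_angle,
                 dihedral = dihedral, refs = refs),
            class = "internal_coordinate")
}

.check_not_collinear <- function(a, b, c) {
  n <- cross3(b - a, c - b)
  if (vnorm(n) < 1e-9 * max(vnorm(b - a), vnorm(c - b), 1))
    stop("reference atoms are collinear")
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Natural extension reference frame: given predecessors a, b, c, returns the
#' point d with |d - c| = bond length, angle(b, c, d) = bond angle and
#' dihedral(a, b, c, d) = dihedral (right-hand rule).
#'
#' @param a,b,c predecessor positions (3-vectors).
#' @param ic an \code{\link{internal_coordinate}}, or a numeric length-3
#'   vector \code{c(length, angle, dihedral)}.
#' @return 3-vector position of the new atom.
#' @export
nerf_place <- function(a, b, c, ic) {
  if (is.numeric(ic) && length(ic) == 3)
    ic <- internal_coordinate(ic[1], ic[2], ic[3])
  .check_not_collinear(a, b, c)
  r <- ic$bond_length
  theta <- deg2rad(ic$bond_angle)
  phi <- deg2rad(ic$dihedral)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-r * cos(theta), r * sin(theta) * cos(phi), -r * sin(theta) * sin(phi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Cartesian chain to internal coordinates
#'
#' Inverse of sequential \code{\link{nerf_place}}: atom i (i >= 4) is described
#' relative to atoms i-3, i-2, i-1.
#'
#' @param xyz n x 3 matrix of positions, n >= 4.
#' @return list of \code{internal_coordinate}, one per atom from the 4th on.
#' @export
cartesian_to_internal <- function(xyz) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 4) stop("need at least 4 atoms")
  out <- vector("list", n - 3)
  for (i in 4:n) {
    a <- xyz[i - 3, ]; b <- xyz[i - 2, ]; c <- xyz[i - 1, ]; d <- xyz[i, ]
    .check_not_collinear(a, b, c)
    out[[i - 3]] <- internal_coordinate(vnorm(d - c), bond_angle(b, c, d),
                                        dihedral_angle(a, b, c, d),
                                        refs = c(i - 3, i - 2, i - 1))
  }
  out
}

#' Rebuild a chain from internal coordinates
#'
#' @param seed_xyz 3 x 3 matrix: positions of the first three atoms (rows).
#' @param ics list of \code{internal_coordinate} as from
#'   \code{\link{cartesian_to_internal}}.
#' @return (3 + length(ics)) x 3 matrix of positions.
#' @export
internal_to_cartesian <- function(seed_xyz, ics) {
  seed_xyz <- as.matrix(seed_xyz)
  stopifnot(nrow(seed_xyz) == 3, ncol(seed_xyz) == 3)
  n <- 3 + length(ics)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1:3, ] <- seed_xyz
  for (k in seq_along(ics)) {
    i <- k + 3
    xyz[i, ] <- nerf_place(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ], ics[[k]])
  }
  xyz
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation 3-vector, Angstrom.
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation is improper (det < 0)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param rt a \code{rigid_transform}.
#' @param xyz n x 3 matrix (or 3-vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(rt, xyz) {
  if (is.null(dim(xyz))) return(as.numeric(rt$rotation %*% xyz + rt$translation))
  t(rt$rotation %*% t(as.matrix(xyz)) + rt$translation)
}

#' Compose two rigid transforms (apply a, then b)
#' @param a,b \code{rigid_transform}s.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation + b$translation))
}

#' Invert a rigid transform
#' @param rt a \code{rigid_transform}.
#' @export
invert_transform <- function(rt) {
  rigid_transform(t(rt$rotation), as.numeric(-t(rt$rotation) %*% rt$translation))
}

#' Orthonormal frame from residue backbone atoms
#'
#' Convention: origin at CA; x along CA->N; z along (CA->N) x (CA->C);
#' y = z x x. Deterministic for non-collinear input.
#'
#' @param n,ca,c backbone N, CA, C positions (3-vectors).
#' @return object of class \code{frame}: \code{origin}, \code{axes} (columns
#'   are the x, y, z axes in global coordinates).
#' @export
frame_from_residue <- function(n, ca, c) {
  .check_not_collinear(n, ca, c)
  e1 <- unitv(n - ca)
  e3 <- unitv(cross3(e1, c - ca))
  e2 <- cross3(e3, e1)
  structure(list(origin = as.numeric(ca), axes = cbind(e1, e2, e3, deparse.level = 0)),
            class = "frame")
}

#' Relative transform between two frames
#'
#' Expressed in f1's local coordinates, so the result is invariant under any
#' common rigid motion of both frames. Applying the result to f1 (via
#' \code{\link{frame_apply_local}}) reproduces f2.
#'
#' @param f1,f2 \code{frame} objects.
#' @return \code{rigid_transform}.
#' @export
transform_between <- function(f1, f2) {
  rigid_transform(crossprod(f1$axes, f2$axes),
                  as.numeric(crossprod(f1$axes, f2$origin - f1$origin)))
}

#' Apply a local-coordinates transform to a frame
#' @param f a \code{frame}; @param rt a \code{rigid_transform} in f's local coordinates.
#' @export
frame_apply_local <- function(f, rt) {
  structure(list(origin = as.numeric(f$origin + f$axes %*% rt$translation),
                 axes = f$axes %*% rt$rotation),
            class = "frame")
}

#' Global rigid motion carrying one frame onto another
#' @param f1,f2 \code{frame} objects.
#' @return \code{rigid_transform} g with g(f1) = f2 in global coordinates.
#' @export
motion_between_frames <- function(f1, f2) {
  R <- f2$axes %*% t(f1$axes)
  rigid_transform(R, as.numeric(f2$origin - R %*% f1$origin))
}

#' Kabsch superposition
#'
#' Least-squares proper-rotation superposition of index-corresponded point
#' sets. Returns the transform mapping p onto q and the residual RMSD.
#'
#' @param p,q n x 3 matrices, n >= 3, row i of p corresponds to row i of q.
#' @return list with \code{transform} (\code{rigid_transform}) and \code{rmsd}.
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q)) stop("point counts differ")
  if (nrow(p) < 3) stop("need at least 3 points")
  pc <- colMeans(p); qc <- colMeans(q)
  P <- sweep(p, 2, pc); Q <- sweep(q, 2, qc)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(qc - R %*% pc)
  rt <- rigid_transform(R, tr)
  rmsd <- sqrt(mean(rowSums((apply_transform(rt, p) - q)^2)))
  list(transform = rt, rmsd = rmsd)
}

#' Root-mean-square deviation without superposition
#' @param p,q n x 3 matrices.
#' @export
rmsd_raw <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(nrow(p) == nrow(q))
  sqrt(mean(rowSums((p - q)^2)))
}

#' Two-fold (C2) rotation of points about an axis
#'
#' @param axis unit 3-vector; @param point_on_axis 3-vector on the axis.
#' @param xyz n x 3 matrix (or 3-vector) of positions.
#' @return rotated positions, same shape as input.
#' @export
c2_apply <- function(axis, point_on_axis, xyz) {
  if (vnorm(axis) < 1e-12) stop("zero axis")
  u <- unitv(axis)
  R <- 2 * (u %o% u) - diag(3)
  one <- is.null(dim(xyz))
  X <- if (one) matrix(xyz, 1, 3) else as.matrix(xyz)
  Y <- t(R %*% (t(X) - point_on_axis) + point_on_axis)
  if (one) as.numeric(Y) else Y
}
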