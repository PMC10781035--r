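#' Rigid water monomer geometry
#'
#' Defines the internal geometry of the rigid 4-site water molecule: O--H
#' bond length, H-O-H angle, and the displacement of the massless M site
#' from the oxygen along the H-O-H bisector (toward the hydrogens).
#' Defaults are the gas-phase experimental geometry used by the Dang--Chang
#' model (Dang & Chang, J. Chem. Phys. 106, 8149, 1997).
#'
#' @param r_oh O--H bond length, Angstrom.
#' @param theta_hoh H-O-H angle, degrees.
#' @param r_om O--M distance along the bisector, Angstrom.
#' @return An object of class `water_geometry`.
#' @examples
#' water_geometry()
#' @export
water_geometry <- function(r_oh = 0.9572, theta_hoh = 104.5, r_om = 0.215) {
  stopifnot(r_oh > 0, theta_hoh > 0, theta_hoh < 180, r_om >= 0, r_om < r_oh)
  structure(list(r_oh = r_oh, theta_hoh = theta_hoh, r_om = r_om),
            class = "water_geometry")
}

#' @export
print.water_geometry <- function(x, ...) {
  cat(sprintf("Rigid water geometry: r(OH) = %.4f A, HOH = %.2f deg, r(OM) = %.4f A\n",
              x$r_oh, x$theta_hoh, x$r_om))
  invisible(x)
}

#' Rotation matrix from an angle-axis vector
#'
#' Rodrigues rotation: the rotation angle is `|p|` (radians) and the axis
#' `p/|p|`; the zero vector gives the identity.  Angle-axis vectors
#' parameterize rigid-body orientations without gimbal lock, which is why
#' they are used for the optimizer's orientational degrees of freedom.
#'
#' @param p numeric length-3 rotation vector, radians.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_from_angle_axis <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3, all(is.finite(p)))
  cpp_rotation(p)
}

#' Canonically reduce an angle-axis vector
#'
#' Maps the rotation vector to the equivalent one with magnitude in
#' `[0, pi]` (same rotation matrix).  Idempotent.  Used when comparing
#' poses; never applied silently during optimization, where a smooth
#' unconstrained parameterization is required.
#'
#' @param p numeric length-3 rotation vector, radians.
#' @return normalized rotation vector.
#' @export
normalize_angle_axis <- function(p) {
  p <- as.numeric(p)
  th <- sqrt(sum(p^2))
  if (th < .Machine$double.eps) return(p * 0)
  th2 <- th %% (2 * pi)
  ax <- p / th
  if (th2 > pi) {
    th2 <- 2 * pi - th2
    ax <- -ax
  }
  ax * th2
}

# body-frame site offsets; O at origin, bisector along +z (toward the
# hydrogens), molecule in the xz-plane
body_frame <- function(geom) {
  half <- 0.5 * geom$theta_hoh * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c(geom$r_oh * sin(half), 0, geom$r_oh * cos(half)),
        H2 = c(-geom$r_oh * sin(half), 0, geom$r_oh * cos(half)),
        M  = c(0, 0, geom$r_om))
}

#' Expand one rigid-body pose to Cartesian interaction sites
#'
#' The reference-frame molecule (O at the origin, H-O-H bisector along +z
#' pointing toward the hydrogens, molecule in the xz-plane) is rotated by
#' the pose orientation and translated by the pose position.  The pose
#' reference point is the O atom.
#'
#' @param pose numeric length-6 vector: position (x, y, z, Angstrom) then
#'   angle-axis orientation (radians); or a list with elements `position`
#'   and `orientation`.
#' @param geom a [water_geometry()].
#' @return 4x3 matrix with rows `O`, `H1`, `H2`, `M`.
#' @export
sites_from_pose <- function(pose, geom = water_geometry()) {
  if (is.list(pose)) pose <- c(pose$position, pose$orientation)
  pose <- as.numeric(pose)
  stopifnot(length(pose) == 6)
  B <- body_frame(geom)
  R <- cpp_rotation(pose[4:6])
  s <- t(R %*% t(B)) + matrix(pose[1:3], 4, 3, byrow = TRUE)
  dimnames(s) <- list(c("O", "H1", "H2", "M"), c("x", "y", "z"))
  s
}

#' Construct a cluster of rigid water molecules
#'
#' A cluster is an ordered set of rigid-body poses, each a position of the
#' O atom plus an angle-axis orientation.
#'
#' @param positions N x 3 matrix of O positions, Angstrom.
#' @param orientations N x 3 matrix of angle-axis vectors, radians
#'   (defaults to identity orientations).
#' @return An object of class `water_cluster`.
#' @export
water_cluster <- function(positions, orientations = NULL) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3)
    stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (is.null(orientations)) orientations <- matrix(0, n, 3)
  orientations <- as.matrix(orientations)
  stopifnot(nrow(orientations) == n, ncol(orientations) == 3)
  stopifnot(n >= 1, all(is.finite(positions)), all(is.finite(orientations)))
  structure(list(pose = cbind(unname(positions), unname(orientations))),
            class = "water_cluster")
}

# N x 6 pose matrix from a cluster (or pass-through for matrices)
pose_matrix <- function(x) {
  if (inherits(x, "water_cluster")) return(x$pose)
  x <- as.matrix(x)
  if (ncol(x) != 6) stop("expected a water_cluster or an N x 6 pose matrix")
  x
}

cluster_from_pose <- function(m) {
  structure(list(pose = m), class = "water_cluster")
}

#' @export
as.matrix.water_cluster <- function(x, ...) x$pose

#' Number of molecules in a cluster
#' @param config a `water_cluster`.
#' @return integer count.
#' @export
cluster_size <- function(config) nrow(pose_matrix(config))

#' @export
print.water_cluster <- function(x, ...) {
  n <- cluster_size(x)
  cat(sprintf("Rigid water cluster: %d molecule%s\n", n, if (n == 1) "" else "s"))
  if (n >= 2) {
    d <- oo_distances(x)
    cat(sprintf("  O-O distances: min %.3f A, max %.3f A\n", min(d), max(d)))
  }
  invisible(x)
}

#' Cartesian sites of every molecule in a cluster
#'
#' @param config a `water_cluster`.
#' @param geom a [water_geometry()].
#' @return list of 4x3 site matrices (rows `O`, `H1`, `H2`, `M`), one per
#'   molecule, in pose order.
#' @export
all_sites <- function(config, geom = water_geometry()) {
  m <- pose_matrix(config)
  lapply(seq_len(nrow(m)), function(i) sites_from_pose(m[i, ], geom))
}

# O positions (N x 3)
o_positions <- function(config) pose_matrix(config)[, 1:3, drop = FALSE]

# angle-axis from a rotation matrix; robust near 0 and pi
angle_axis_from_rotation <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(ct)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  if (th < 1e-7) return(v)
  if (th < pi - 1e-4) return(v / sin(th) * th)
  B <- (R + diag(3)) / 2
  k <- which.max(diag(B))
  ax <- B[, k] / sqrt(B[k, k])
  ax <- ax / sqrt(sum(ax^2))
  if (sum(v * ax) < 0) ax <- -ax
  ax * th
}

# apply a global rigid motion (rotation matrix + translation) to a cluster
transform_cluster <- function(config, R = diag(3), t = c(0, 0, 0)) {
  m <- pose_matrix(config)
  pos <- t(R %*% t(m[, 1:3, drop = FALSE])) +
    matrix(t, nrow(m), 3, byrow = TRUE)
  ori <- t(vapply(seq_len(nrow(m)), function(i) {
    angle_axis_from_rotation(R %*% cpp_rotation(m[i, 4:6]))
  }, numeric(3)))
  water_cluster(pos, ori)
}
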