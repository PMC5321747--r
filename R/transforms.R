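# Rigid-body transforms: ZYZ intrinsic Euler rotations plus voxel shifts.
#
# Conventions: apply_transform(m, t) rotates the volume about the centre
# voxel floor(N/2) (0-based) by R = Rz(phi) Ry(theta) Rz(psi) and then
# translates by `shift` voxels.  Composition t2 %after% t1 applies t1 first.

#' Rigid transform (ZYZ Euler angles + voxel shift)
#'
#' @param phi,theta,psi intrinsic ZYZ Euler angles in degrees.
#' @param shift numeric length-3 translation in voxels, applied after the
#'   rotation.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(phi = 0, theta = 0, psi = 0, shift = c(0, 0, 0)) {
  stopifnot(length(shift) == 3)
  structure(list(euler = c(phi = as.numeric(phi), theta = as.numeric(theta),
                           psi = as.numeric(psi)),
                 shift = as.numeric(shift)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> ZYZ euler (%.2f, %.2f, %.2f) deg, shift (%.2f, %.2f, %.2f) vox\n",
    x$euler[1], x$euler[2], x$euler[3], x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' Returns the 3x3 matrix R = Rz(phi) Ry(theta) Rz(psi) (intrinsic ZYZ).
#'
#' @param t a [rigid_transform()].
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(t) {
  e <- t$euler * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(e[1]) %*% ry(e[2]) %*% rz(e[3])
}

# ZYZ Euler angles (degrees) from a rotation matrix; theta in [0, 180].
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (abs(sin(theta)) < 1e-6) {
    # gimbal: phi and psi degenerate; fold everything into phi
    phi <- if (ct > 0) atan2(R[2, 1], R[1, 1]) else atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  } else {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(phi, theta, psi) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_transform(t2, t1)` is the transform equivalent to applying `t1`
#' first and `t2` second.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_transform <- function(t2, t1) {
  R <- rotation_matrix(t2) %*% rotation_matrix(t1)
  s <- as.vector(rotation_matrix(t2) %*% t1$shift) + t2$shift
  e <- matrix_to_euler(R)
  rigid_transform(e[1], e[2], e[3], s)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  R <- t(rotation_matrix(t))
  e <- matrix_to_euler(R)
  rigid_transform(e[1], e[2], e[3], as.vector(-R %*% t$shift))
}

#' Apply a rigid transform to a density map
#'
#' The volume is rotated about its centre voxel and translated, with
#' trilinear interpolation; voxels mapped from outside the source grid are
#' filled with 0.
#'
#' @param m a [density_map()] or 3D array.
#' @param t a [rigid_transform()].
#' @return transformed map of the same class and geometry as `m`.
#' @export
apply_transform <- function(m, t) {
  vol <- map_values(m)
  d <- dim(vol)
  Rinv <- t(rotation_matrix(t))
  cc <- grid_center(d)
  co <- grid_coords(d)
  # out(x) = in(Rinv (x - c - s) + c)
  p <- sweep(co, 2, cc + t$shift)
  xyz <- p %*% t(Rinv)
  xyz <- sweep(xyz, 2, cc, "+")
  v <- array(trilinear(vol, xyz, fill = 0), d)
  if (inherits(m, "density_map"))
    density_map(v, m$voxel_size, m$origin, m$label)
  else v
}

#' Draw rotations uniformly from SO(3)
#'
#' Uniform sampling via random unit quaternions (Shoemake's method),
#' avoiding the polar bias an independent Euler-angle draw would have.
#'
#' @param n number of rotations.
#' @return a list of [rigid_transform()] with zero shift.
#' @export
random_rotations <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  qw <- sqrt(1 - u1) * sin(2 * pi * u2)
  qx <- sqrt(1 - u1) * cos(2 * pi * u2)
  qy <- sqrt(u1) * sin(2 * pi * u3)
  qz <- sqrt(u1) * cos(2 * pi * u3)
  lapply(seq_len(n), function(i) {
    w <- qw[i]; x <- qx[i]; y <- qy[i]; z <- qz[i]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3)
    e <- matrix_to_euler(R)
    rigid_transform(e[1], e[2], e[3])
  })
}
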