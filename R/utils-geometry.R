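# Small 3D geometry helpers used throughout the package.
#
# Global frame convention: right-handed, X anterior, Y left, Z cranial.
# Positions mm, forces N, moments N.mm, stresses MPa; angles in radians
# internally, degrees at the user interface.

#' Skew-symmetric (cross-product) matrix
#'
#' Returns the 3x3 matrix `S` such that `S %*% b == cross3(a, b)`.
#'
#' @param a numeric length-3 vector.
#' @return 3x3 matrix.
#' @keywords internal
skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about the global Y axis
#' @param phi angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_y <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), 3, 3)
}

#' @keywords internal
rot_x <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)
}

#' @keywords internal
rot_z <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(c, s, 0,
           -s, c, 0,
           0, 0, 1), 3, 3)
}

#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

# Reflection across the sagittal (XZ) plane: y -> -y.
#' @keywords internal
mirror_point <- function(p) c(p[1], -p[2], p[3])

# Mirror a rotation matrix expressed in the global frame: R' = M R M with
# M = diag(1, -1, 1).  This keeps the mirrored frame right-handed for frames
# built from sagittal-plane rotations.
#' @keywords internal
mirror_rotation <- function(R) {
  M <- diag(c(1, -1, 1))
  M %*% R %*% M
}

#' Motion axis in the global frame
#'
#' Maps a motion label to the unit moment/rotation axis: flexion rotates the
#' trunk forward about +Y, extension about -Y, lateral bending to the left
#' about -X, to the right about +X, and axial rotation about +Z.
#'
#' @param motion one of `"flexion"`, `"extension"`, `"lateral_left"`,
#'   `"lateral_right"`, `"axial_rotation"`.
#' @return unit length-3 vector.
#' @export
motion_axis <- function(motion) {
  switch(motion,
    flexion        = c(0, 1, 0),
    extension      = c(0, -1, 0),
    lateral_left   = c(-1, 0, 0),
    lateral_right  = c(1, 0, 0),
    axial_rotation = c(0, 0, 1),
    stop("unknown motion label: ", motion)
  )
}

#' @keywords internal
all_motions <- function() c("flexion", "extension", "lateral_left", "lateral_right")

#' @keywords internal
calibration_motions <- function() {
  c("flexion", "extension", "lateral_left", "lateral_right", "axial_rotation")
}
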