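#' Forward kinematics of the 4-DOF arm
#'
#' Maps the four joint angles (shoulder pitch, yaw, roll, and elbow, in
#' radians) to the 3-D wrist position by multiplying the four homogeneous
#' transformation matrices of the arm's kinematic chain. Link translations
#' are 0.05 (shoulder), 0.22 (upper arm) and 0.16 (forearm) in dimensionless
#' link-length units, so every reachable position has norm at most 0.43.
#'
#' @param angles Numeric vector of length 4 (`pitch`, `yaw`, `roll`,
#'   `elbow`, radians), or a matrix / data frame with those four columns.
#' @return For a single angle set, a named numeric vector `c(x, y, z)`.
#'   For multi-row input, a [tibble::tibble()] with columns `x`, `y`, `z`.
#' @examples
#' forward_kinematics(c(0, 0, 0, 0))
#' @export
forward_kinematics <- function(angles) {
  if (is.data.frame(angles)) angles <- as.matrix(angles[, c("pitch", "yaw", "roll", "elbow")])
  if (is.matrix(angles)) {
    out <- t(apply(angles, 1L, fk_one))
    return(tibble::tibble(x = out[, 1L], y = out[, 2L], z = out[, 3L]))
  }
  fk_one(angles)
}

fk_one <- function(a) {
  if (length(a) != 4L || !all(is.finite(a))) {
    stop("`angles` must be four finite values (pitch, yaw, roll, elbow)", call. = FALSE)
  }
  pitch <- a[[1L]]; yaw <- a[[2L]]; roll <- a[[3L]]; elbow <- a[[4L]]
  G01 <- matrix(c(
    cos(pitch), 0, -sin(pitch), 0,
    sin(pitch), 0,  cos(pitch), 0,
    0, -1, 0, 0,
    0,  0, 0, 1), 4L, 4L, byrow = TRUE)
  ay <- pi / 2 + yaw
  G12 <- matrix(c(
    cos(ay), 0, -sin(ay), 0.05 * cos(ay),
    sin(ay), 0,  cos(ay), 0.05 * sin(ay),
    0, -1, 0, 0,
    0,  0, 0, 1), 4L, 4L, byrow = TRUE)
  ar <- pi / 2 + roll
  G23 <- matrix(c(
    cos(ar), 0,  sin(ar), 0,
    sin(ar), 0, -cos(ar), 0,
    0, 1, 0, 0.22,
    0, 0, 0, 1), 4L, 4L, byrow = TRUE)
  ae <- pi / 2 + elbow
  G34 <- matrix(c(
    cos(ae), -sin(ae), 0, 0.16 * cos(ae),
    sin(ae),  cos(ae), 0, 0.16 * sin(ae),
    0, 0, 1, 0,
    0, 0, 0, 1), 4L, 4L, byrow = TRUE)
  p <- G01 %*% G12 %*% G23 %*% G34 %*% c(0, 0, 0, 1)
  c(x = p[[1L]], y = p[[2L]], z = p[[3L]])
}

#' Rotate a point about an axis through the origin
#'
#' Rigid (Rodrigues) rotation of `position` by `angle` radians about the
#' origin-anchored `axis`, following the right-hand rule. Used to apply the
#' visuomotor cursor rotation (the adaptation protocol anchors the axis at
#' the initial hand position by translating before and after the call).
#'
#' @param position Numeric length-3 point.
#' @param axis Numeric length-3 rotation axis (any non-zero length).
#' @param angle Rotation angle in radians.
#' @return The rotated point (named numeric `x`, `y`, `z`).
#' @export
rotate_endpoint <- function(position, axis, angle) {
  stopifnot(length(position) == 3L, length(axis) == 3L, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("degenerate rotation axis (zero vector)", call. = FALSE)
  k <- axis / n
  v <- as.numeric(position)
  rot <- v * cos(angle) + cross3(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
  c(x = rot[[1L]], y = rot[[2L]], z = rot[[3L]])
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed angular (directional) reach error
#'
#' Projects the movement vector (`final - initial`) and the goal vector
#' (`goal - initial`) onto the plane orthogonal to `plane_normal` and
#' returns the angle between them in degrees. The magnitude is the planar
#' angle at the initial position; the sign is positive when the movement is
#' rotated counter-clockwise from the goal direction about `plane_normal`
#' (right-hand rule), which is what renders the aftereffect sign flip when
#' a visuomotor rotation is removed.
#'
#' @param initial,final,goal Numeric length-3 positions.
#' @param plane_normal Normal of the measurement plane (non-zero).
#' @return Signed angle in degrees.
#' @export
angular_error <- function(initial, final, goal, plane_normal) {
  nn <- sqrt(sum(plane_normal^2))
  if (nn < 1e-12) stop("degenerate plane normal (zero vector)", call. = FALSE)
  k <- plane_normal / nn
  proj <- function(v) v - sum(v * k) * k
  u <- proj(as.numeric(goal) - as.numeric(initial))    # desired direction
  v <- proj(as.numeric(final) - as.numeric(initial))   # actual direction
  if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12) {
    stop("undefined angular error: projected movement or goal vector is degenerate",
         call. = FALSE)
  }
  ang <- atan2(sum(k * cross3(u, v)), sum(u * v))
  ang * 180 / pi
}

#' Hand position of the resting arm configuration
#'
#' The reference posture (all joint angles at their reference value, zero by
#' default) from which every movement starts and from which goal distances
#' are measured.
#'
#' @param fixed CPG fixed-parameter set, see [cpg_fixed()]; only `U_ref` is
#'   used.
#' @return Named numeric position `c(x, y, z)`.
#' @export
initial_hand_position <- function(fixed = cpg_fixed()) {
  forward_kinematics(fixed$U_ref)
}
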