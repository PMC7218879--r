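#' Normalization configuration
#'
#' Settings for removing global translation and heading from poses.
#' Translation is removed by placing the root joint at the origin;
#' heading (rotation about the vertical y axis) is removed by rotating the
#' pose so that the hip-to-hip vector (`right_hip - left_hip`) lies along
#' the +z axis, which turns the subject's facing direction toward +x in a
#' right-handed y-up frame. Only the y rotation is removed: full 3-DOF
#' alignment would also erase lean and posture, which carry action
#' information.
#'
#' @param root_index 1-based index of the root (centre-of-mass) joint.
#' @param left_hip_index,right_hip_index 1-based indices of the hip pair.
#'   Which physical joint is "left" is a convention; any consistent choice
#'   yields an equivalent classifier, so the default simply matches the
#'   synthetic skeleton template.
#' @param per_frame if `TRUE` (default) every frame is normalized
#'   independently; if `FALSE` each frame is centred but a single heading,
#'   estimated from the first frame, is removed from the whole clip.
#' @return an object of class `norm_config`.
#' @export
norm_config <- function(root_index = 1L, left_hip_index = 2L,
                        right_hip_index = 3L, per_frame = TRUE) {
  idx <- c(root_index, left_hip_index, right_hip_index)
  if (anyDuplicated(idx))
    stop("root and hip indices must be distinct")
  if (any(idx < 1L))
    stop("joint indices must be >= 1")
  structure(list(root_index = as.integer(root_index),
                 left_hip_index = as.integer(left_hip_index),
                 right_hip_index = as.integer(right_hip_index),
                 per_frame = isTRUE(per_frame)),
            class = "norm_config")
}

check_indices <- function(cfg, J) {
  idx <- c(cfg$root_index, cfg$left_hip_index, cfg$right_hip_index)
  if (any(idx > J))
    stop("normalization joint index out of range for J = ", J)
}

# Projection length below which the hip vector carries no usable heading.
.hip_degenerate_tol <- 1e-12

#' Centre a pose at its root joint
#'
#' Subtracts the root joint's coordinates from every joint, so the root
#' lands exactly at (0, 0, 0).
#'
#' @param p a `J x 3` pose matrix.
#' @param root_index 1-based root joint index.
#' @return the centred pose.
#' @export
center_pose <- function(p, root_index = 1L) {
  p <- pose(p)
  if (root_index < 1L || root_index > nrow(p))
    stop("root_index out of range")
  sweep(p, 2L, p[root_index, ])
}

#' Heading angle of a root-centred pose
#'
#' Returns the angle `theta` in `(-pi, pi]` such that [rotate_about_y()]
#' by `theta` places the hip-to-hip vector (right hip minus left hip)
#' along +z in the xz-plane (x component 0, z component >= 0).
#'
#' @param p a root-centred `J x 3` pose matrix.
#' @param cfg a [norm_config()].
#' @return the heading angle in radians, or `NA_real_` when the hip
#'   vector's xz projection is degenerate (length below 1e-12), meaning
#'   "no heading": callers treat the rotation as the identity.
#' @export
heading_angle <- function(p, cfg = norm_config()) {
  p <- pose(p)
  check_indices(cfg, nrow(p))
  hip <- unname(p[cfg$right_hip_index, ] - p[cfg$left_hip_index, ])
  if (sqrt(hip[1]^2 + hip[3]^2) < .hip_degenerate_tol) return(NA_real_)
  theta <- -atan2(hip[1], hip[3])
  if (theta <= -pi) theta <- theta + 2 * pi
  theta
}

#' Rotate a pose about the y axis
#'
#' Applies `(x, y, z) -> (x cos t + z sin t, y, -x sin t + z cos t)` to
#' every joint; y coordinates and all pairwise joint distances are
#' preserved (rigid rotation).
#'
#' @param p a `J x 3` pose matrix.
#' @param angle rotation angle in radians.
#' @return the rotated pose.
#' @export
rotate_about_y <- function(p, angle) {
  p <- pose(p)
  if (!is.finite(angle)) stop("rotation angle must be finite")
  ct <- cos(angle); st <- sin(angle)
  cbind(x = p[, 1] * ct + p[, 3] * st,
        y = p[, 2],
        z = -p[, 1] * st + p[, 3] * ct)
}

#' Normalize a single pose
#'
#' Centres the pose at the root joint, then removes the heading rotation.
#' After normalization the root is at the origin, the hip-to-hip vector
#' has |x| < 1e-9 and z >= 0, and the operation is idempotent. A pose with
#' a degenerate hip projection (e.g. all joints coincident) is returned
#' centred but unrotated, with a warning.
#'
#' @param p a `J x 3` pose matrix.
#' @param cfg a [norm_config()].
#' @return the normalized pose.
#' @export
normalize_pose <- function(p, cfg = norm_config()) {
  p <- center_pose(p, cfg$root_index)
  theta <- heading_angle(p, cfg)
  if (is.na(theta)) {
    warning("degenerate hip projection: heading left unchanged")
    return(p)
  }
  rotate_about_y(p, theta)
}

#' Normalize every frame of a motion
#'
#' With `cfg$per_frame = TRUE` (default) each frame is normalized
#' independently, so only "how the motion is performed" remains. With
#' `per_frame = FALSE` every frame is centred but a single heading,
#' estimated from the first frame, is removed from the whole clip (a
#' whole-clip reading of orientation removal). Frame count, fps and label
#' are preserved.
#'
#' @param m a `motion`.
#' @param cfg a [norm_config()].
#' @return the normalized `motion`.
#' @export
normalize_motion <- function(m, cfg = norm_config()) {
  stopifnot(inherits(m, "motion"))
  J <- n_joints(m)
  check_indices(cfg, J)
  F <- m$frames
  xc <- seq(1L, 3L * J, by = 3L)
  yc <- xc + 1L
  zc <- xc + 2L
  # centre: subtract root columns from every joint, per axis
  ri <- cfg$root_index
  F[, xc] <- F[, xc] - F[, xc[ri]]
  F[, yc] <- F[, yc] - F[, yc[ri]]
  F[, zc] <- F[, zc] - F[, zc[ri]]
  # heading per frame (or from frame 1 only)
  hx <- F[, xc[cfg$right_hip_index]] - F[, xc[cfg$left_hip_index]]
  hz <- F[, zc[cfg$right_hip_index]] - F[, zc[cfg$left_hip_index]]
  degen <- sqrt(hx^2 + hz^2) < .hip_degenerate_tol
  theta <- -atan2(hx, hz)
  theta[degen] <- 0
  if (any(degen))
    warning("degenerate hip projection in ", sum(degen),
            " frame(s): heading left unchanged there")
  if (!cfg$per_frame) theta <- rep(theta[1L], length(theta))
  ct <- cos(theta); st <- sin(theta)
  X <- F[, xc, drop = FALSE]
  Z <- F[, zc, drop = FALSE]
  F[, xc] <- X * ct + Z * st
  F[, zc] <- -X * st + Z * ct
  out <- m
  out$frames <- F
  out
}
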