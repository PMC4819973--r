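# Rigid-body transforms with named coordinate frames, quaternion utilities,
# and pose-stream interpolation. Internally a transform is stored as a 3x3
# rotation plus translation; `as_homogeneous()` gives the 4x4 view.

#' Construct a rigid transform between two named coordinate frames
#'
#' A rigid transform maps coordinates in `from` into coordinates in `to`
#' as `p_to = R %*% p_from + t`. The rotation must be orthonormal with
#' determinant +1; small numerical drift (up to `1e-6`) is projected back
#' onto the rotation group by polar decomposition.
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation numeric length-3, millimetres.
#' @param from,to coordinate frame labels.
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(rot_axis_angle("z", 90), c(1, 0, 0), "a", "b")
#' transform_points(t, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = "from", to = "to") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    usnav_stop("rotation must be a finite 3x3 matrix", "usnav_invalid_transform")
  if (length(translation) != 3L || !all(is.finite(translation)))
    usnav_stop("translation must be a finite 3-vector", "usnav_invalid_transform")
  drift <- max(abs(crossprod(rotation) - diag(3)))
  if (drift > 1e-6)
    usnav_stop("rotation is not orthonormal", "usnav_invalid_transform")
  if (drift > 1e-12) rotation <- polar_orthonormalize(rotation)
  if (det(rotation) < 0)
    usnav_stop("rotation has determinant -1 (reflection)",
               "usnav_invalid_transform")
  dimnames(rotation) <- NULL
  names(translation) <- NULL
  structure(list(rotation = rotation, translation = translation,
                 from = as.character(from), to = as.character(to),
                 depth = 1L),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from, x$to))
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(NULL, c("r1", "r2", "r3", "t_mm"))
  print(round(m, 6))
  invisible(x)
}

#' Identity transform between two frames
#' @param from,to frame labels.
#' @return A `rigid_transform`.
#' @export
identity_transform <- function(from = "from", to = from) {
  rigid_transform(diag(3), c(0, 0, 0), from, to)
}

# Nearest rotation in Frobenius norm (polar decomposition via SVD).
polar_orthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  r
}

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param axis `"x"`, `"y"`, `"z"`, or a 3-vector (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  a <- as.numeric(axis)
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) usnav_stop("axis must be non-zero", "usnav_invalid_transform")
  a <- a / nrm
  th <- angle_deg * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`; it therefore requires
#' `a$from == b$to` and maps `b$from` into `a$to`. A frame-label mismatch is
#' an error — silent composition across the wrong frames is the classic
#' calibration-chain bug. After long chains (> 10 links) the rotation is
#' re-orthonormalized by polar decomposition to bound float drift.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$from, b$to))
    usnav_stop(sprintf("frame chain mismatch: cannot compose [%s -> %s] after [%s -> %s]",
                       a$from, a$to, b$from, b$to), "usnav_frame_error")
  r <- a$rotation %*% b$rotation
  t <- drop(a$rotation %*% b$translation) + a$translation
  depth <- a$depth + b$depth
  if (depth > 10L) {
    r <- polar_orthonormalize(r)
    depth <- 1L
  }
  out <- rigid_transform(r, t, from = b$from, to = a$to)
  out$depth <- as.integer(depth)
  out
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return The inverse transform, with frame labels swapped.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), drop(-t(t$rotation) %*% t$translation),
                  from = t$to, to = t$from)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param pts a length-3 vector or an n x 3 matrix of points (mm).
#' @return Points in the same shape as the input.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(as.numeric(pts), 1L, 3L) else as.matrix(pts)
  if (ncol(p) != 3L || !all(is.finite(p)))
    usnav_stop("points must be finite n x 3", "usnav_invalid_input")
  out <- p %*% t(t$rotation)
  out <- sweep(out, 2L, t$translation, "+")
  if (vec) drop(out) else out
}

#' Homogeneous 4x4 matrix view of a rigid transform
#' @param t a `rigid_transform`.
#' @return 4x4 matrix.
#' @export
as_homogeneous <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' Rigid transform from a homogeneous 4x4 matrix
#' @param m 4x4 matrix with last row (0,0,0,1).
#' @param from,to frame labels.
#' @return A `rigid_transform`.
#' @export
from_homogeneous <- function(m, from = "from", to = "to") {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L)) || max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    usnav_stop("not a homogeneous rigid matrix", "usnav_invalid_transform")
  rigid_transform(m[1:3, 1:3], m[1:3, 4], from, to)
}

# ---- quaternions (w, x, y, z), unit norm ----------------------------------

quat_from_rotation <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

rotation_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Shortest-arc spherical linear interpolation; u in [0, 1].
quat_slerp <- function(q0, q1, u) {
  d <- sum(q0 * q1)
  if (d < 0) {  # antipodal representations: take the short way round
    q1 <- -q1
    d <- -d
  }
  if (d > 1 - 1e-12) {
    q <- (1 - u) * q0 + u * q1
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(min(1, d))
  (sin((1 - u) * th) * q0 + sin(u * th) * q1) / sin(th)
}

# ---- pose streams ---------------------------------------------------------

#' Construct a timestamped pose stream
#'
#' Carrier for tracker output: a sequence of tool poses, each mapping
#' sensor-local coordinates into tracker coordinates, at strictly increasing
#' timestamps.
#'
#' @param timestamps_ms numeric vector, strictly increasing, milliseconds.
#' @param poses list of `rigid_transform`, all with the same frame labels.
#' @return An object of class `pose_stream`.
#' @export
pose_stream <- function(timestamps_ms, poses) {
  timestamps_ms <- as.numeric(timestamps_ms)
  n <- length(timestamps_ms)
  if (n == 0L)
    usnav_stop("pose stream must be non-empty", "usnav_empty_input")
  if (!all(is.finite(timestamps_ms)))
    usnav_stop("timestamps must be finite", "usnav_invalid_input")
  if (n > 1L && any(diff(timestamps_ms) <= 0))
    usnav_stop("timestamps must be strictly increasing", "usnav_invalid_input")
  if (length(poses) != n)
    usnav_stop("one pose per timestamp required", "usnav_invalid_input")
  from <- poses[[1L]]$from
  to <- poses[[1L]]$to
  quat <- matrix(0, n, 4L)
  trans <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    if (!identical(p$from, from) || !identical(p$to, to))
      usnav_stop("all poses in a stream must share frame labels",
                 "usnav_frame_error")
    quat[i, ] <- quat_from_rotation(p$rotation)
    trans[i, ] <- p$translation
  }
  # consistent hemisphere so row-wise slerp never flips sign mid-stream
  for (i in seq_len(n)[-1L]) {
    if (sum(quat[i, ] * quat[i - 1L, ]) < 0) quat[i, ] <- -quat[i, ]
  }
  structure(list(t_ms = timestamps_ms, quat = quat, trans = trans,
                 from = from, to = to),
            class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream %s -> %s: %d samples, %.1f..%.1f ms>\n",
              x$from, x$to, length(x$t_ms), min(x$t_ms), max(x$t_ms)))
  invisible(x)
}

#' Number of samples in a pose stream
#' @param stream a `pose_stream`.
#' @return Integer count.
#' @export
n_poses <- function(stream) length(stream$t_ms)

#' Extract one sample of a pose stream as a rigid transform
#' @param stream a `pose_stream`.
#' @param i sample index.
#' @return A `rigid_transform`.
#' @export
pose_at <- function(stream, i) {
  rigid_transform(rotation_from_quat(stream$quat[i, ]), stream$trans[i, ],
                  from = stream$from, to = stream$to)
}

#' Interpolate a pose stream at an arbitrary time
#'
#' Translation is interpolated linearly; rotation on the shortest arc by
#' spherical linear interpolation of unit quaternions. Querying at a sample
#' timestamp returns that sample exactly. Times outside the stream range are
#' an error — poses are never extrapolated or clamped silently.
#'
#' @param stream a `pose_stream`.
#' @param t_ms query time, milliseconds.
#' @return A `rigid_transform`.
#' @export
interpolate_pose <- function(stream, t_ms) {
  stopifnot(inherits(stream, "pose_stream"))
  ts <- stream$t_ms
  if (!is.finite(t_ms) || t_ms < ts[1L] || t_ms > ts[length(ts)])
    usnav_stop(sprintf("time %.3f ms outside pose stream range [%.3f, %.3f]",
                       t_ms, ts[1L], ts[length(ts)]),
               "usnav_extrapolation_error")
  k <- findInterval(t_ms, ts)
  if (ts[k] == t_ms) return(pose_at(stream, k))
  u <- (t_ms - ts[k]) / (ts[k + 1L] - ts[k])
  q <- quat_slerp(stream$quat[k, ], stream$quat[k + 1L, ], u)
  tr <- (1 - u) * stream$trans[k, ] + u * stream$trans[k + 1L, ]
  rigid_transform(rotation_from_quat(q), tr, from = stream$from, to = stream$to)
}
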