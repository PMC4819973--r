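# Rigid registration methods: least-squares landmark fit, fast one-landmark
# orientation registration, centerline ICP (point-to-segment), and the
# trajectory-to-airway variant with an orientation gate. All solvers share
# the SVD-based rigid fit with a reflection guard.

#' Construct a named landmark set
#'
#' @param points n x 3 matrix (mm) with unique rownames, or a data.frame with
#'   columns `name`, `x_mm`, `y_mm`, `z_mm`.
#' @param frame coordinate frame label.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame = "unknown") {
  if (is.data.frame(points)) {
    nm <- as.character(points$name)
    points <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L || !all(is.finite(points)))
    usnav_stop("landmarks must be finite n x 3", "usnav_invalid_input")
  if (is.null(rownames(points)))
    rownames(points) <- paste0("p", seq_len(nrow(points)))
  if (anyDuplicated(rownames(points)))
    usnav_stop("landmark names must be unique", "usnav_invalid_input")
  colnames(points) <- NULL
  structure(list(points = points, frame = as.character(frame)),
            class = "landmark_set")
}

#' Construct a centerline (ordered 3D polyline)
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2, consecutive
#'   points distinct.
#' @param tangents optional n x 3 matrix of unit tangent vectors.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, tangents = NULL) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (ncol(points) != 3L || nrow(points) < 2L || !all(is.finite(points)))
    usnav_stop("centerline needs >= 2 finite 3D points", "usnav_invalid_input")
  seglen <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  if (any(seglen == 0))
    usnav_stop("consecutive centerline points must be distinct",
               "usnav_invalid_input")
  if (!is.null(tangents)) {
    tangents <- as.matrix(tangents)
    dimnames(tangents) <- NULL
    if (!all(dim(tangents) == dim(points)))
      usnav_stop("one tangent per point required", "usnav_invalid_input")
    nrm <- sqrt(rowSums(tangents^2))
    if (any(abs(nrm - 1) > 1e-6))
      usnav_stop("tangents must be unit vectors", "usnav_invalid_input")
    tangents <- tangents / nrm
  }
  structure(list(points = points, tangents = tangents), class = "centerline")
}

#' Centerline tangents by central differences
#'
#' Returns the stored tangents if present, otherwise unit tangents estimated
#' by central differences (one-sided at the ends).
#'
#' @param cl a `centerline`.
#' @return n x 3 matrix of unit tangents.
#' @export
centerline_tangents <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  if (!is.null(cl$tangents)) return(cl$tangents)
  p <- cl$points
  n <- nrow(p)
  d <- rbind(p[2L, ] - p[1L, ],
             if (n > 2L) p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
             p[n, ] - p[n - 1L, ])
  d / sqrt(rowSums(d^2))
}

# Least-squares rigid fit F ~ R M + t (Arun/Umeyama without scale), with the
# det = +1 reflection guard.
fit_rigid <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  h <- crossprod(sweep(moving, 2L, cm), sweep(fixed, 2L, cf))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, translation = drop(cf - r %*% cm))
}

registration_result <- function(transform, rms_residual, per_iteration_residuals,
                                n_correspondences, method) {
  structure(list(transform = transform, rms_residual = rms_residual,
                 per_iteration_residuals = per_iteration_residuals,
                 n_correspondences = n_correspondences, method = method),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %s, %d correspondences, rms %.4g mm, %d iteration(s)>\n",
              x$method, x$n_correspondences, x$rms_residual,
              length(x$per_iteration_residuals)))
  print(x$transform)
  invisible(x)
}

#' Landmark registration by least squares
#'
#' Matches landmarks by name and finds the rigid transform minimising
#' \eqn{\sum_i |T m_i - f_i|^2} via the SVD solution with a reflection guard
#' (the returned rotation always has determinant +1). Usable for both
#' image-to-image and image-to-patient registration.
#'
#' @param moving,fixed `landmark_set` objects sharing at least 3 landmark
#'   names; the common points must not be collinear.
#' @return A `registration_result` whose transform maps the moving frame
#'   into the fixed frame.
#' @export
register_landmarks <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  common <- intersect(rownames(moving$points), rownames(fixed$points))
  if (length(common) < 3L)
    usnav_stop(sprintf("need >= 3 common landmarks, found %d", length(common)),
               "usnav_insufficient_landmarks")
  m <- moving$points[common, , drop = FALSE]
  f <- fixed$points[common, , drop = FALSE]
  sv <- svd(sweep(m, 2L, colMeans(m)))$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    usnav_stop("landmarks are collinear: rotation is not determined",
               "usnav_degenerate_geometry")
  fit <- fit_rigid(m, f)
  t <- rigid_transform(fit$rotation, fit$translation,
                       from = moving$frame, to = fixed$frame)
  res <- sqrt(mean(rowSums((transform_points(t, m) - f)^2)))
  registration_result(t, res, res, length(common), "landmark")
}

#' Fast registration from one landmark and a tool orientation
#'
#' Rough initial registration: the rotation is the minimal rotation carrying
#' the reference axis (moving space) onto the tool axis (fixed space), and
#' the translation then maps the single landmark exactly. Not an accurate
#' method; intended as an initial estimate for refinement.
#'
#' For anti-parallel axes the rotation is 180 degrees about the coordinate
#' axis most perpendicular to the reference axis (deterministic tie-break).
#'
#' @param landmark_moving,landmark_fixed corresponding point (mm) in each space.
#' @param tool_axis_fixed,reference_axis_moving unit direction vectors.
#' @param from,to frame labels for the resulting transform.
#' @return A `registration_result` (moving -> fixed); its residual at the
#'   landmark is exactly zero.
#' @export
register_fast <- function(landmark_moving, landmark_fixed,
                          tool_axis_fixed, reference_axis_moving,
                          from = "moving", to = "fixed") {
  a <- as.numeric(reference_axis_moving)
  b <- as.numeric(tool_axis_fixed)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (abs(na - 1) > 1e-6 || abs(nb - 1) > 1e-6)
    usnav_stop("axes must be unit vectors", "usnav_invalid_input")
  a <- a / na; b <- b / nb
  d <- sum(a * b)
  if (d < -1 + 1e-12) {
    # anti-parallel: any perpendicular axis works; pick deterministically
    perp <- which.min(abs(a))
    axis <- c(0, 0, 0)
    axis[perp] <- 1
    axis <- axis - sum(axis * a) * a
    r <- rot_axis_angle(axis, 180)
  } else if (d > 1 - 1e-12) {
    r <- diag(3)
  } else {
    axis <- c(a[2] * b[3] - a[3] * b[2],
              a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
    r <- rot_axis_angle(axis, acos(max(-1, min(1, d))) * 180 / pi)
  }
  tr <- as.numeric(landmark_fixed) - drop(r %*% as.numeric(landmark_moving))
  t <- rigid_transform(r, tr, from = from, to = to)
  registration_result(t, 0, 0, 1L, "fast")
}

#' ICP settings
#'
#' @param max_iter maximum ICP iterations.
#' @param tol stop when the change in rms residual falls below this (mm).
#' @param trim_fraction fraction of worst correspondences dropped each
#'   iteration (0 disables trimming).
#' @param initial optional `rigid_transform` initial guess (default identity).
#' @param max_angle_deg orientation gate for trajectory registration: a
#'   candidate correspondence is rejected when the angle between the tool
#'   pointing axis and the local centerline running direction exceeds this.
#' @param min_samples minimum number of trajectory samples required.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iter = 100L, tol = 1e-6, trim_fraction = 0,
                       initial = NULL, max_angle_deg = 60, min_samples = 10L) {
  stopifnot(max_iter >= 1L, tol >= 0, trim_fraction >= 0, trim_fraction < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 trim_fraction = trim_fraction, initial = initial,
                 max_angle_deg = max_angle_deg,
                 min_samples = as.integer(min_samples)),
            class = "icp_params")
}

# Concatenate polylines into segment endpoint arrays plus unit tangents.
polyline_segments <- function(polylines) {
  a <- list(); b <- list(); pid <- list()
  for (k in seq_along(polylines)) {
    p <- polylines[[k]]$points
    a[[k]] <- p[-nrow(p), , drop = FALSE]
    b[[k]] <- p[-1L, , drop = FALSE]
    pid[[k]] <- rep(k, nrow(p) - 1L)
  }
  a <- do.call(rbind, a)
  b <- do.call(rbind, b)
  d <- b - a
  len <- sqrt(rowSums(d^2))
  list(a = a, b = b, tangent = d / len, length = len,
       polyline = unlist(pid))
}

# For each point the closest point on any segment (optionally restricted by
# an orientation gate), chunked to bound memory. Returns closest points,
# distances and the index of the chosen segment (NA when gated out).
closest_on_segments <- function(pts, seg, gate_cos = NULL, axes = NULL,
                                chunk = 256L) {
  n <- nrow(pts)
  s <- nrow(seg$a)
  cp <- matrix(NA_real_, n, 3L)
  dist <- rep(Inf, n)
  segidx <- rep(NA_integer_, n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    p <- pts[lo:hi, , drop = FALSE]
    m <- hi - lo + 1L
    # t* = clamp((p-a).d / |d|^2), per point x segment
    tx <- (outer(p[, 1], seg$a[, 1], "-") * rep(seg$tangent[, 1], each = m) +
           outer(p[, 2], seg$a[, 2], "-") * rep(seg$tangent[, 2], each = m) +
           outer(p[, 3], seg$a[, 3], "-") * rep(seg$tangent[, 3], each = m))
    tx <- pmin(pmax(tx, 0), rep(seg$length, each = m))
    qx <- rep(seg$a[, 1], each = m) + tx * rep(seg$tangent[, 1], each = m)
    qy <- rep(seg$a[, 2], each = m) + tx * rep(seg$tangent[, 2], each = m)
    qz <- rep(seg$a[, 3], each = m) + tx * rep(seg$tangent[, 3], each = m)
    d2 <- (qx - p[, 1])^2 + (qy - p[, 2])^2 + (qz - p[, 3])^2
    if (!is.null(gate_cos)) {
      ca <- axes[lo:hi, , drop = FALSE] %*% t(seg$tangent)
      d2[ca < gate_cos] <- Inf
    }
    dim(d2) <- c(m, s)
    j <- max.col(-d2, ties.method = "first")
    best <- d2[cbind(seq_len(m), j)]
    ok <- is.finite(best)
    rows <- (lo:hi)[ok]
    jok <- j[ok]
    iok <- which(ok)
    cp[rows, ] <- cbind(qx[cbind(iok, jok)], qy[cbind(iok, jok)],
                        qz[cbind(iok, jok)])
    dist[rows] <- sqrt(best[ok])
    segidx[rows] <- jok
  }
  list(point = cp, dist = dist, segment = segidx)
}

# Shared ICP core: moving points against fixed polylines with
# point-to-segment correspondences. `axes` (unit rows) enables the
# orientation gate. Residual sequence is forced non-increasing: an uphill
# step reverts to the previous transform and stops.
icp_core <- function(moving_pts, fixed_polylines, params,
                     axes = NULL, from = "moving", to = "fixed",
                     method = "icp_centerline") {
  seg <- polyline_segments(fixed_polylines)
  t_cur <- params$initial
  if (is.null(t_cur)) t_cur <- rigid_transform(diag(3), c(0, 0, 0), from, to)
  gate_cos <- if (!is.null(axes)) cos(params$max_angle_deg * pi / 180) else NULL
  residuals <- numeric(0)
  rms_prev <- Inf
  n_used <- 0L
  for (iter in seq_len(params$max_iter)) {
    p <- transform_points(t_cur, moving_pts)
    ax <- if (!is.null(axes)) axes %*% t(t_cur$rotation) else NULL
    cc <- closest_on_segments(p, seg, gate_cos, ax)
    keep <- which(is.finite(cc$dist))
    if (length(keep) == 0L)
      usnav_stop("no correspondences: all candidates rejected",
                 "usnav_no_correspondence")
    if (params$trim_fraction > 0 && length(keep) > 3L) {
      n_drop <- floor(params$trim_fraction * length(keep))
      if (n_drop > 0L && length(keep) - n_drop >= 3L)
        keep <- keep[order(cc$dist[keep])][seq_len(length(keep) - n_drop)]
    }
    fit <- fit_rigid(moving_pts[keep, , drop = FALSE],
                     cc$point[keep, , drop = FALSE])
    t_new <- rigid_transform(fit$rotation, fit$translation, from, to)
    p_new <- transform_points(t_new, moving_pts[keep, , drop = FALSE])
    rms <- sqrt(mean(rowSums((p_new - cc$point[keep, , drop = FALSE])^2)))
    if (rms > rms_prev) break  # uphill (possible with trimming/gating): stop
    t_cur <- t_new
    residuals <- c(residuals, rms)
    n_used <- length(keep)
    if (is.finite(rms_prev) && abs(rms_prev - rms) < params$tol) {
      rms_prev <- rms
      break
    }
    rms_prev <- rms
  }
  out <- registration_result(t_cur, residuals[length(residuals)], residuals,
                             n_used, method)
  # final correspondences (under the returned transform) for inspection
  p <- transform_points(t_cur, moving_pts)
  ax <- if (!is.null(axes)) axes %*% t(t_cur$rotation) else NULL
  cc <- closest_on_segments(p, seg, gate_cos, ax)
  out$correspondences <- data.frame(segment = cc$segment,
                                    polyline = seg$polyline[cc$segment],
                                    distance_mm = cc$dist)
  out
}

#' Centerline registration by iterative closest point
#'
#' Registers a moving centerline onto a fixed one by alternating closest
#' point correspondence and least-squares rigid fitting until the rms
#' residual converges. Correspondences are point-to-segment (orthogonal
#' projection onto the fixed polyline), so residuals do not depend on the
#' fixed line's sampling resolution.
#'
#' @param moving a `centerline` (or bare n x 3 point matrix).
#' @param fixed a `centerline` or list of centerlines.
#' @param params an [icp_params()] list.
#' @return A `registration_result` (moving -> fixed) with the residual
#'   history in `per_iteration_residuals` (non-increasing).
#' @export
icp_register_centerlines <- function(moving, fixed, params = icp_params()) {
  pts <- if (inherits(moving, "centerline")) moving$points else as.matrix(moving)
  if (inherits(fixed, "centerline")) fixed <- list(fixed)
  icp_core(pts, fixed, params)
}

#' Register a tracked trajectory to an airway centerline
#'
#' Image-to-patient registration for bronchoscopy: the recorded trajectory
#' of the tracked scope tip is matched to the airway centerline by a
#' modified ICP that uses orientation as well as position. A candidate
#' correspondence is rejected when the angle between the tip's pointing
#' axis (sensor +z) and the running direction of the centerline at the
#' candidate segment exceeds `params$max_angle_deg`; this keeps the fit out
#' of branches the scope cannot have traversed.
#'
#' @param trajectory a `pose_stream` of tip poses (>= `params$min_samples`).
#' @param airway a `centerline` or a list of centerlines (one per airway
#'   branch); tangents are used as the running direction (estimated by
#'   central differences when absent).
#' @param params an [icp_params()] list.
#' @return A `registration_result` (trajectory frame -> airway frame).
#' @export
register_trajectory_to_airway <- function(trajectory, airway,
                                          params = icp_params(trim_fraction = 0.1)) {
  stopifnot(inherits(trajectory, "pose_stream"))
  if (inherits(airway, "centerline")) airway <- list(airway)
  airway <- lapply(airway, function(cl) {
    stopifnot(inherits(cl, "centerline"))
    if (is.null(cl$tangents)) centerline(cl$points, centerline_tangents(cl))
    else cl
  })
  n <- n_poses(trajectory)
  if (n < params$min_samples)
    usnav_stop(sprintf("trajectory has %d samples, need >= %d", n,
                       params$min_samples), "usnav_invalid_input")
  axes <- t(vapply(seq_len(n), function(i)
    drop(rotation_from_quat(trajectory$quat[i, ]) %*% c(0, 0, 1)),
    numeric(3)))
  icp_core(trajectory$trans, airway, params, axes = axes,
           method = "icp_trajectory")
}

#' Landmark displacement imposed by a registration
#'
#' Quantitative registration validation: for each landmark defined in the
#' moving space, the distance it is moved by the registration transform,
#' \eqn{|T p_i - p_i|}.
#'
#' @param landmarks a `landmark_set` in the transform's `from` frame.
#' @param t a `rigid_transform`.
#' @return A list with `per_landmark` (data.frame `name`,
#'   `displacement_mm`), `mean_mm` and `max_mm`.
#' @export
evaluate_registration_displacement <- function(landmarks, t) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(t, "rigid_transform"))
  if (!identical(landmarks$frame, t$from))
    usnav_stop(sprintf("landmarks are in frame '%s' but transform maps from '%s'",
                       landmarks$frame, t$from), "usnav_frame_error")
  p <- landmarks$points
  d <- sqrt(rowSums((transform_points(t, p) - p)^2))
  list(per_landmark = data.frame(name = rownames(p), displacement_mm = unname(d),
                                 stringsAsFactors = FALSE),
       mean_mm = mean(d), max_mm = max(d))
}
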