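# Independent oracles used to cross-check the implementation, plus small
# generators for random test cases. The oracles deliberately use brute force
# or direct per-element evaluation, never the code paths they check.

# Random rotation via QR of a Gaussian matrix, sign-fixed to det +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function(from = "a", to = "b", t_scale = 10) {
  rigid_transform(random_rotation(), rnorm(3, sd = t_scale), from, to)
}

# Brute-force landmark registration: grid search over Euler angles
# (zyx convention), optimal translation by centroid matching at each grid
# node. Returns the best achievable rms on the grid.
grid_search_rigid_rms <- function(moving, fixed, max_angle_deg = 25,
                                  step_deg = 2.5) {
  angles <- seq(-max_angle_deg, max_angle_deg, by = step_deg)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  mc <- sweep(moving, 2, cm)
  fc <- sweep(fixed, 2, cf)
  best <- Inf
  for (az in angles) for (ay in angles) for (ax in angles) {
    r <- rot_axis_angle("z", az) %*% rot_axis_angle("y", ay) %*%
      rot_axis_angle("x", ax)
    rms <- sqrt(mean(rowSums((mc %*% t(r) - fc)^2)))
    if (rms < best) best <- rms
  }
  best
}

# Per-pixel polar test for a sector probe mask.
sector_mask_oracle <- function(probe) {
  rows <- probe$image_size[1]
  cols <- probe$image_size[2]
  out <- matrix(FALSE, rows, cols)
  eps <- 1e-9
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    y <- (c - probe$origin_px[2]) * probe$pixel_spacing[2]
    z <- (r - probe$origin_px[1]) * probe$pixel_spacing[1]
    if (probe$geometry_kind == "linear") {
      out[r, c] <- abs(y) <= probe$width / 2 + eps &&
        z >= probe$depth_start - eps && z <= probe$depth_end + eps
    } else {
      rad <- sqrt(y^2 + z^2)
      ang <- atan2(y, z) * 180 / pi
      out[r, c] <- rad >= probe$depth_start - eps &&
        rad <= probe$depth_end + eps && abs(ang) <= probe$width / 2 + eps
    }
  }
  out
}

# Densely sampled centerline along a set of waypoints.
polyline_centerline <- function(waypoints, step = 0.5) {
  pts <- list()
  for (i in seq_len(nrow(waypoints) - 1)) {
    a <- waypoints[i, ]
    b <- waypoints[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    s <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    if (i > 1) s <- s[-1]
    pts[[i]] <- outer(1 - s, a) + outer(s, b)
  }
  centerline(do.call(rbind, pts))
}

# Pose stream whose tip pointing axis (sensor +z) follows given tangents.
make_trajectory <- function(points, tangents, from = "tool", to = "ct") {
  poses <- lapply(seq_len(nrow(points)), function(i) {
    z <- tangents[i, ] / sqrt(sum(tangents[i, ]^2))
    ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    x <- ref - sum(ref * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    rigid_transform(cbind(x, y, z), points[i, ], from, to)
  })
  pose_stream(seq_len(nrow(points)) * 40, poses)
}

# Voxelized tube volume: TRUE where within `radius` of any of the segments.
tube_volume <- function(segments, radius, spacing, lo, hi) {
  dims <- as.integer(round((hi - lo) / spacing)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  g <- expand.grid(x = gx, y = gy, z = gz)
  inside <- rep(FALSE, nrow(g))
  for (s in segments) {
    d <- s$b - s$a
    len2 <- sum(d^2)
    t <- ((g$x - s$a[1]) * d[1] + (g$y - s$a[2]) * d[2] +
            (g$z - s$a[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- s$a[1] + t * d[1]; qy <- s$a[2] + t * d[2]; qz <- s$a[3] + t * d[3]
    inside <- inside | ((g$x - qx)^2 + (g$y - qy)^2 + (g$z - qz)^2 <= radius^2)
  }
  us_volume(array(inside, dims), spacing, origin = lo)
}
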