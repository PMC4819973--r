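# Freehand 3D ultrasound reconstruction: probe model with sector clipping,
# temporal calibration / pose assignment, and pixel-nearest-neighbour (PNN)
# compounding of tracked 2D frames into an axis-aligned voxel volume.
#
# Image-plane frame convention (right handed):
#   x = elevation (scan-plane normal), y = azimuth (lateral, columns),
#   z = radial (depth, rows). A pixel (row, col) maps to
#   (0, (col - origin_px[2]) * pixel_spacing[2], (row - origin_px[1]) * pixel_spacing[1]).

#' Construct an ultrasound probe model
#'
#' Describes the probe geometry used for sector clipping, the pixel-to-mm
#' scaling, the spatial calibration (image plane -> tracking sensor) and the
#' temporal calibration (offset added to frame timestamps to align the image
#' clock with the tracker clock).
#'
#' @param geometry_kind `"linear"` or `"sector"`.
#' @param width lateral width in mm (linear) or full sector angle in degrees
#'   (sector).
#' @param depth_start,depth_end imaging depth range in mm, measured from the
#'   beam origin; `depth_end > depth_start >= 0`.
#' @param pixel_spacing `c(row_mm, col_mm)` per pixel, both > 0.
#' @param image_size `c(rows, cols)`.
#' @param origin_px pixel coordinate `c(row, col)` of the beam origin
#'   (1-based, may be fractional or outside the raster).
#' @param calibration `rigid_transform` from the image-plane frame to the
#'   sensor frame.
#' @param temporal_offset milliseconds added to frame timestamps.
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(geometry_kind = c("linear", "sector"), width,
                        depth_start, depth_end, pixel_spacing, image_size,
                        origin_px, calibration = identity_transform("image", "sensor"),
                        temporal_offset = 0) {
  geometry_kind <- match.arg(geometry_kind)
  pixel_spacing <- as.numeric(pixel_spacing)
  image_size <- as.integer(image_size)
  if (any(pixel_spacing <= 0) || length(pixel_spacing) != 2L)
    usnav_stop("pixel_spacing must be two positive numbers", "usnav_invalid_input")
  if (any(image_size <= 0L) || length(image_size) != 2L)
    usnav_stop("image_size must be two positive integers", "usnav_invalid_input")
  if (!(depth_end > depth_start) || depth_start < 0)
    usnav_stop("need depth_end > depth_start >= 0", "usnav_invalid_input")
  if (width <= 0) usnav_stop("width must be positive", "usnav_invalid_input")
  stopifnot(inherits(calibration, "rigid_transform"))
  structure(list(geometry_kind = geometry_kind, width = width,
                 depth_start = depth_start, depth_end = depth_end,
                 pixel_spacing = pixel_spacing, image_size = image_size,
                 origin_px = as.numeric(origin_px), calibration = calibration,
                 temporal_offset = temporal_offset),
            class = "probe_model")
}

#' Construct a 2D ultrasound frame
#' @param pixels rows x cols numeric matrix of intensities (0-255 scale).
#' @param timestamp_ms acquisition time in milliseconds.
#' @return An object of class `us_frame`.
#' @export
us_frame <- function(pixels, timestamp_ms) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)))
    usnav_stop("frame intensities must be finite", "usnav_invalid_input")
  structure(list(pixels = pixels, timestamp_ms = as.numeric(timestamp_ms)),
            class = "us_frame")
}

# In-plane (azimuth y, radial z) coordinates of pixel centres, mm.
pixel_plane_coords <- function(probe, rows = seq_len(probe$image_size[1L]),
                               cols = seq_len(probe$image_size[2L])) {
  list(y = (cols - probe$origin_px[2L]) * probe$pixel_spacing[2L],
       z = (rows - probe$origin_px[1L]) * probe$pixel_spacing[1L])
}

#' Imaging-sector mask for a probe
#'
#' Marks the pixels that lie inside the imaging sector, so invalid parts of
#' the raster (outside the beam) can be clipped away before reconstruction.
#' Linear probes keep pixels within the lateral half-width and depth range;
#' sector probes keep pixels within the angular half-width and radial depth
#' range measured from the beam origin.
#'
#' @param probe a `probe_model`.
#' @return Logical rows x cols matrix, `TRUE` inside the sector.
#' @export
sector_mask <- function(probe) {
  stopifnot(inherits(probe, "probe_model"))
  pc <- pixel_plane_coords(probe)
  y <- matrix(pc$y, probe$image_size[1L], probe$image_size[2L], byrow = TRUE)
  z <- matrix(pc$z, probe$image_size[1L], probe$image_size[2L])
  eps <- 1e-9
  if (probe$geometry_kind == "linear") {
    abs(y) <= probe$width / 2 + eps &
      z >= probe$depth_start - eps & z <= probe$depth_end + eps
  } else {
    r <- sqrt(y^2 + z^2)
    ang <- atan2(y, z) * 180 / pi
    r >= probe$depth_start - eps & r <= probe$depth_end + eps &
      abs(ang) <= probe$width / 2 + eps
  }
}

#' Map an image pixel to reference-frame coordinates
#'
#' Applies the full chain pixel -> mm scaling, spatial calibration
#' (image -> sensor), then the sensor pose (sensor -> tracker/reference).
#'
#' @param probe a `probe_model`.
#' @param sensor_pose `rigid_transform`, sensor frame -> reference frame.
#' @param pixel `c(row, col)` (1-based) or an n x 2 matrix of pixels.
#' @return 3-vector or n x 3 matrix of reference coordinates (mm).
#' @export
pixel_to_reference <- function(probe, sensor_pose, pixel) {
  stopifnot(inherits(probe, "probe_model"), inherits(sensor_pose, "rigid_transform"))
  vec <- is.null(dim(pixel))
  px <- if (vec) matrix(as.numeric(pixel), 1L, 2L) else as.matrix(pixel)
  if (any(px[, 1L] < 1 - 1e-9) || any(px[, 1L] > probe$image_size[1L] + 1e-9) ||
      any(px[, 2L] < 1 - 1e-9) || any(px[, 2L] > probe$image_size[2L] + 1e-9))
    usnav_stop("pixel outside image bounds", "usnav_invalid_input")
  p_img <- cbind(0,
                 (px[, 2L] - probe$origin_px[2L]) * probe$pixel_spacing[2L],
                 (px[, 1L] - probe$origin_px[1L]) * probe$pixel_spacing[1L])
  chain <- compose(sensor_pose, probe$calibration)
  out <- transform_points(chain, p_img)
  if (vec) drop(out) else out
}

#' Assign tracker poses to ultrasound frames
#'
#' Interpolates the pose stream at each frame's timestamp shifted by the
#' probe's temporal calibration offset. Frames whose shifted timestamp falls
#' outside the stream range are dropped (never extrapolated); the dropped
#' count is reported via a message and the `n_dropped` attribute.
#'
#' @param frames list of `us_frame`.
#' @param stream a `pose_stream` (sensor -> reference).
#' @param probe a `probe_model` (supplies `temporal_offset`).
#' @return List of `rigid_transform`, one per kept frame, with attributes
#'   `frame_indices` (indices of kept frames) and `n_dropped`.
#' @export
assign_frame_poses <- function(frames, stream, probe) {
  stopifnot(inherits(stream, "pose_stream"), inherits(probe, "probe_model"))
  ts <- vapply(frames, function(f) f$timestamp_ms, numeric(1)) +
    probe$temporal_offset
  rng <- range(stream$t_ms)
  keep <- which(ts >= rng[1L] & ts <= rng[2L])
  if (length(keep) < length(frames))
    message(sprintf("assign_frame_poses: dropped %d/%d frame(s) outside pose stream range",
                    length(frames) - length(keep), length(frames)))
  poses <- lapply(keep, function(i) interpolate_pose(stream, ts[i]))
  attr(poses, "frame_indices") <- keep
  attr(poses, "n_dropped") <- length(frames) - length(keep)
  poses
}

#' Construct a 3D scalar volume
#'
#' @param voxels 3D array (x fastest-varying dimension first).
#' @param spacing voxel spacing, scalar or 3-vector mm.
#' @param origin centre of voxel (1,1,1) in the reference frame, mm.
#' @param frame reference frame label.
#' @param fill_mask logical array marking voxels that received data directly
#'   (before hole filling); defaults to all `TRUE`.
#' @param data_mask logical array marking voxels carrying data after hole
#'   filling; defaults to `fill_mask`.
#' @return An object of class `us_volume`.
#' @export
us_volume <- function(voxels, spacing, origin = c(0, 0, 0), frame = "reference",
                      fill_mask = NULL, data_mask = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    usnav_stop("voxels must be a 3D array", "usnav_invalid_input")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) usnav_stop("spacing must be positive", "usnav_invalid_input")
  if (is.null(fill_mask)) fill_mask <- array(TRUE, dim(voxels))
  if (is.null(data_mask)) data_mask <- fill_mask
  if (!all(dim(fill_mask) == dim(voxels)) || !all(dim(data_mask) == dim(voxels)))
    usnav_stop("masks must match the voxel grid", "usnav_invalid_input")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), frame = as.character(frame),
                 fill_mask = fill_mask, data_mask = data_mask),
            class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("<us_volume %s: %s voxels @ %s mm, origin (%s), %.1f%% filled>\n",
              x$frame, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", "),
              100 * mean(x$fill_mask)))
  invisible(x)
}

#' Voxel-centre coordinates of a volume
#' @param vol a `us_volume`.
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(vol, idx) {
  sweep(sweep(as.matrix(idx) - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

# Spherical neighbourhood offsets within `radius` voxels, excluding centre.
sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9 &
           !(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g)
}

#' Pixel-nearest-neighbour reconstruction of a freehand sweep
#'
#' Forward-maps every unmasked pixel of every frame into the reference frame
#' (via the probe calibration and the frame's sensor pose) and bins it to
#' its nearest voxel. Voxels receiving several contributions store their
#' mean, which makes the result independent of frame order. Remaining holes
#' (unfilled voxels with at least one filled neighbour within
#' `hole_fill_radius` voxels) are then filled with the mean of their filled
#' neighbours in a single pass. The volume is axis-aligned with the
#' reference frame and tightly bounds the mapped pixels plus one voxel of
#' padding.
#'
#' @param frames list of `us_frame`.
#' @param poses list of `rigid_transform` (sensor -> reference), e.g. from
#'   [assign_frame_poses()]; a `frame_indices` attribute, when present,
#'   selects the matching frames.
#' @param probe a `probe_model`.
#' @param spacing output voxel spacing in mm; default is the maximum
#'   in-plane pixel spacing (avoids aliasing holes).
#' @param hole_fill_radius neighbourhood radius in voxels for hole filling.
#' @return A `us_volume`; `fill_mask` records pre-fill coverage.
#' @export
reconstruct_pnn <- function(frames, poses, probe, spacing = NULL,
                            hole_fill_radius = 1) {
  stopifnot(inherits(probe, "probe_model"))
  fi <- attr(poses, "frame_indices")
  if (!is.null(fi)) frames <- frames[fi]
  if (length(frames) == 0L || length(frames) != length(poses))
    usnav_stop("need matching non-empty frames and poses", "usnav_empty_input")
  if (is.null(spacing)) spacing <- max(probe$pixel_spacing)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) usnav_stop("spacing must be positive", "usnav_invalid_input")

  mask <- sector_mask(probe)
  if (!any(mask))
    usnav_stop("probe mask removes every pixel", "usnav_empty_input")
  pc <- pixel_plane_coords(probe)
  ymat <- matrix(pc$y, probe$image_size[1L], probe$image_size[2L], byrow = TRUE)
  zmat <- matrix(pc$z, probe$image_size[1L], probe$image_size[2L])
  p_img <- cbind(0, ymat[mask], zmat[mask])

  pts <- vector("list", length(frames))
  vals <- vector("list", length(frames))
  ref_frame <- poses[[1L]]$to
  for (i in seq_along(frames)) {
    chain <- compose(poses[[i]], probe$calibration)
    pts[[i]] <- transform_points(chain, p_img)
    vals[[i]] <- frames[[i]]$pixels[mask]
  }
  pts <- do.call(rbind, pts)
  vals <- unlist(vals, use.names = FALSE)

  lo <- apply(pts, 2L, min) - spacing
  hi <- apply(pts, 2L, max)
  dims <- pmax(as.integer(round((hi - lo) / spacing)) + 2L, 2L)
  idx <- round(sweep(sweep(pts, 2L, lo), 2L, spacing, "/")) + 1
  lin <- as.integer(idx[, 1L] + dims[1L] * ((idx[, 2L] - 1) +
                                              dims[2L] * (idx[, 3L] - 1)))
  acc <- rowsum(cbind(vals, 1), lin)
  where <- as.integer(rownames(acc))
  sums <- numeric(prod(dims)); cnts <- numeric(prod(dims))
  sums[where] <- acc[, 1L]
  cnts[where] <- acc[, 2L]
  dim(sums) <- dims; dim(cnts) <- dims
  fill <- cnts > 0
  vox <- array(0, dims)
  vox[fill] <- sums[fill] / cnts[fill]

  data_mask <- fill
  if (hole_fill_radius > 0) {
    offs <- sphere_offsets(hole_fill_radius)
    nsum <- array(0, dims); ncnt <- array(0, dims)
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      dst <- list(max(1, 1 - o[1]):min(dims[1], dims[1] - o[1]),
                  max(1, 1 - o[2]):min(dims[2], dims[2] - o[2]),
                  max(1, 1 - o[3]):min(dims[3], dims[3] - o[3]))
      src <- list(dst[[1]] + o[1], dst[[2]] + o[2], dst[[3]] + o[3])
      nsum[dst[[1]], dst[[2]], dst[[3]]] <-
        nsum[dst[[1]], dst[[2]], dst[[3]]] +
        vox[src[[1]], src[[2]], src[[3]]] * fill[src[[1]], src[[2]], src[[3]]]
      ncnt[dst[[1]], dst[[2]], dst[[3]]] <-
        ncnt[dst[[1]], dst[[2]], dst[[3]]] +
        fill[src[[1]], src[[2]], src[[3]]]
    }
    holes <- !fill & ncnt > 0
    vox[holes] <- nsum[holes] / ncnt[holes]
    data_mask <- fill | holes
  }

  us_volume(vox, spacing, origin = lo, frame = ref_frame,
            fill_mask = fill, data_mask = data_mask)
}
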