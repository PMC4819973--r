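# Automatic navigation system accuracy (NSA) evaluation with a wire-cross
# phantom: segmentation of the wires from a reconstructed sweep volume,
# 3D binary-thinning centerline extraction, modified ICP registration of the
# extracted centerlines to the nominal (gold standard) cross, and the
# displacement at the cross point as the NSA. Also the stochastic
# error-budget combiner E = sqrt(sum(e_i^2)) and acquisition summaries.

#' Construct a wire-cross phantom model
#'
#' Two straight wire segments whose infinite lines intersect; the gold
#' standard of the accuracy test. Wires are 1 mm diameter by default.
#'
#' @param wires list of two wires, each `list(center, direction, half_length)`
#'   with `direction` a unit 3-vector and lengths in mm.
#' @param wire_diameter wire diameter in mm.
#' @param frame coordinate frame label.
#' @return An object of class `wire_cross_model`.
#' @seealso [make_wire_cross()] for the parametric constructor.
#' @export
wire_cross_model <- function(wires, wire_diameter = 1.0, frame = "reference") {
  if (length(wires) != 2L)
    usnav_stop("a wire cross has exactly two wires", "usnav_invalid_input")
  wires <- lapply(wires, function(w) {
    w$center <- as.numeric(w$center)
    w$direction <- as.numeric(w$direction)
    nrm <- sqrt(sum(w$direction^2))
    if (abs(nrm - 1) > 1e-6)
      usnav_stop("wire directions must be unit vectors", "usnav_invalid_input")
    w$direction <- w$direction / nrm
    if (w$half_length <= 0)
      usnav_stop("wire half_length must be positive", "usnav_invalid_input")
    w
  })
  model <- structure(list(wires = wires, wire_diameter = wire_diameter,
                          frame = as.character(frame)),
                     class = "wire_cross_model")
  cp <- line_pair_closest(wires[[1L]], wires[[2L]])
  if (cp$gap > 1e-6)
    usnav_stop(sprintf("wire lines do not intersect (gap %.3g mm)", cp$gap),
               "usnav_invalid_input")
  model
}

# Closest approach of two infinite lines: midpoint and gap.
line_pair_closest <- function(w1, w2) {
  d1 <- w1$direction; d2 <- w2$direction
  r <- w1$center - w2$center
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  d <- sum(d1 * r); e <- sum(d2 * r)
  den <- a * c - b * b
  if (abs(den) < 1e-12)
    usnav_stop("wires are parallel", "usnav_invalid_input")
  s <- (b * e - c * d) / den
  t <- (a * e - b * d) / den
  p1 <- w1$center + s * d1
  p2 <- w2$center + t * d2
  list(point = (p1 + p2) / 2, gap = sqrt(sum((p1 - p2)^2)))
}

#' Cross point of a wire-cross model
#' @param model a `wire_cross_model`.
#' @return 3-vector (mm), the intersection of the two wire lines.
#' @export
cross_point <- function(model) {
  stopifnot(inherits(model, "wire_cross_model"))
  line_pair_closest(model$wires[[1L]], model$wires[[2L]])$point
}

#' Sample the nominal wire-cross centerlines
#'
#' @param model a `wire_cross_model`.
#' @param step_mm sampling step along each wire (default 0.1 mm, below any
#'   practical voxel spacing).
#' @return List of two `centerline` objects with tangents.
#' @export
nominal_centerlines <- function(model, step_mm = 0.1) {
  stopifnot(inherits(model, "wire_cross_model"), step_mm > 0)
  lapply(model$wires, function(w) {
    s <- seq(-w$half_length, w$half_length, by = step_mm)
    if (s[length(s)] < w$half_length) s <- c(s, w$half_length)
    pts <- outer(s, w$direction) + matrix(w$center, length(s), 3L, byrow = TRUE)
    centerline(pts, matrix(w$direction, length(s), 3L, byrow = TRUE))
  })
}

#' Segment the wires from a reconstructed volume
#'
#' Thresholds at a fraction of the maximum originally-filled intensity and
#' keeps the largest 26-connected component. Hole-filled voxels are eligible
#' for segmentation (so the wire stays solid), but the threshold reference
#' is the maximum over voxels that received data directly.
#'
#' @param vol a `us_volume` with at least one filled voxel.
#' @param threshold_fraction fraction in (0, 1) of the maximum filled
#'   intensity.
#' @return A `us_volume` with logical voxels (the segmentation).
#' @export
segment_wires <- function(vol, threshold_fraction = 0.5) {
  stopifnot(inherits(vol, "us_volume"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    usnav_stop("threshold_fraction must be in (0, 1)", "usnav_invalid_input")
  if (!any(vol$fill_mask))
    usnav_stop("volume has no filled voxels", "usnav_empty_input")
  thr <- threshold_fraction * max(vol$voxels[vol$fill_mask])
  bin <- vol$data_mask & vol$voxels >= thr
  if (!any(bin))
    usnav_stop("segmentation is empty: no voxel reaches the threshold",
               "usnav_empty_segmentation")
  lab <- label3d_cpp(bin, dim(bin))
  keep <- lab == 1L
  us_volume(keep, vol$spacing, vol$origin, vol$frame,
            fill_mask = keep, data_mask = keep)
}

#' Extract centerlines from a binary volume by 3D thinning
#'
#' Topological (simple-point) thinning reduces the binary object to a
#' unit-width voxel skeleton that preserves connectivity; the skeleton is
#' then traced into ordered polylines, splitting at branch points. Points
#' are reported in reference-frame millimetres.
#'
#' @param binary a `us_volume` with logical voxels.
#' @return List of `centerline` objects.
#' @export
extract_centerline <- function(binary) {
  stopifnot(inherits(binary, "us_volume"))
  b <- binary$voxels
  storage.mode(b) <- "logical"
  if (!any(b))
    usnav_stop("binary volume is empty", "usnav_empty_input")
  skel <- thin3d_cpp(b, dim(b))
  vox <- which(skel, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0L)
    usnav_stop("thinning removed every voxel", "usnav_empty_segmentation")
  dims <- dim(b)
  lin <- vox[, 1L] + dims[1L] * ((vox[, 2L] - 1) + dims[2L] * (vox[, 3L] - 1))
  row_of <- integer(prod(dims))
  row_of[lin] <- seq_len(n)
  offs <- sphere_offsets(sqrt(3) + 1e-6)  # 26-neighbourhood
  adj <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ni <- vox[, 1L] + o[1L]; nj <- vox[, 2L] + o[2L]; nk <- vox[, 3L] + o[3L]
    ok <- ni >= 1 & nj >= 1 & nk >= 1 &
      ni <= dims[1L] & nj <= dims[2L] & nk <= dims[3L]
    nlin <- ni[ok] + dims[1L] * ((nj[ok] - 1) + dims[2L] * (nk[ok] - 1))
    hit <- row_of[nlin]
    src <- which(ok)[hit > 0L]
    hit <- hit[hit > 0L]
    for (ii in seq_along(src)) adj[[src[ii]]] <- c(adj[[src[ii]]], hit[ii])
  }
  deg <- lengths(adj)
  pts_mm <- voxel_centers(binary, vox)

  used <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  polylines <- list()
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(edge_key(start, nxt), TRUE, envir = used)
    prev <- start; cur <- nxt
    while (deg[cur] == 2L) {
      nb <- adj[[cur]]
      nxt2 <- nb[nb != prev]
      if (length(nxt2) == 0L) break
      nxt2 <- nxt2[1L]
      if (!is.null(used[[edge_key(cur, nxt2)]])) break
      assign(edge_key(cur, nxt2), TRUE, envir = used)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }
  terminals <- which(deg != 2L & deg > 0L)
  for (s in terminals) {
    for (nb in adj[[s]]) {
      if (is.null(used[[edge_key(s, nb)]])) {
        path <- walk(s, nb)
        polylines[[length(polylines) + 1L]] <- path
      }
    }
  }
  # pure cycles (no terminal): start anywhere
  for (s in which(deg == 2L)) {
    for (nb in adj[[s]]) {
      if (is.null(used[[edge_key(s, nb)]])) {
        path <- walk(s, nb)
        polylines[[length(polylines) + 1L]] <- path
      }
    }
  }
  lapply(polylines, function(p) centerline(pts_mm[p, , drop = FALSE]))
}

#' NSA evaluation parameters
#'
#' @param threshold_fraction segmentation threshold, fraction of max filled
#'   intensity.
#' @param sample_step_mm sampling step of the nominal centerlines.
#' @param icp ICP settings; the default enables 10% worst-correspondence
#'   trimming (the "modified" element of the ICP).
#' @param probe_pose optional `rigid_transform` (image plane -> reference)
#'   used to decompose the displacement into probe-frame components.
#' @return A list of class `nsa_params`.
#' @export
nsa_params <- function(threshold_fraction = 0.5, sample_step_mm = 0.1,
                       icp = icp_params(trim_fraction = 0.1),
                       probe_pose = NULL) {
  structure(list(threshold_fraction = threshold_fraction,
                 sample_step_mm = sample_step_mm, icp = icp,
                 probe_pose = probe_pose),
            class = "nsa_params")
}

#' Navigation system accuracy from a reconstructed wire-cross volume
#'
#' Runs the automatic accuracy pipeline: segmentation of the wire cross from
#' the ultrasound volume, centerline extraction by 3D thinning, and modified
#' ICP registration of the extracted centerlines to the nominal model's
#' centerline representation. The displacement imposed by that registration,
#' evaluated at the nominal cross point (so rotational misalignment is
#' captured where accuracy matters), is the NSA; its magnitude is the
#' headline number.
#'
#' @param reconstructed a `us_volume` from a sweep over the phantom.
#' @param nominal a `wire_cross_model` (the accurately measured gold
#'   standard).
#' @param params an [nsa_params()] list.
#' @return An object of class `nsa_result` with fields `displacement` (mm,
#'   reconstructed -> nominal at the cross point), `magnitude`,
#'   `probe_frame_components` (elevation, azimuth, radial; `NULL` without a
#'   probe pose), `residual_rms` and `per_iteration_residuals`.
#' @export
compute_nsa <- function(reconstructed, nominal, params = nsa_params()) {
  stopifnot(inherits(reconstructed, "us_volume"),
            inherits(nominal, "wire_cross_model"))
  seg <- segment_wires(reconstructed, params$threshold_fraction)
  cls <- extract_centerline(seg)
  moving <- do.call(rbind, lapply(cls, function(cl) cl$points))
  fixed <- nominal_centerlines(nominal, params$sample_step_mm)
  reg <- icp_core(moving, fixed, params$icp,
                  from = reconstructed$frame, to = nominal$frame,
                  method = "icp_nsa")
  cp <- cross_point(nominal)
  disp <- drop(transform_points(reg$transform, cp)) - cp
  comps <- if (!is.null(params$probe_pose))
    decompose_nsa(disp, params$probe_pose) else NULL
  structure(list(displacement = disp, magnitude = sqrt(sum(disp^2)),
                 probe_frame_components = comps,
                 residual_rms = reg$rms_residual,
                 per_iteration_residuals = reg$per_iteration_residuals,
                 n_centerline_points = nrow(moving),
                 registration = reg),
            class = "nsa_result")
}

#' @export
print.nsa_result <- function(x, ...) {
  cat(sprintf("<nsa_result: NSA %.3f mm, displacement (%s) mm, icp rms %.3f mm>\n",
              x$magnitude, paste(sprintf("%.3f", x$displacement), collapse = ", "),
              x$residual_rms))
  if (!is.null(x$probe_frame_components))
    cat(sprintf("  probe-frame components (elev, azim, radial): %s mm\n",
                paste(sprintf("%.3f", x$probe_frame_components), collapse = ", ")))
  invisible(x)
}

#' Decompose a displacement into scan-plane components
#'
#' Expresses an NSA displacement vector in the reference frame of the
#' ultrasound scan plane: elevation (x, the plane normal), azimuth (y,
#' lateral in-plane) and radial (z, depth in-plane). The component vector is
#' an orthonormal re-expression, so its norm equals the displacement norm.
#'
#' @param displacement 3-vector, mm, in the reference frame.
#' @param probe_pose `rigid_transform` from the image-plane frame to the
#'   reference frame.
#' @return Named numeric vector `c(elevation, azimuth, radial)` in mm.
#' @export
decompose_nsa <- function(displacement, probe_pose) {
  stopifnot(inherits(probe_pose, "rigid_transform"))
  d <- as.numeric(displacement)
  comps <- drop(t(probe_pose$rotation) %*% d)
  names(comps) <- c("elevation", "azimuth", "radial")
  comps
}

#' Construct an error budget
#'
#' @param magnitudes named or unnamed numeric vector of independent error
#'   magnitudes, mm, all finite and non-negative.
#' @return An object of class `error_budget`.
#' @export
error_budget <- function(magnitudes) {
  magnitudes <- unlist(magnitudes)
  if (length(magnitudes) && (!all(is.finite(magnitudes)) || any(magnitudes < 0)))
    usnav_stop("error magnitudes must be finite and >= 0", "usnav_invalid_input")
  nm <- names(magnitudes)
  if (is.null(nm))
    nm <- if (length(magnitudes)) paste0("component_", seq_along(magnitudes))
    else character(0)
  structure(list(components = data.frame(name = nm,
                                         magnitude_mm = as.numeric(magnitudes),
                                         stringsAsFactors = FALSE)),
            class = "error_budget")
}

#' Root-sum-of-squares combination of independent error sources
#'
#' Stochastically independent error contributions combine as
#' \eqn{E = \sqrt{\sum_i e_i^2}}, not as their plain sum; the result always
#' lies between the largest single component and the arithmetic sum.
#'
#' @param budget an `error_budget` or a bare numeric vector of magnitudes.
#' @return The combined error E in mm.
#' @examples
#' rss_error_budget(c(1.0, 0.5, 0.1))            # laboratory chain
#' rss_error_budget(c(1.0, 0.5, 0.1, 2.0, 10.0)) # worst-case clinical chain
#' @export
rss_error_budget <- function(budget) {
  if (!inherits(budget, "error_budget")) budget <- error_budget(budget)
  e <- budget$components$magnitude_mm
  if (length(e) == 0L)
    usnav_stop("error budget is empty", "usnav_empty_input")
  sqrt(sum(e^2))
}

# One-decimal reporting rule: round half away from zero.
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarise NSA acquisitions by group
#'
#' Mean and sample standard deviation (n - 1 denominator) of NSA magnitudes
#' per acquisition group plus an overall row.
#'
#' @param results list of `nsa_result` objects or a numeric vector of NSA
#'   magnitudes (mm).
#' @param groups character vector of group labels, one per result.
#' @return data.frame with columns `group`, `n`, `mean_mm`, `sd_mm`; the
#'   last row (`all`) pools every acquisition.
#' @export
summarize_acquisitions <- function(results, groups = NULL) {
  mags <- if (is.numeric(results)) as.numeric(results)
  else vapply(results, function(r) r$magnitude, numeric(1))
  if (length(mags) == 0L)
    usnav_stop("no acquisitions to summarise", "usnav_empty_input")
  if (is.null(groups)) groups <- rep("all", length(mags))
  groups <- as.character(groups)
  if (length(groups) != length(mags))
    usnav_stop("one group label per result required", "usnav_invalid_input")
  one <- function(g, m) data.frame(group = g, n = length(m), mean_mm = mean(m),
                                   sd_mm = if (length(m) > 1L) sd(m) else NA_real_,
                                   stringsAsFactors = FALSE)
  out <- do.call(rbind, c(
    lapply(unique(groups), function(g) one(g, mags[groups == g])),
    list(one("all", mags))))
  rownames(out) <- NULL
  out
}
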