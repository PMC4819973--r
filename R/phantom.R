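# Synthetic phantom and sweep simulator: a 1-mm wire cross in a water tank,
# a tracked linear-probe sweep over it, and controlled error injection
# (calibration offset, tracking jitter, sound-speed scale, latency). This is
# the test harness for the reconstruction and NSA pipeline: zero injection
# must come back as (near) zero NSA, and injected offsets must be recovered.
#
# Default geometry (the simulated study conditions): 40 mm wire arms
# crossing at 90 degrees in the middle of a 100 mm water tank, cross point
# 42 mm below the probe face, linear probe imaging 30-55.4 mm depth so a
# 16 mm sweep yields a desk-scale volume (about 100x130x140 voxels at
# 0.2 mm spacing).

#' Parametric wire-cross phantom
#'
#' Two wires of equal arm length crossing at a given angle in the horizontal
#' plane through `center` (wire 1 along +x, wire 2 rotated by
#' `crossing_angle` about the vertical axis).
#'
#' @param arm_length half-length of each wire from the cross point, mm.
#' @param crossing_angle angle between the wires, degrees, in (0, 180).
#' @param center cross point in the reference frame, mm.
#' @param wire_diameter wire diameter, mm (nominal 1.0).
#' @return A `wire_cross_model`.
#' @export
make_wire_cross <- function(arm_length = 40, crossing_angle = 90,
                            center = c(0, 0, 42), wire_diameter = 1.0) {
  if (arm_length <= 0)
    usnav_stop("arm_length must be positive", "usnav_invalid_input")
  if (crossing_angle <= 0 || crossing_angle >= 180)
    usnav_stop("crossing_angle must be in (0, 180) degrees",
               "usnav_invalid_input")
  th <- crossing_angle * pi / 180
  wire_cross_model(list(
    list(center = center, direction = c(1, 0, 0), half_length = arm_length),
    list(center = center, direction = c(cos(th), sin(th), 0),
         half_length = arm_length)),
    wire_diameter = wire_diameter)
}

#' Error injection settings for the simulator
#'
#' @param calibration_offset `rigid_transform` (image -> image) perturbing
#'   the true image-to-sensor calibration; this is the deception presented
#'   to the consumer that creates NSA error.
#' @param tracking_jitter_mm standard deviation of per-sample translational
#'   tracking noise, mm.
#' @param tracking_jitter_deg standard deviation of per-sample rotational
#'   tracking noise, degrees.
#' @param sound_speed_scale apparent-depth scale factor (1 = calibrated
#'   speed of sound; 1.05 makes echoes appear 5% deeper).
#' @param latency_ms delay between true motion and reported poses, ms.
#' @return A list of class `error_injection`.
#' @export
error_injection <- function(calibration_offset = identity_transform("image"),
                            tracking_jitter_mm = 0, tracking_jitter_deg = 0,
                            sound_speed_scale = 1, latency_ms = 0) {
  stopifnot(inherits(calibration_offset, "rigid_transform"))
  if (tracking_jitter_mm < 0 || tracking_jitter_deg < 0)
    usnav_stop("jitter SDs must be >= 0", "usnav_invalid_input")
  if (sound_speed_scale <= 0)
    usnav_stop("sound_speed_scale must be > 0", "usnav_invalid_input")
  structure(list(calibration_offset = calibration_offset,
                 tracking_jitter_mm = tracking_jitter_mm,
                 tracking_jitter_deg = tracking_jitter_deg,
                 sound_speed_scale = sound_speed_scale,
                 latency_ms = latency_ms),
            class = "error_injection")
}

#' Sweep specification
#'
#' @param direction `"along"` (probe travels along wire 1) or `"diagonal"`
#'   (along the bisector of the two wires).
#' @param towards `"front_to_back"` or `"back_to_front"` (sweep sense).
#' @param span_mm total travel, centred over the cross point.
#' @param n_frames number of frames (>= 2).
#' @param frame_rate frames per second.
#' @param seed integer seed for all randomness of this acquisition.
#' @return A list of class `sweep_spec`; `direction_label` combines the two
#'   direction fields.
#' @export
sweep_spec <- function(direction = c("along", "diagonal"),
                       towards = c("front_to_back", "back_to_front"),
                       span_mm = 16, n_frames = 96, frame_rate = 20, seed = 1L) {
  direction <- match.arg(direction)
  towards <- match.arg(towards)
  if (n_frames < 2L) usnav_stop("n_frames must be >= 2", "usnav_invalid_input")
  if (frame_rate <= 0) usnav_stop("frame_rate must be > 0", "usnav_invalid_input")
  structure(list(direction = direction, towards = towards, span_mm = span_mm,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 seed = as.integer(seed),
                 direction_label = paste(direction, towards, sep = "_")),
            class = "sweep_spec")
}

#' Default simulated linear probe
#'
#' 128 x 120 pixel raster at 0.2 mm/px, imaging 30-55.4 mm depth over a
#' 24 mm lateral width; identity spatial calibration (image frame = sensor
#' frame) and zero temporal offset.
#'
#' @return A `probe_model`.
#' @export
default_probe <- function() {
  probe_model("linear", width = 24, depth_start = 30, depth_end = 55.4,
              pixel_spacing = c(0.2, 0.2), image_size = c(128L, 120L),
              origin_px = c(1 - 150, 60.5),
              calibration = identity_transform("image", "sensor"),
              temporal_offset = 0)
}

# Probe orientation for a sweep: image x (elevation) along the travel
# direction, image z (radial) straight down (+z), image y = z cross x.
sweep_rotation <- function(dir_vec) {
  x <- dir_vec / sqrt(sum(dir_vec^2))
  z <- c(0, 0, 1)
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y / sqrt(sum(y^2)), z)
}

sweep_direction_vector <- function(model, spec) {
  d1 <- model$wires[[1L]]$direction
  d2 <- model$wires[[2L]]$direction
  v <- if (spec$direction == "along") d1 else (d1 + d2) / sqrt(sum((d1 + d2)^2))
  if (spec$towards == "back_to_front") -v else v
}

#' Simulate a tracked ultrasound sweep over a wire-cross phantom
#'
#' Renders one frame per time step by intersecting the finite-thickness scan
#' plane with the wire cylinders: pixel intensity is water background
#' (about 5) plus a wire echo (about 200) with Gaussian cross-section
#' falloff (sigma = wire radius in-plane, half the elevation beam width
#' out-of-plane) and additive speckle-like Gaussian noise, clamped to 0-255.
#' Reported tracker poses are the true poses composed with per-sample white
#' jitter and timestamped `latency_ms` late; apparent echo depth is scaled
#' by `sound_speed_scale`; and the probe handed to the consumer carries
#' `true calibration o calibration_offset` instead of the true calibration.
#' All randomness is drawn from the single seed in `spec`.
#'
#' @param model a `wire_cross_model`.
#' @param spec a [sweep_spec()].
#' @param probe a `probe_model` (its calibration is taken as the true one).
#' @param inject an [error_injection()].
#' @param beam_width_mm elevation beam width (scan-plane thickness), mm.
#' @param echo_amplitude,background,noise_sd image-formation constants.
#' @return A list of class `simulated_acquisition` with `frames` (list of
#'   `us_frame`), `poses` (reported `pose_stream`), `probe` (the perturbed
#'   probe the consumer must use) and `truth` (model, injection, seed, true
#'   calibration, mid-sweep image-to-reference pose).
#' @export
simulate_sweep <- function(model, spec, probe = default_probe(),
                           inject = error_injection(), beam_width_mm = 1,
                           echo_amplitude = 200, background = 5, noise_sd = 2) {
  stopifnot(inherits(model, "wire_cross_model"), inherits(spec, "sweep_spec"),
            inherits(probe, "probe_model"), inherits(inject, "error_injection"))
  set.seed(spec$seed)
  dirv <- sweep_direction_vector(model, spec)
  rot <- sweep_rotation(dirv)
  cp <- cross_point(model)
  start <- c(cp[1L], cp[2L], 0) - dirv * spec$span_mm / 2
  dt <- 1000 / spec$frame_rate
  t_frames <- (seq_len(spec$n_frames) - 1L) * dt
  pos_at <- function(t) start + dirv * (t / (1000 * (spec$n_frames - 1L) / spec$frame_rate)) * spec$span_mm

  rows <- probe$image_size[1L]; cols <- probe$image_size[2L]
  pc <- pixel_plane_coords(probe)
  y <- rep(pc$y, each = rows)
  z_app <- rep(pc$z, times = cols)
  z_true <- z_app / inject$sound_speed_scale
  sigma_w <- model$wire_diameter / 2
  sigma_e <- beam_width_mm / 2

  render <- function(trans) {
    # pixel positions in the reference frame (true chain, true sound path)
    chain <- compose(rigid_transform(rot, trans, "sensor", "reference"),
                     probe$calibration)
    cr <- chain$rotation; ct <- chain$translation
    normal <- cr[, 1L]
    px <- ct[1L] + cr[1, 2L] * y + cr[1, 3L] * z_true
    py <- ct[2L] + cr[2, 2L] * y + cr[2, 3L] * z_true
    pz <- ct[3L] + cr[3, 2L] * y + cr[3, 3L] * z_true
    intensity <- rep(background, rows * cols)
    for (w in model$wires) {
      wx <- px - w$center[1L]; wy <- py - w$center[2L]; wz <- pz - w$center[3L]
      s <- wx * w$direction[1L] + wy * w$direction[2L] + wz * w$direction[3L]
      s <- pmin(pmax(s, -w$half_length), w$half_length)
      vx <- wx - s * w$direction[1L]
      vy <- wy - s * w$direction[2L]
      vz <- wz - s * w$direction[3L]
      d_out <- vx * normal[1L] + vy * normal[2L] + vz * normal[3L]
      d_in2 <- pmax(vx^2 + vy^2 + vz^2 - d_out^2, 0)
      intensity <- intensity + echo_amplitude *
        exp(-0.5 * d_in2 / sigma_w^2) * exp(-0.5 * d_out^2 / sigma_e^2)
    }
    intensity <- intensity + rnorm(rows * cols, 0, noise_sd)
    matrix(pmin(pmax(intensity, 0), 255), rows, cols)
  }

  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    frames[[k]] <- us_frame(render(pos_at(t_frames[k])), t_frames[k])
  }

  # reported pose stream: padded beyond the frame window so interpolation
  # still covers every frame after the latency shift
  pad <- max(200, abs(inject$latency_ms) + 2 * dt)
  t_samples <- seq(t_frames[1L] - pad, t_frames[spec$n_frames] + pad, by = dt)
  poses <- vector("list", length(t_samples))
  for (k in seq_along(t_samples)) {
    true_pose <- rigid_transform(rot, pos_at(t_samples[k]), "sensor", "reference")
    if (inject$tracking_jitter_mm > 0 || inject$tracking_jitter_deg > 0) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      jr <- rot_axis_angle(ax, rnorm(1, 0, inject$tracking_jitter_deg))
      jt <- rnorm(3, 0, inject$tracking_jitter_mm)
      jitter <- rigid_transform(jr, jt, "sensor", "sensor")
      true_pose <- compose(true_pose, jitter)
    }
    poses[[k]] <- true_pose
  }
  stream <- pose_stream(t_samples + inject$latency_ms, poses)

  consumer_probe <- probe
  consumer_probe$calibration <- compose(probe$calibration,
                                        inject$calibration_offset)
  mid_pose <- rigid_transform(rot, pos_at(t_frames[spec$n_frames] / 2),
                              "sensor", "reference")
  structure(list(frames = frames, poses = stream, probe = consumer_probe,
                 truth = list(model = model, inject = inject, seed = spec$seed,
                              spec = spec, true_calibration = probe$calibration,
                              probe_pose_mid = compose(mid_pose, probe$calibration))),
            class = "simulated_acquisition")
}

#' @export
print.simulated_acquisition <- function(x, ...) {
  cat(sprintf("<simulated_acquisition: %d frames, %s sweep, seed %d>\n",
              length(x$frames), x$truth$spec$direction_label, x$truth$seed))
  invisible(x)
}

#' Batch of simulated acquisitions (the 3 x 4 accuracy study design)
#'
#' @param model a `wire_cross_model`.
#' @param specs list of [sweep_spec()] objects (see
#'   [standard_acquisition_specs()] for the 12-acquisition design: 3 repeats
#'   of along/diagonal crossed with front-to-back/back-to-front).
#' @param probe a `probe_model`.
#' @param inject an [error_injection()].
#' @return List of `simulated_acquisition` objects.
#' @export
batch_acquisitions <- function(model, specs, probe = default_probe(),
                               inject = error_injection()) {
  if (length(specs) == 0L)
    usnav_stop("no sweep specs given", "usnav_empty_input")
  lapply(specs, function(s) simulate_sweep(model, s, probe, inject))
}

#' The 12-acquisition study design
#'
#' Three repeats of each of the four sweep conditions (along/diagonal x
#' front-to-back/back-to-front), with distinct seeds derived from
#' `base_seed`.
#'
#' @param base_seed integer; acquisition i uses `base_seed + i - 1`.
#' @param n_repeats repeats per condition.
#' @param ... passed to [sweep_spec()] (e.g. `n_frames`).
#' @return List of 4 * `n_repeats` `sweep_spec` objects.
#' @export
standard_acquisition_specs <- function(base_seed = 1L, n_repeats = 3L, ...) {
  conds <- expand.grid(direction = c("along", "diagonal"),
                       towards = c("front_to_back", "back_to_front"),
                       rep = seq_len(n_repeats), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(conds)), function(i)
    sweep_spec(direction = conds$direction[i], towards = conds$towards[i],
               seed = base_seed + i - 1L, ...))
}

#' Run the full NSA pipeline on a simulated acquisition
#'
#' Convenience wrapper: assigns poses to frames, reconstructs the volume by
#' PNN, and computes the NSA against the acquisition's own nominal model,
#' decomposing the displacement in the mid-sweep scan-plane frame.
#'
#' @param acq a `simulated_acquisition`.
#' @param spacing reconstruction voxel spacing, mm.
#' @param hole_fill_radius hole-filling radius, voxels.
#' @param params an [nsa_params()] list; its `probe_pose` is filled from the
#'   acquisition truth when unset.
#' @return An `nsa_result`.
#' @export
nsa_from_acquisition <- function(acq, spacing = 0.2, hole_fill_radius = 1,
                                 params = nsa_params()) {
  stopifnot(inherits(acq, "simulated_acquisition"))
  poses <- assign_frame_poses(acq$frames, acq$poses, acq$probe)
  vol <- reconstruct_pnn(acq$frames, poses, acq$probe, spacing = spacing,
                         hole_fill_radius = hole_fill_radius)
  if (is.null(params$probe_pose)) params$probe_pose <- acq$truth$probe_pose_mid
  compute_nsa(vol, acq$truth$model, params)
}
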