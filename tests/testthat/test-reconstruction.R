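flat_probe <- function(rows = 8, cols = 10, sp = 0.5) {
  # beam origin at pixel (1,1): depth 0 at the first row, lateral 0 at col 1
  probe_model("linear", width = 2 * (cols - 1) * sp + 1, depth_start = 0,
              depth_end = (rows - 1) * sp, pixel_spacing = c(sp, sp),
              image_size = c(rows, cols), origin_px = c(1, 1))
}

test_that("sector masks clip exactly what the geometry says", {
  p <- flat_probe()
  expect_true(all(sector_mask(p)))

  shallow <- probe_model("linear", width = 100, depth_start = 0,
                         depth_end = 1.9, pixel_spacing = c(0.5, 0.5),
                         image_size = c(8, 10), origin_px = c(1, 1))
  m <- sector_mask(shallow)
  expect_true(all(m[1:4, ]))   # depths 0 .. 1.5
  expect_false(any(m[6:8, ]))  # deeper than depth_end

  fan <- probe_model("sector", width = 60, depth_start = 2, depth_end = 11,
                     pixel_spacing = c(0.1, 0.1), image_size = c(128, 128),
                     origin_px = c(1, 64.5))
  expect_identical(sector_mask(fan), sector_mask_oracle(fan))
  expect_identical(sector_mask(flat_probe()), sector_mask_oracle(flat_probe()))
})

test_that("pixel_to_reference applies the full calibrated chain", {
  p <- flat_probe()
  ident <- identity_transform("sensor", "reference")
  expect_equal(pixel_to_reference(p, ident, c(1, 1)), c(0, 0, 0))
  expect_equal(pixel_to_reference(p, ident, c(2, 1)), c(0, 0, 0.5))
  expect_error(pixel_to_reference(p, ident, c(0, 1)),
               class = "usnav_invalid_input")
  expect_error(pixel_to_reference(p, ident, c(1, 99)),
               class = "usnav_invalid_input")

  # random chain equals independently multiplied homogeneous matrices
  set.seed(91)
  cal <- random_rigid("image", "sensor")
  pose <- random_rigid("sensor", "reference")
  p2 <- flat_probe()
  p2$calibration <- cal
  px <- c(4, 7)
  img_pt <- c(0, (px[2] - 1) * 0.5, (px[1] - 1) * 0.5)
  oracle <- (as_homogeneous(pose) %*% as_homogeneous(cal) %*%
               c(img_pt, 1))[1:3]
  expect_equal(pixel_to_reference(p2, pose, px), oracle, tolerance = 1e-9)
})

test_that("frame poses honour the temporal offset and drop policy", {
  p <- flat_probe()
  mk_pose <- function(x) rigid_transform(diag(3), c(x, 0, 0), "sensor", "reference")
  st <- pose_stream(seq(0, 100, by = 10), lapply(seq(0, 100, by = 10), mk_pose))
  frames <- lapply(c(0, 30, 50), function(t) us_frame(matrix(0, 8, 10), t))

  poses <- assign_frame_poses(frames, st, p)
  expect_equal(vapply(poses, function(q) q$translation[1], numeric(1)),
               c(0, 30, 50))

  # constant stream: any offset returns the constant pose
  stc <- pose_stream(c(0, 100), list(mk_pose(7), mk_pose(7)))
  pc <- flat_probe(); pc$temporal_offset <- 25
  poses <- assign_frame_poses(frames, stc, pc)
  expect_true(all(vapply(poses, function(q) q$translation[1], numeric(1)) == 7))

  # linear motion at 1 mm per 10 ms: offset shifts position by velocity * dt
  po <- flat_probe(); po$temporal_offset <- 15
  poses <- suppressMessages(assign_frame_poses(frames, st, po))
  expect_equal(vapply(poses, function(q) q$translation[1], numeric(1)),
               c(0, 30, 50) + 15)

  # frames whose shifted timestamp leaves the stream are dropped, not clamped
  po$temporal_offset <- 60
  expect_message(poses <- assign_frame_poses(frames, st, po), "dropped")
  expect_equal(attr(poses, "n_dropped"), 1L)
  expect_equal(attr(poses, "frame_indices"), 1:2)
})

test_that("a single identity-chain frame reconstructs to its own pixels", {
  p <- flat_probe(8, 10, 0.5)
  set.seed(101)
  img <- matrix(runif(80, 10, 200), 8, 10)
  fr <- list(us_frame(img, 0))
  pose <- list(identity_transform("sensor", "reference"))
  vol <- reconstruct_pnn(fr, pose, p, spacing = 0.5, hole_fill_radius = 0)

  filled_idx <- which(vol$fill_mask, arr.ind = TRUE)
  expect_equal(length(unique(filled_idx[, 1])), 1L)  # one voxel out of plane
  centers <- voxel_centers(vol, filled_idx)
  # voxel at (y, z) must hold the pixel rendered there
  for (k in seq_len(nrow(filled_idx))) {
    col <- round(centers[k, 2] / 0.5) + 1
    row <- round(centers[k, 3] / 0.5) + 1
    expect_equal(vol$voxels[filled_idx[k, , drop = FALSE]], img[row, col])
  }

  # two coincident identical frames average to the same volume
  vol2 <- reconstruct_pnn(list(us_frame(img, 0), us_frame(img, 5)),
                          c(pose, pose), p, spacing = 0.5,
                          hole_fill_radius = 0)
  expect_equal(vol2$voxels, vol$voxels)
  expect_equal(vol2$fill_mask, vol$fill_mask)
})

test_that("a swept point target lands within one voxel diagonal", {
  p <- flat_probe(16, 16, 0.5)
  target <- c(2.0, 3.5, 4.0)  # x chosen on a frame plane below
  xs <- seq(0, 4, by = 0.5)
  frames <- list(); poses <- list()
  for (i in seq_along(xs)) {
    img <- matrix(0, 16, 16)
    if (abs(xs[i] - target[1]) < 1e-9) {
      img[target[3] / 0.5 + 1, target[2] / 0.5 + 1] <- 255
    }
    frames[[i]] <- us_frame(img, (i - 1) * 50)
    poses[[i]] <- rigid_transform(diag(3), c(xs[i], 0, 0), "sensor", "reference")
  }
  vol <- reconstruct_pnn(frames, poses, p, spacing = 0.5)
  am <- which(vol$voxels == max(vol$voxels), arr.ind = TRUE)
  err <- voxel_centers(vol, am[1, , drop = FALSE]) - target
  expect_lt(sqrt(sum(err^2)), sqrt(3) * 0.5)
})

test_that("reconstruction is frame-order invariant and range preserving", {
  model <- make_wire_cross()
  spec <- sweep_spec(n_frames = 24, span_mm = 6, seed = 5)
  acq <- simulate_sweep(model, spec)
  poses <- assign_frame_poses(acq$frames, acq$poses, acq$probe)
  vol <- reconstruct_pnn(acq$frames, poses, acq$probe, spacing = 0.4)

  set.seed(111)
  perm <- sample(length(acq$frames))
  poses_p <- poses[perm]
  attr(poses_p, "frame_indices") <- NULL
  vol_p <- reconstruct_pnn(acq$frames[perm], poses_p, acq$probe, spacing = 0.4)
  expect_equal(vol_p$voxels, vol$voxels, tolerance = 1e-6)
  expect_identical(vol_p$fill_mask, vol$fill_mask)

  # every data voxel lies within the global pixel intensity range
  px_rng <- range(vapply(acq$frames, function(f) range(f$pixels),
                         numeric(2)))
  vals <- vol$voxels[vol$data_mask]
  expect_gte(min(vals), px_rng[1] - 1e-9)
  expect_lte(max(vals), px_rng[2] + 1e-9)
})

test_that("growing the hole-fill radius never loses coverage", {
  model <- make_wire_cross()
  spec <- sweep_spec(n_frames = 10, span_mm = 6, seed = 6)
  acq <- simulate_sweep(model, spec)
  poses <- assign_frame_poses(acq$frames, acq$poses, acq$probe)
  n_filled <- vapply(c(0, 1, 2), function(r) {
    v <- reconstruct_pnn(acq$frames, poses, acq$probe, spacing = 0.3,
                         hole_fill_radius = r)
    sum(v$data_mask)
  }, numeric(1))
  expect_true(all(diff(n_filled) >= 0))

  expect_error(reconstruct_pnn(list(), list(), acq$probe),
               class = "usnav_empty_input")
})
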