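test_that("wire segmentation thresholds on filled intensity and keeps one component", {
  # uniform volume: every filled voxel survives any fraction
  u <- us_volume(array(100, c(4, 4, 4)), 0.5)
  seg <- segment_wires(u, 0.5)
  expect_true(all(seg$voxels))

  # a single bright voxel among zeros
  a <- array(0, c(5, 5, 5))
  a[3, 3, 3] <- 200
  seg <- segment_wires(us_volume(a, 0.5), 0.5)
  expect_equal(which(seg$voxels), which(a == 200))

  # synthetic wire against a dim background, checked per voxel
  set.seed(121)
  a <- array(runif(9 * 9 * 20, 0, 40), c(9, 9, 20))
  a[5, 5, ] <- runif(20, 150, 200)
  vol <- us_volume(a, 0.5)
  seg <- segment_wires(vol, 0.5)
  thr <- 0.5 * max(a)
  expect_identical(seg$voxels, array(a >= thr, dim(a)))

  # disconnected dim blob loses to the largest component
  b <- array(0, c(12, 3, 3))
  b[1:6, 2, 2] <- 200
  b[9:11, 2, 2] <- 200
  seg <- segment_wires(us_volume(b, 0.5), 0.5)
  expect_equal(sum(seg$voxels), 6)

  expect_error(segment_wires(us_volume(array(0, c(3, 3, 3)), 1,
                                       fill_mask = array(FALSE, c(3, 3, 3))),
                             0.5),
               class = "usnav_empty_input")
  expect_error(segment_wires(u, 1.5), class = "usnav_invalid_input")
})

test_that("thinning reduces tubes to their axis and keeps crossings", {
  # an already unit-width line is its own skeleton, one polyline
  a <- array(FALSE, c(20, 5, 5))
  a[2:19, 3, 3] <- TRUE
  cls <- extract_centerline(us_volume(a, 0.5))
  expect_length(cls, 1)
  expect_equal(nrow(cls[[1]]$points), 18)
  expect_true(all(abs(cls[[1]]$points[, 2] - 1) < 1e-12))  # y = (3-1)*0.5

  # a solid radius-3-voxel tube along z thins to (near) its axis
  axis_xy <- c(5, 5)
  seg <- list(list(a = c(axis_xy * 0.5, 0.5), b = c(axis_xy * 0.5, 14.5)))
  tube <- tube_volume(seg, radius = 1.5, spacing = 0.5,
                      lo = c(0, 0, 0), hi = c(5, 5, 15))
  cls <- extract_centerline(tube)
  pts <- do.call(rbind, lapply(cls, function(c) c$points))
  interior <- pts[pts[, 3] > 2 & pts[, 3] < 13, , drop = FALSE]
  off_axis <- sqrt((interior[, 1] - 2.5)^2 + (interior[, 2] - 2.5)^2)
  expect_true(all(off_axis <= 0.5 + 1e-9))  # within one voxel of the axis

  # two crossing tubes: polylines meet near the crossing point
  cross <- tube_volume(list(
    list(a = c(0.5, 5, 5), b = c(14.5, 5, 5)),
    list(a = c(7.5, 0.5, 5), b = c(7.5, 9.5, 5))),
    radius = 1.0, spacing = 0.5, lo = c(0, 0, 0), hi = c(15, 10, 10))
  cls <- extract_centerline(cross)
  expect_gte(length(cls), 2)
  pts <- do.call(rbind, lapply(cls, function(c) c$points))
  d_to_cross <- sqrt(rowSums(sweep(pts, 2, c(7.5, 5, 5))^2))
  expect_lt(min(d_to_cross), sqrt(3) * 0.5 + 1e-9)
})

test_that("a perfect rendering of the nominal model registers to itself", {
  model <- make_wire_cross(arm_length = 10, center = c(0, 0, 0))
  segs <- lapply(model$wires, function(w) list(
    a = w$center - w$half_length * w$direction,
    b = w$center + w$half_length * w$direction))
  vol <- tube_volume(segs, radius = model$wire_diameter / 2, spacing = 0.2,
                     lo = c(-11, -11, -1.4), hi = c(11, 11, 1.4))
  vol$voxels <- vol$voxels * 200
  res <- compute_nsa(vol, model)
  expect_lt(res$magnitude, 0.25)
})

test_that("displacement decomposition is an orthonormal re-expression", {
  pose <- identity_transform("image", "reference")
  expect_equal(decompose_nsa(c(0.7, 0, 0), pose),
               c(elevation = 0.7, azimuth = 0, radial = 0))
  expect_equal(decompose_nsa(c(0, 0, 1.2), pose),
               c(elevation = 0, azimuth = 0, radial = 1.2))

  set.seed(131)
  for (rep in 1:5) {
    p <- random_rigid("image", "reference")
    d <- rnorm(3)
    comps <- decompose_nsa(d, p)
    expect_equal(unname(comps), drop(t(p$rotation) %*% d), tolerance = 1e-12)
    expect_equal(sqrt(sum(comps^2)), sqrt(sum(d^2)), tolerance = 1e-9)
    # components reconstruct the displacement exactly
    expect_equal(drop(p$rotation %*% comps), d, tolerance = 1e-9)
  }
})

test_that("the error budget combines independent sources as an RSS", {
  expect_equal(rss_error_budget(c(3, 4)), 5)
  e <- rss_error_budget(c(1.0, 0.5, 0.1))
  expect_equal(e, sqrt(1.26), tolerance = 1e-12)

  # invariances: permutation, singleton identity, monotonicity, bounds
  set.seed(141)
  x <- runif(6, 0, 4)
  expect_equal(rss_error_budget(sample(x)), rss_error_budget(x))
  expect_equal(rss_error_budget(x[1]), x[1])
  bumped <- x + c(0.5, rep(0, 5))
  expect_gt(rss_error_budget(bumped), rss_error_budget(x))
  expect_gte(rss_error_budget(x), max(x))
  expect_lte(rss_error_budget(x), sum(x))

  expect_error(rss_error_budget(numeric(0)), class = "usnav_empty_input")
  expect_error(error_budget(c(1, -0.2)), class = "usnav_invalid_input")

  b <- error_budget(c(calibration = 1.0, tracking = 0.5))
  expect_equal(rss_error_budget(b), sqrt(1.25))
})

test_that("acquisition summaries use sample SD and pool correctly", {
  s <- summarize_acquisitions(c(1, 1, 1), rep("A", 3))
  expect_equal(s$mean_mm[s$group == "A"], 1)
  expect_equal(s$sd_mm[s$group == "A"], 0)

  s <- summarize_acquisitions(c(1, 2, 3), rep("G", 3))
  expect_equal(s$mean_mm[s$group == "G"], 2)
  expect_equal(s$sd_mm[s$group == "G"], 1)  # (n-1) denominator

  mags <- c(rep(1.1, 6), rep(0.9, 6))
  groups <- c(rep("A", 6), rep("D", 6))
  s <- summarize_acquisitions(mags, groups)
  all_row <- s[s$group == "all", ]
  expect_equal(all_row$n, 12)
  expect_equal(all_row$mean_mm, (6 * 1.1 + 6 * 0.9) / 12)

  expect_error(summarize_acquisitions(numeric(0)), class = "usnav_empty_input")
})
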