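test_that("landmark registration recovers generating transforms exactly", {
  # noise-free correspondences: recovery to 1e-9 for any >= 3 non-collinear
  # points under any rigid transform
  set.seed(51)
  for (rep in 1:6) {
    n <- sample(3:8, 1)
    pts <- matrix(rnorm(3 * n, sd = 30), n, 3)
    rownames(pts) <- paste0("L", seq_len(n))
    truth <- random_rigid("m", "f")
    moving <- landmark_set(pts, "m")
    fixed <- landmark_set(transform_points(truth, pts), "f")
    res <- register_landmarks(moving, fixed)
    expect_lt(res$rms_residual, 1e-9)
    expect_equal(res$transform$rotation, truth$rotation, tolerance = 1e-9)
    expect_equal(res$transform$translation, truth$translation,
                 tolerance = 1e-9)
  }

  # identical sets give identity with zero residual
  pts <- rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 10, 0),
               d = c(3, 4, 5))
  same <- register_landmarks(landmark_set(pts, "m"), landmark_set(pts, "f"))
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(same$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(same$rms_residual, 0, tolerance = 1e-12)
})

test_that("landmark registration matches names, guards degeneracy and reflections", {
  pts <- rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 10, 0),
               d = c(0, 0, 10))
  # shuffled rownames still pair correctly
  shuffled <- pts[c("d", "b", "a", "c"), ]
  res <- register_landmarks(landmark_set(shuffled, "m"),
                            landmark_set(pts, "f"))
  expect_lt(res$rms_residual, 1e-12)

  expect_error(register_landmarks(landmark_set(pts[1:2, ], "m"),
                                  landmark_set(pts, "f")),
               class = "usnav_insufficient_landmarks")
  line <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0),
                d = c(3, 0, 0))
  expect_error(register_landmarks(landmark_set(line, "m"),
                                  landmark_set(line, "f")),
               class = "usnav_degenerate_geometry")

  # near-mirrored data must still return a proper rotation (det +1)
  set.seed(61)
  m <- matrix(rnorm(12, sd = 10), 4, 3)
  rownames(m) <- paste0("p", 1:4)
  f <- m %*% diag(c(1, 1, -1)) + matrix(rnorm(12, sd = 0.01), 4, 3)
  rownames(f) <- rownames(m)
  res <- register_landmarks(landmark_set(m, "m"), landmark_set(f, "f"))
  expect_equal(det(res$transform$rotation), 1, tolerance = 1e-9)
})

test_that("landmark least squares is at least as good as a rotation-grid search", {
  set.seed(71)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(3 * n, sd = 25), n, 3)
    rownames(pts) <- paste0("p", seq_len(n))
    truth <- rigid_transform(rot_axis_angle(rnorm(3), runif(1, 2, 15)),
                             rnorm(3, sd = 5), "m", "f")
    noisy <- transform_points(truth, pts) + matrix(rnorm(3 * n, sd = 0.1), n, 3)
    rownames(noisy) <- rownames(pts)
    res <- register_landmarks(landmark_set(pts, "m"),
                              landmark_set(noisy, "f"))
    oracle <- grid_search_rigid_rms(pts, noisy)
    expect_lte(res$rms_residual, oracle + 1e-9)
  }
})

test_that("fast registration aligns the axis and maps the landmark exactly", {
  # coincident landmarks, identical axes -> identity
  res <- register_fast(c(1, 2, 3), c(1, 2, 3), c(0, 0, 1), c(0, 0, 1))
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(res$transform$translation, c(0, 0, 0), tolerance = 1e-12)

  # identical axes, offset landmarks -> pure translation
  res <- register_fast(c(0, 0, 0), c(0, 0, 10), c(0, 0, 1), c(0, 0, 1))
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(res$transform$translation, c(0, 0, 10))

  # reference +z onto tool +x, landmarks at origin
  res <- register_fast(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(drop(res$transform$rotation %*% c(0, 0, 1)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(res$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(res$rms_residual, 0)

  # anti-parallel axes: deterministic 180-degree choice, still maps a -> -a
  r1 <- register_fast(c(0, 0, 0), c(0, 0, 0), c(0, 0, -1), c(0, 0, 1))
  r2 <- register_fast(c(0, 0, 0), c(0, 0, 0), c(0, 0, -1), c(0, 0, 1))
  expect_identical(r1$transform$rotation, r2$transform$rotation)
  expect_equal(drop(r1$transform$rotation %*% c(0, 0, 1)), c(0, 0, -1),
               tolerance = 1e-9)
  expect_equal(det(r1$transform$rotation), 1, tolerance = 1e-9)

  expect_error(register_fast(c(0, 0, 0), c(0, 0, 0), c(0, 0, 2), c(0, 0, 1)),
               class = "usnav_invalid_input")
})

test_that("centerline ICP recovers known displacements with monotone residuals", {
  # self-registration terminates immediately at (near) zero
  path <- polyline_centerline(rbind(c(0, 0, 0), c(30, 0, 0), c(30, 20, 0)))
  self <- icp_register_centerlines(path, path)
  expect_lt(self$rms_residual, 1e-9)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-7)

  # 1 mm displacement perpendicular to a straight path
  straight <- polyline_centerline(rbind(c(0, 0, 0), c(20, 0, 0)))
  moved <- centerline(sweep(straight$points, 2, c(0, 1, 0), "+"))
  res <- icp_register_centerlines(moved, straight)
  expect_equal(sqrt(sum(res$transform$translation^2)), 1, tolerance = 1e-6)

  # L-shaped path under a 5 degree / 2 mm transform
  L <- polyline_centerline(rbind(c(0, 0, 0), c(25, 0, 0), c(25, 25, 0)),
                           step = 0.5)
  truth <- rigid_transform(rot_axis_angle("z", 5), c(2, 0, 0),
                           "moving", "fixed")
  moved <- centerline(transform_points(invert(truth), L$points))
  res <- icp_register_centerlines(moved, L)
  expect_equal(res$transform$rotation, truth$rotation, tolerance = 1e-3)
  expect_equal(res$transform$translation, truth$translation, tolerance = 1e-3)
  expect_true(all(diff(res$per_iteration_residuals) <= 1e-12))
})

test_that("ICP residual sequences never increase on random problems", {
  set.seed(81)
  for (rep in 1:20) {
    w <- matrix(rnorm(12, sd = 15), 4, 3)
    fixed <- polyline_centerline(w, step = 1)
    d <- rigid_transform(rot_axis_angle(rnorm(3), runif(1, 0, 10)),
                         rnorm(3, sd = 2), "moving", "fixed")
    moving <- centerline(transform_points(d, fixed$points))
    res <- icp_register_centerlines(moving, fixed,
                                    icp_params(max_iter = 30))
    expect_true(all(diff(res$per_iteration_residuals) <= 1e-12))
    expect_lte(res$per_iteration_residuals[length(res$per_iteration_residuals)],
               res$per_iteration_residuals[1] + 1e-12)
  }
})

test_that("trajectory-to-airway registration is exact on the centerline", {
  airway <- polyline_centerline(rbind(c(0, 0, 0), c(0, 0, 40), c(15, 0, 70)),
                                step = 1)
  tang <- centerline_tangents(airway)
  idx <- seq(3, nrow(airway$points) - 2, by = 2)
  traj <- make_trajectory(airway$points[idx, ], tang[idx, ])
  res <- register_trajectory_to_airway(traj, airway,
                                       icp_params(trim_fraction = 0))
  expect_lt(res$rms_residual, 1e-6)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-5)
  expect_equal(res$transform$translation, c(0, 0, 0), tolerance = 1e-4)
})

test_that("trajectory registration recovers a small displacement", {
  airway <- polyline_centerline(rbind(c(0, 0, 0), c(0, 5, 40), c(15, 5, 70),
                                      c(30, 20, 80)), step = 1)
  tang <- centerline_tangents(airway)
  idx <- seq(2, nrow(airway$points) - 1, by = 2)
  offset <- rigid_transform(rot_axis_angle(c(0.3, 1, 0.2), 3), c(2, -3, 1),
                            "tool", "ct")
  pts <- transform_points(invert(offset), airway$points[idx, ])
  tg <- tang[idx, ] %*% t(invert(offset)$rotation)
  traj <- make_trajectory(pts, tg)
  res <- register_trajectory_to_airway(traj, airway,
                                       icp_params(trim_fraction = 0))
  # rotation error as an angle
  rel <- t(res$transform$rotation) %*% offset$rotation
  ang <- acos(min(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  cen <- colMeans(pts)
  err <- transform_points(res$transform, cen) - transform_points(offset, cen)
  expect_lt(sqrt(sum(err^2)), 0.5)
})

test_that("the orientation gate excludes the wrong branch of a Y tree", {
  trunk_a <- polyline_centerline(rbind(c(0, 0, 0), c(0, 0, 30),
                                       c(12, 0, 55)), step = 1)
  branch_b <- polyline_centerline(rbind(c(0, 0, 30), c(-12, 0, 55)), step = 1)
  # trajectory runs down branch A, pointing along A's running direction;
  # displaced slightly toward B so distance alone would grab B's segments
  ta <- centerline_tangents(trunk_a)
  idx <- which(trunk_a$points[, 3] > 31)
  pts <- sweep(trunk_a$points[idx, ], 2, c(-1.5, 0, 0), "+")
  traj <- make_trajectory(pts, ta[idx, ])
  res <- register_trajectory_to_airway(
    traj, list(trunk_a, branch_b),
    icp_params(trim_fraction = 0, max_angle_deg = 45,
               max_iter = 1))
  used <- res$correspondences$polyline
  expect_true(all(stats::na.omit(used) == 1))

  # with orientations anti-parallel to every branch, nothing correlates
  traj_flip <- make_trajectory(pts, -ta[idx, ])
  expect_error(register_trajectory_to_airway(
    traj_flip, list(trunk_a, branch_b),
    icp_params(trim_fraction = 0, max_angle_deg = 45)),
    class = "usnav_no_correspondence")
})

test_that("registration displacement metric matches closed forms", {
  pts <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  lm <- landmark_set(pts, "m")
  ident <- identity_transform("m")
  expect_equal(evaluate_registration_displacement(lm, ident)$per_landmark$displacement_mm,
               c(0, 0, 0))

  tr <- rigid_transform(diag(3), c(3, 4, 0), "m", "f")
  d <- evaluate_registration_displacement(lm, tr)
  expect_equal(d$per_landmark$displacement_mm, c(5, 5, 5))
  expect_equal(d$mean_mm, 5)
  expect_equal(d$max_mm, 5)

  rz <- rigid_transform(rot_axis_angle("z", 90), c(0, 0, 0), "m", "f")
  drot <- evaluate_registration_displacement(
    landmark_set(rbind(p = c(1, 0, 0)), "m"), rz)
  expect_equal(drot$per_landmark$displacement_mm, sqrt(2), tolerance = 1e-12)

  # invariant to relabeling
  relabeled <- pts[c("c", "a", "b"), ]
  d2 <- evaluate_registration_displacement(landmark_set(relabeled, "m"), tr)
  expect_equal(sort(d2$per_landmark$displacement_mm),
               sort(d$per_landmark$displacement_mm))

  wrong <- landmark_set(pts, "other")
  expect_error(evaluate_registration_displacement(wrong, tr),
               class = "usnav_frame_error")
})
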