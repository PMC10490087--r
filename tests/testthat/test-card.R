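test_that("detected card corners agree with the renderer truth within 1 px", {
  for (el in c(90, 78)) {
    r <- render_depth(make_scene(scene_spec()), default_cam(elevation = el))
    det <- detect_card(r$intensity)
    err <- vapply(seq_len(4), function(i) {
      min(sqrt(rowSums((r$card_corners_px -
                          matrix(det$corners_px[i, ], 4, 2,
                                 byrow = TRUE))^2)))
    }, numeric(1))
    expect_lt(max(err), 1)
    expect_gte(det$confidence, 0.9)
  }
})

test_that("blank images raise a catchable card-not-found condition", {
  expect_error(detect_card(matrix(0.3, 100, 100)),
               class = "mealmetry_card_not_found")
})

test_that("of two candidate quadrilaterals the higher rectangularity x area
          wins", {
  img <- matrix(0.2, 200, 200)
  img[20:60, 20:100] <- 0.95            # clean 41 x 81 rectangle
  img[120:180, 120:180] <- 0.95         # bigger square ...
  for (i in 120:180) img[i, 120:min(180, i)] <- 0.2  # ... cut to a triangle
  det <- detect_card(img, min_rectangularity = 0.3)
  ctr <- colMeans(det$corners_px)
  expect_lt(ctr[1], 110)  # the rectangle, not the triangle, was chosen
  expect_lt(ctr[2], 110)
})

test_that("pose recovery matches the pinhole model on exact corners", {
  cam <- default_cam()
  sc <- make_scene(scene_spec())
  cc <- project_points(cam, sc$card_corner_world)
  pose <- estimate_pose(cbind(cc$u, cc$v), card_spec(), cam)
  expect_equal(pose$centre_depth_mm, 400, tolerance = 0.1)
  expect_equal(pose$centre_distance_mm, sqrt(90^2 + 55^2 + 400^2),
               tolerance = 0.1)

  cam15 <- default_cam(elevation = 75)   # card plane tilted 15 deg from view
  cc15 <- project_points(cam15, sc$card_corner_world)
  pose15 <- estimate_pose(cbind(cc15$u, cc15$v), card_spec(), cam15)
  true_n <- as.numeric(cam15$rotation %*% c(0, 0, 1))
  ang <- acos(min(abs(sum(pose15$plane_normal * true_n)), 1)) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("collinear corners are unsolvable", {
  expect_error(
    estimate_pose(cbind(c(10, 20, 30, 40), c(10, 20, 30, 40)), card_spec(),
                  default_cam()),
    class = "mealmetry_pose_unsolvable")
})

test_that("pose recovery over random synthetic poses: median distance error
          under 1%, normal under 1 degree", {
  set.seed(11)
  derr <- c(); nerr <- c()
  for (i in 1:100) {
    el <- runif(1, 60, 90)
    dist <- runif(1, 250, 600)
    yaw <- runif(1, -40, 40)
    sc <- make_scene(scene_spec(card_pose = c(-60, -40, yaw)))
    cam <- camera_at(distance_mm = dist, elevation_deg = el,
                     azimuth_deg = -90 + runif(1, -15, 15))
    cc <- project_points(cam, sc$card_corner_world)
    pose <- estimate_pose(cbind(cc$u, cc$v), card_spec(), cam)
    centre_true <- as.numeric(cam$rotation %*% c(-60, -40, 0) +
                                cam$translation)
    derr <- c(derr, abs(pose$centre_distance_mm - sqrt(sum(centre_true^2))) /
                sqrt(sum(centre_true^2)))
    tn <- as.numeric(cam$rotation %*% c(0, 0, 1))
    nerr <- c(nerr, acos(min(abs(sum(pose$plane_normal * tn)), 1)) * 180 / pi)
  }
  expect_lt(median(derr), 0.01)
  expect_lt(median(nerr), 1)
})

test_that("metric alignment is a ratio, an identity for metric input, and
          idempotent", {
  r <- render_depth(make_scene(scene_spec()), default_cam())
  pose <- estimate_pose(r$card_corners_px, card_spec(), default_cam())

  arb <- depth_map(r$depth$values / 200, r$depth$valid)  # arbitrary units
  al <- metric_align(arb, pose, r$card_mask)
  expect_equal(al$scale, 200, tolerance = 1e-6)

  al_metric <- metric_align(r$depth, pose, r$card_mask)
  expect_equal(al_metric$scale, 1, tolerance = 1e-6)
  expect_equal(al_metric$aligned$values, r$depth$values, tolerance = 1e-6)

  twice <- metric_align(al_metric$aligned, pose, r$card_mask)
  expect_equal(twice$scale, 1, tolerance = 1e-9)
})

test_that("metric alignment is scale-equivariant in the provider's units", {
  r <- render_depth(make_scene(scene_spec()), default_cam())
  pose <- estimate_pose(r$card_corners_px, card_spec(), default_cam())
  base <- metric_align(r$depth, pose, r$card_mask)$aligned
  for (c in c(0.01, 3.7, 1000)) {
    scaled <- depth_map(r$depth$values * c, r$depth$valid)
    al <- metric_align(scaled, pose, r$card_mask)$aligned
    expect_equal(al$values, base$values, tolerance = 1e-9)
  }
})

test_that("alignment without valid card depth is impossible but catchable", {
  r <- render_depth(make_scene(scene_spec()), default_cam())
  pose <- estimate_pose(r$card_corners_px, card_spec(), default_cam())
  nowhere <- matrix(FALSE, nrow(r$depth$values), ncol(r$depth$values))
  expect_error(metric_align(r$depth, pose, nowhere),
               class = "mealmetry_alignment_impossible")
})
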