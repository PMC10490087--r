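test_that("fronto-parallel renders reproduce trivial depths", {
  cam <- default_cam()
  empty <- render_depth(make_scene(scene_spec()), cam)
  expect_true(all(empty$depth$values[empty$depth$valid] == 400))

  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30))
  r <- render_depth(sc, cam)
  top <- r$depth$values[r$item_masks[[1]]]
  # pixels on the top face sit at 400 - 30; a thin rim catches the sides
  expect_equal(min(top), 370, tolerance = 1e-9)
  expect_gt(mean(abs(top - 370) < 1e-6), 0.95)
})

test_that("card corners project exactly and the projected width matches the
          pinhole model", {
  cam <- default_cam()
  r <- render_depth(make_scene(scene_spec()), cam)
  expect_equal(unname(r$card_corners_px[2, "u"] - r$card_corners_px[1, "u"]),
               85.6 * 800 / 400, tolerance = 1e-9)
  truth <- project_points(cam, make_scene(scene_spec())$card_corner_world)
  expect_equal(unname(r$card_corners_px[, "u"]), truth$u)
  expect_equal(unname(r$card_corners_px[, "v"]), truth$v)
})

test_that("item masks are pairwise disjoint and card pixels are a distinct
          intensity band", {
  sc <- make_scene(default_meal_catalogue()$dinner_pasta)
  r <- render_depth(sc, default_cam())
  overlap <- Reduce(`+`, lapply(r$item_masks, function(m) m * 1L))
  expect_true(all(overlap <= 1L))
  expect_true(all(r$intensity[r$card_mask] >= 0.9))
  expect_true(all(r$intensity[!r$card_mask] < 0.9))
})

test_that("back-projecting a noiseless render lands on the generating
          surfaces within 0.5 mm", {
  cam <- default_cam(elevation = 80)
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30))
  r <- render_depth(sc, cam)

  cl <- backproject(r$depth, r$item_masks[[1]], cam)
  w <- cloud_to_world(cl, cam)
  d_box <- box_surface_distance(w$x - 60, w$y - 30, w$z, 100, 80, 30)
  expect_lt(max(d_box), 0.5)

  plane <- r$index == 0 & r$depth$valid
  clp <- backproject(r$depth, plane, cam)
  wp <- cloud_to_world(clp, cam)
  expect_lt(max(abs(wp$z)), 0.5)
})

test_that("renderer rejects unusable cameras", {
  sc <- make_scene(scene_spec())
  # card behind / outside the frustum
  away <- camera_at(target = c(500, 500, 0), distance_mm = 300,
                    elevation_deg = 90)
  expect_error(render_depth(sc, away), class = "mealmetry_card_outside")
  expect_error(render_depth(sc, default_cam(width = 32, height = 32)),
               class = "mealmetry_bad_camera")
})

test_that("stereo renders carry exact correspondences for both views", {
  sc <- make_scene(default_meal_catalogue()$lunch_rice)
  cam_a <- default_cam()
  cam_b <- default_cam(elevation = 75)
  st <- render_stereo(sc, cam_a, cam_b)
  expect_gte(nrow(st$correspondences), 8)
  pa <- project_points(cam_a, st$correspondences)
  pb <- project_points(cam_b, st$correspondences)
  expect_equal(st$correspondences$ua, pa$u)
  expect_equal(st$correspondences$vb, pb$v)
  # identical cameras give zero disparity at every correspondence
  st2 <- render_stereo(sc, cam_a, cam_a)
  expect_equal(st2$correspondences$ua, st2$correspondences$ub)
  expect_equal(st2$correspondences$va, st2$correspondences$vb)
})

test_that("depth noise is seeded, counted, and a no-op at zero settings", {
  r <- render_depth(make_scene(scene_spec()), default_cam())
  expect_identical(add_depth_noise(r$depth, 0, 0, seed = 7), r$depth)
  n1 <- add_depth_noise(r$depth, 2, 0.05, seed = 42)
  n2 <- add_depth_noise(r$depth, 2, 0.05, seed = 42)
  expect_identical(n1, n2)
  n3 <- add_depth_noise(r$depth, 2, 0.05, seed = 43)
  expect_false(identical(n1, n3))
})

test_that("outlier replacement count follows round(frac * n_valid)", {
  vals <- matrix(400, 100, 100)
  d <- depth_map(vals)
  noisy <- add_depth_noise(d, sigma_mm = 0, outlier_frac = 0.05, seed = 1)
  expect_identical(sum(noisy$values != 400), as.integer(round(0.05 * 1e4)))
})

test_that("depth rasters round-trip through 16-bit files with sidecar", {
  cam <- default_cam()
  r <- render_depth(make_scene(scene_spec()), cam)
  path <- withr::local_tempfile(fileext = ".tif")
  write_depth(r$depth, path, camera = cam)
  back <- read_depth(path)
  expect_equal(back$values, r$depth$values, tolerance = 0.04)
  expect_identical(back$valid, r$depth$valid)
  cam2 <- attr(back, "camera")
  expect_equal(cam2$rotation, cam$rotation)
  expect_equal(cam2$fx, cam$fx)
})
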