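test_that("a pure-horizontal-baseline pair is already rectified", {
  sc <- make_scene(scene_spec(solids = list(
    solid_cuboid(90, 70, 30, x = 80, y = 40, category = "bread white")),
    card_pose = c(0, -55, 0)))
  cam_a <- default_cam()
  # displace along the camera x axis: classic side-by-side rig
  bl_world <- as.numeric(t(cam_a$rotation) %*% c(60, 0, 0))
  cam_b <- translated_camera(cam_a, bl_world)
  st <- render_stereo(sc, cam_a, cam_b)
  pair <- rectify_pair(st$correspondences, cam_a, cam_b)
  expect_lt(pair$row_epsilon_px, 0.1)
  # homographies reduce to (near) identity for this geometry
  Ha <- pair$homography_a / pair$homography_a[3, 3]
  expect_equal(Ha, diag(3), tolerance = 1e-6)
  # known baseline and depth give the textbook disparity f*B/Z
  d_corr <- pair$corr_rect$ua - pair$corr_rect$ub
  plane_pts <- grepl("^card", st$correspondences$name)
  expect_equal(d_corr[plane_pts], rep(800 * 60 / 400, sum(plane_pts)),
               tolerance = 0.01)
})

test_that("the 90/75 pair rectifies with sub-half-pixel row residual", {
  sc <- make_scene(default_meal_catalogue()$lunch_rice)
  st <- render_stereo(sc, default_cam(), default_cam(elevation = 75))
  pair <- rectify_pair(st$correspondences, default_cam(),
                       default_cam(elevation = 75))
  expect_lt(pair$row_epsilon_px, 0.5)
})

test_that("fewer than 8 correspondences fail rectification", {
  sc <- make_scene(default_meal_catalogue()$lunch_rice)
  st <- render_stereo(sc, default_cam(), default_cam(elevation = 75))
  expect_error(rectify_pair(st$correspondences[1:7, ], default_cam(),
                            default_cam(elevation = 75)),
               class = "mealmetry_rectification_failed")
})

test_that("block matching recovers a synthetic integer shift exactly", {
  set.seed(3)
  L <- matrix(runif(120 * 160), 120, 160)
  L <- (L + cbind(L[, -1], L[, 160]) + rbind(L[-1, ], L[120, ])) / 3  # smooth
  R <- cbind(L[, 13:160], matrix(runif(120 * 12), 120, 12))  # shift by 12
  disp <- compute_disparity(list(rect_a = L, rect_b = R), block_px = 7,
                            max_disp = 30)
  inner <- disp$valid
  inner[, 1:20] <- FALSE; inner[, 141:160] <- FALSE
  expect_gt(sum(inner), 5000)
  expect_true(all(disp$values[inner] == 12))
})

test_that("identical images give zero disparity and uniform images give no
          valid disparity", {
  set.seed(4)
  img <- matrix(runif(100 * 100), 100, 100)
  d0 <- compute_disparity(list(rect_a = img, rect_b = img), block_px = 5,
                          max_disp = 20)
  expect_true(all(d0$values[d0$valid] == 0))
  flat <- matrix(0.5, 100, 100)
  dflat <- compute_disparity(list(rect_a = flat, rect_b = flat),
                             block_px = 5, max_disp = 20)
  expect_false(any(dflat$valid))
})

test_that("disparity-to-depth follows Z = f B / d, guards d <= 0, and is
          monotone", {
  vals <- matrix(c(120, 0, 60, 240), 2, 2)
  disp <- structure(list(values = vals,
                         valid = matrix(TRUE, 2, 2)),
                    class = "disparity_map")
  depth <- disparity_to_depth(disp, focal_px = 800, baseline_mm = 60)
  expect_equal(depth$values[1, 1], 400)
  expect_false(depth$valid[2, 1])     # zero disparity never divides
  expect_equal(depth$values[1, 2], 800)
  expect_equal(depth$values[2, 2], 200)
  d <- 1:50
  z <- 800 * 60 / d
  expect_true(all(diff(z) < 0))
})

test_that("stereo round trip stays within the disparity quantisation bound", {
  sc <- make_scene(scene_spec(solids = list(
    solid_cuboid(90, 70, 30, x = 80, y = 40, category = "bread white")),
    card_pose = c(0, -55, 0)))
  cam_a <- default_cam()
  bl_world <- as.numeric(t(cam_a$rotation) %*% c(60, 0, 0))
  cam_b <- translated_camera(cam_a, bl_world)
  st <- render_stereo(sc, cam_a, cam_b)
  depth <- stereo_depth_map(st, cam_a, cam_b)
  # block matching is well-posed away from the depth discontinuity at the
  # item boundary: erode the mask by half a block plus margin
  m <- st$a$item_masks[[1]]
  shift2 <- function(mm, dr, dc) {
    out <- matrix(FALSE, nrow(mm), ncol(mm))
    rs <- seq_len(nrow(mm)) + dr; cs <- seq_len(ncol(mm)) + dc
    ok_r <- rs >= 1 & rs <= nrow(mm); ok_c <- cs >= 1 & cs <= ncol(mm)
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- m
  for (dr in c(-8, 0, 8)) for (dc in c(-8, 0, 8)) {
    interior <- interior & shift2(m, dr, dc)
  }
  sel <- interior & depth$valid
  true_z <- st$a$depth$values[sel]
  est_z <- depth$values[sel]
  d_int <- round(800 * 60 / est_z)
  bound <- 800 * 60 * (1 / pmax(d_int - 1, 1) - 1 / d_int) + 0.5
  expect_gt(mean(abs(est_z - true_z) <= bound), 0.99)
})

test_that("geometry back-end depth matches rendered truth on the 90/75
          default scene", {
  sc <- make_scene(default_meal_catalogue()$lunch_rice)
  cam_a <- default_cam(); cam_b <- default_cam(elevation = 75)
  st <- render_stereo(sc, cam_a, cam_b)
  depth <- stereo_depth_map(st, cam_a, cam_b)
  food <- Reduce(`|`, st$a$item_masks)
  sel <- food & depth$valid
  err <- abs(depth$values[sel] - st$a$depth$values[sel]) /
    st$a$depth$values[sel]
  expect_lt(median(err), 0.02)
})
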