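test_that("back-projection follows the pinhole equations", {
  vals <- matrix(400, 64, 64)
  cam <- camera_model(800, 800, 32, 32, 64, 64)
  d <- depth_map(vals)
  m <- matrix(FALSE, 64, 64)
  m[33, 33] <- TRUE   # pixel (u, v) = (32, 32) = principal point
  cl <- backproject(d, m, cam)
  expect_equal(c(cl$x, cl$y, cl$z), c(0, 0, 400))
  m2 <- matrix(FALSE, 64, 64)
  m2[33, 34] <- TRUE  # one pixel right of the principal point
  cl2 <- backproject(d, m2, cam)
  expect_equal(cl2$x, 0.5)
  expect_error(backproject(d, matrix(FALSE, 64, 64), cam),
               class = "mealmetry_empty_item")
})

test_that("card-frame transform zeroes the plane, preserves distances, and
          recovers item heights", {
  cam <- default_cam(elevation = 80)
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30))
  r <- render_depth(sc, cam)
  pose <- estimate_pose(r$card_corners_px, card_spec(), cam)

  card_cloud <- backproject(r$depth, r$card_mask, cam)
  cc <- to_card_frame(card_cloud, pose)
  expect_lt(max(abs(cc$z)), 0.1)

  item <- backproject(r$depth, r$item_masks[[1]], cam)
  set.seed(5)
  i <- sample(nrow(item), 200)
  before <- as.matrix(dist(cbind(item$x, item$y, item$z)[i, ]))
  ic <- to_card_frame(item, pose)
  after <- as.matrix(dist(cbind(ic$x, ic$y, ic$z)[i, ]))
  expect_lt(max(abs(before - after)), 1e-6)

  # top-face points map to the cuboid height; rim pixels graze the sides
  top <- ic$z[ic$z > 25]
  expect_equal(median(top), 30, tolerance = 0.5)
  expect_gt(mean(abs(top - 30) < 0.5), 0.9)
})

test_that("statistical outlier removal keeps clean back-projected clouds and
          agrees with a brute-force oracle", {
  cam <- default_cam()
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30))
  r <- render_depth(sc, cam)
  pose <- estimate_pose(r$card_corners_px, card_spec(), cam)
  cl <- to_card_frame(backproject(r$depth, r$item_masks[[1]], cam), pose)
  out <- remove_statistical_outliers(cl)
  expect_lt(attr(out, "removed_count") / nrow(cl), 0.01)

  # small cloud with one distant speck: brute-force oracle for the whole rule
  g <- expand.grid(x = seq(0, 50, by = 1), y = seq(0, 40, by = 1))
  cl2 <- structure(tibble::tibble(x = c(g$x, 25), y = c(g$y, 20),
                                  z = c(rep(10, nrow(g)), 110)),
                   class = c("mealmetry_cloud", class(tibble::tibble())))
  attr(cl2, "frame") <- "card"
  D <- as.matrix(dist(cbind(cl2$x, cl2$y, cl2$z)))
  stat <- apply(D, 1, function(row) mean(sort(row)[2:21]))  # 20-NN mean
  keep_oracle <- stat <= mean(stat) + 2 * sd(stat)
  out2 <- remove_statistical_outliers(cl2)
  expect_identical(attr(out2, "removed_count"),
                   as.integer(sum(!keep_oracle)))
  expect_equal(out2$z, cl2$z[keep_oracle])
  expect_false(any(out2$z > 100))   # the speck is gone
})

test_that("clouds no larger than k pass through unchanged with a warning", {
  cl <- structure(tibble::tibble(x = 1:20, y = 1:20, z = 0),
                  class = c("mealmetry_cloud", class(tibble::tibble())))
  attr(cl, "frame") <- "card"
  expect_warning(out <- remove_statistical_outliers(cl, k_neighbours = 20))
  expect_identical(nrow(out), 20L)
  expect_true(attr(out, "too_few_points"))
})

test_that("height rules discard outside [-5, +50] mm and clip at the plane", {
  mk <- function(z) {
    cl <- structure(tibble::tibble(x = seq_along(z), y = 0, z = z),
                    class = c("mealmetry_cloud", class(tibble::tibble())))
    attr(cl, "frame") <- "card"
    cl
  }
  out <- apply_height_rules(mk(c(-10, -4, -2, 25, 49, 70)))
  expect_equal(out$z, c(0, 0, 25, 49))   # -10 and 70 gone, negatives clipped
  expect_error(apply_height_rules(mk(c(-20, 60))),
               class = "mealmetry_empty_after_rules")
})

test_that("height-field integration recovers a dense slab within 2%", {
  # samples at cell midpoints represent a 100 x 80 mm slab
  g <- expand.grid(x = seq(0.25, 99.75, by = 0.5),
                   y = seq(0.25, 79.75, by = 0.5))
  cl <- structure(tibble::tibble(x = g$x, y = g$y, z = 30),
                  class = c("mealmetry_cloud", class(tibble::tibble())))
  attr(cl, "frame") <- "card"
  expect_equal(integrate_volume(cl), 240, tolerance = 0.02)
  few <- cl[1:9, ]
  attr(few, "frame") <- "card"
  expect_error(integrate_volume(few), class = "mealmetry_insufficient_points")
})

test_that("the cup cap clips strictly above 2.5 cups", {
  rules <- volume_rules()
  expect_identical(cap_volume(750, rules), list(volume_mL = 600, capped = TRUE))
  expect_identical(cap_volume(100, rules),
                   list(volume_mL = 100, capped = FALSE))
  expect_identical(cap_volume(600, rules),
                   list(volume_mL = 600, capped = FALSE))
})

test_that("item estimation falls back to the standard serving when the card
          is missing or depth is unusable", {
  cam <- default_cam()
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30,
                                     category = "bread white"))
  r <- render_depth(sc, cam)
  serving <- load_nutrient_table()

  est <- estimate_item_volume(r$depth, r$item_masks[[1]], NULL, "bread white",
                              serving, volume_rules(), cam)
  expect_true(est$fallback_serving)
  expect_false(est$card_found)
  expect_equal(est$volume_mL,
               serving$serving_volume_mL[serving$fine_category ==
                                           "bread white"])

  pose <- estimate_pose(r$card_corners_px, card_spec(), cam)
  dead <- depth_map(matrix(0, 480, 640), matrix(FALSE, 480, 640))
  est2 <- estimate_item_volume(dead, r$item_masks[[1]], pose, "bread white",
                               serving, volume_rules(), cam)
  expect_true(est2$fallback_serving)

  expect_error(
    estimate_item_volume(dead, r$item_masks[[1]], NULL, "unicorn stew",
                         serving, volume_rules(), cam),
    class = "mealmetry_missing_serving")
})

test_that("estimated volume matches the analytic truth on a clean render", {
  cam <- default_cam()
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30,
                                     category = "bread white"))
  r <- render_depth(sc, cam)
  pose <- estimate_pose(detect_card(r$intensity), card_spec(), cam)
  al <- metric_align(r$depth, pose, r$card_mask)
  est <- estimate_item_volume(al$aligned, r$item_masks[[1]], pose,
                              "bread white", load_nutrient_table(),
                              volume_rules(), cam)
  expect_false(est$fallback_serving)
  expect_true(est$card_found)
  expect_equal(est$volume_mL, 240, tolerance = 0.05)
})

test_that("graceful degradation under depth noise: cuboid volume error stays
          under 10% (median over seeds)", {
  cam <- default_cam()
  sc <- one_solid_scene(solid_cuboid(100, 80, 30, x = 60, y = 30,
                                     category = "bread white"))
  r <- render_depth(sc, cam)
  pose <- estimate_pose(detect_card(r$intensity), card_spec(), cam)
  errs <- vapply(1:20, function(s) {
    noisy <- add_depth_noise(r$depth, sigma_mm = 2, outlier_frac = 0,
                             seed = s)
    al <- metric_align(noisy, pose, r$card_mask)
    est <- estimate_item_volume(al$aligned, r$item_masks[[1]], pose,
                                "bread white", load_nutrient_table(),
                                volume_rules(), cam)
    abs(est$volume_mL - 240) / 240
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
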