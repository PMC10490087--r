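#' Volume-rule constants
#'
#' The fixed rules applied to every item's point cloud before integration:
#' points more than `bottom_tol_mm` below the card plane are discarded,
#' points more than `top_max_mm` above it are discarded, and no item volume
#' may exceed `max_cups` cups (1 cup = `cup_mL`, the nutrition-label cup).
#' `grid_cell_mm` is the plan-view cell size of the height-field
#' integration.
#'
#' @param bottom_tol_mm Tolerated depth below the card plane (mm).
#' @param top_max_mm Maximum height above the card plane (mm).
#' @param cup_mL Millilitres per cup.
#' @param max_cups Cap on item volume, in cups.
#' @param grid_cell_mm Height-field cell size (mm).
#' @return A `volume_rules` list with derived `cap_mL = cup_mL * max_cups`.
#' @export
volume_rules <- function(bottom_tol_mm = 5, top_max_mm = 50, cup_mL = 240,
                         max_cups = 2.5, grid_cell_mm = 2) {
  stopifnot(bottom_tol_mm > 0, top_max_mm > 0, cup_mL > 0, max_cups > 0,
            grid_cell_mm > 0)
  structure(list(bottom_tol_mm = bottom_tol_mm, top_max_mm = top_max_mm,
                 cup_mL = cup_mL, max_cups = max_cups,
                 grid_cell_mm = grid_cell_mm,
                 cap_mL = cup_mL * max_cups),
            class = "volume_rules")
}

new_cloud <- function(x, y, z, frame) {
  out <- tibble(x = x, y = y, z = z)
  attr(out, "frame") <- frame
  class(out) <- c("mealmetry_cloud", class(out))
  out
}

#' Point-cloud frame tag
#' @param cloud A point-cloud tibble from [backproject()] or
#'   [to_card_frame()].
#' @return `"camera"` or `"card"`.
#' @export
cloud_frame <- function(cloud) attr(cloud, "frame")

#' Back-project masked depth pixels to a 3-D point cloud
#'
#' For each masked valid pixel, `X = (u - cx) Z / fx`, `Y = (v - cy) Z / fy`,
#' `Z = depth`, in the camera frame (mm).
#'
#' @param depth A metric [depth_map()].
#' @param mask Logical matrix selecting the item's pixels.
#' @param camera A [camera_model()] (intrinsics only are used).
#' @return A point-cloud tibble with columns `x`, `y`, `z` and frame tag
#'   `"camera"`.
#' @export
backproject <- function(depth, mask, camera) {
  stopifnot(inherits(depth, "depth_map"), is.logical(mask),
            all(dim(mask) == dim(depth$values)))
  sel <- which(mask & depth$valid, arr.ind = TRUE)
  if (nrow(sel) == 0) {
    abort("mask selects no valid depth pixels", class = "mealmetry_empty_item")
  }
  u <- unname(sel[, 2]) - 1; v <- unname(sel[, 1]) - 1
  Z <- depth$values[sel]
  new_cloud((u - camera$cx) * Z / camera$fx,
            (v - camera$cy) * Z / camera$fy,
            Z, frame = "camera")
}

#' Transform a camera-frame cloud into the card frame
#'
#' Applies the rigid transform that puts the card plane at z = 0 with +z
#' toward the camera side; distances are preserved exactly, so heights above
#' the card plane can be read off the z column.
#'
#' @param cloud A camera-frame point-cloud tibble.
#' @param pose A `card_pose` from [estimate_pose()].
#' @return A card-frame point-cloud tibble.
#' @export
to_card_frame <- function(cloud, pose) {
  stopifnot(inherits(pose, "card_pose"))
  if (!identical(cloud_frame(cloud), "camera")) {
    abort("cloud must be in the camera frame")
  }
  P <- cbind(cloud$x, cloud$y, cloud$z)
  Pc <- sweep(P, 2, pose$translation) %*% pose$rotation
  new_cloud(Pc[, 1], Pc[, 2], Pc[, 3], frame = "card")
}

#' Remove statistical outliers from a point cloud
#'
#' Classic k-nearest-neighbour statistical filter: a point is removed when
#' its mean distance to its `k_neighbours` nearest neighbours exceeds the
#' global mean plus `std_ratio` standard deviations of that statistic.
#' Clouds with at most `k_neighbours` points are returned unchanged with a
#' `"too_few_points"` attribute set.
#'
#' @param cloud A point-cloud tibble.
#' @param k_neighbours Number of neighbours for the distance statistic.
#' @param std_ratio Standard-deviation multiplier of the cutoff.
#' @return The filtered cloud; attribute `"removed_count"` reports how many
#'   points were dropped.
#' @export
remove_statistical_outliers <- function(cloud, k_neighbours = 20,
                                        std_ratio = 2.0) {
  n <- nrow(cloud)
  if (n <= k_neighbours) {
    warn("too few points for statistical outlier removal; cloud unchanged")
    attr(cloud, "removed_count") <- 0L
    attr(cloud, "too_few_points") <- TRUE
    return(cloud)
  }
  d <- knn_mean_dist(cbind(cloud$x, cloud$y, cloud$z), as.integer(k_neighbours))
  keep <- d <= mean(d) + std_ratio * sd(d)
  out <- cloud[keep, ]
  attr(out, "frame") <- cloud_frame(cloud)
  class(out) <- class(cloud)
  attr(out, "removed_count") <- as.integer(sum(!keep))
  out
}

#' Apply the card-plane height rules
#'
#' Discards points more than `bottom_tol_mm` below the card plane and points
#' more than `top_max_mm` above it, then clips the remaining heights below
#' at zero so integration measures height from the card plane.
#'
#' @param cloud A card-frame point-cloud tibble.
#' @param rules A [volume_rules()].
#' @return The filtered cloud (z clipped at 0).
#' @export
apply_height_rules <- function(cloud, rules = volume_rules()) {
  if (!identical(cloud_frame(cloud), "card")) {
    abort("height rules apply in the card frame")
  }
  keep <- cloud$z >= -rules$bottom_tol_mm & cloud$z <= rules$top_max_mm
  if (!any(keep)) {
    abort("no points remain after the card-plane height rules",
          class = "mealmetry_empty_after_rules")
  }
  out <- cloud[keep, ]
  out$z <- pmax(out$z, 0)
  attr(out, "frame") <- "card"
  class(out) <- class(cloud)
  out
}

#' Integrate item volume as a height field over the card plane
#'
#' Partitions the plan-view bounding box into `grid_cell_mm` squares, takes
#' the median height of the points falling in each cell (robust to residual
#' speckle), and sums cell area times height. Empty cells contribute zero;
#' no inpainting is performed. A single-view depth map only observes the top
#' surface of an item, so a height field above the plane is the faithful
#' volume model.
#'
#' @param cloud A card-frame point-cloud tibble (after
#'   [apply_height_rules()]).
#' @param rules A [volume_rules()].
#' @return Volume in millilitres.
#' @export
integrate_volume <- function(cloud, rules = volume_rules()) {
  if (!identical(cloud_frame(cloud), "card")) {
    abort("integration happens in the card frame")
  }
  if (nrow(cloud) < 10) {
    abort("fewer than 10 points; volume integration unreliable",
          class = "mealmetry_insufficient_points")
  }
  cell <- rules$grid_cell_mm
  ix <- floor((cloud$x - min(cloud$x)) / cell)
  iy <- floor((cloud$y - min(cloud$y)) / cell)
  heights <- tibble(ix = ix, iy = iy, z = cloud$z) |>
    group_by(ix, iy) |>
    summarise(h = median(z), .groups = "drop")
  sum(heights$h) * cell^2 / 1000
}

#' Cap an item volume at the rule maximum
#'
#' No single food item is allowed a volume over `max_cups` cups; anything
#' larger is treated as point-cloud noise and clipped.
#'
#' @param v Volume in mL (>= 0).
#' @param rules A [volume_rules()].
#' @return List with `volume_mL` (clipped value) and `capped` (logical).
#' @export
cap_volume <- function(v, rules = volume_rules()) {
  stopifnot(v >= 0)
  if (v > rules$cap_mL) list(volume_mL = rules$cap_mL, capped = TRUE)
  else list(volume_mL = v, capped = FALSE)
}

#' Estimate one item's volume, with standard-serving fallback
#'
#' Orchestrates the full per-item chain: back-projection, card-frame
#' transform, statistical outlier removal, card-plane height rules,
#' height-field integration, and the cup cap. If the card is missing or any
#' stage degenerates (no valid pixels, everything outside the height band,
#' too few points), the item falls back to the standard serving volume from
#' `serving_table` — never an error, because a missing card is an expected
#' condition in free-living captures.
#'
#' @param depth A metric [depth_map()] (already card-aligned).
#' @param mask Logical matrix for the item.
#' @param card Either a `card_pose`, or `NULL` when the card was absent or
#'   undetected.
#' @param category Fine taxonomy label of the item.
#' @param serving_table Data frame with columns `fine_category` and
#'   `serving_volume_mL` (a nutrient table works).
#' @param rules A [volume_rules()].
#' @param camera A [camera_model()] for back-projection.
#' @return One-row tibble: `fine_category`, `volume_mL`, `card_found`,
#'   `capped`, `fallback_serving`, `outliers_removed`.
#' @export
estimate_item_volume <- function(depth, mask, card, category, serving_table,
                                 rules = volume_rules(), camera) {
  fallback <- function() {
    row <- serving_table[serving_table$fine_category == category, ]
    if (nrow(row) == 0) {
      abort(sprintf("no standard serving for category '%s'", category),
            class = "mealmetry_missing_serving")
    }
    tibble(fine_category = category, volume_mL = row$serving_volume_mL[1],
           card_found = !is.null(card), capped = FALSE,
           fallback_serving = TRUE, outliers_removed = 0L)
  }
  if (is.null(card)) return(fallback())
  stopifnot(inherits(card, "card_pose"))
  res <- tryCatch({
    cloud <- backproject(depth, mask, camera)
    cloud <- to_card_frame(cloud, card)
    cloud <- suppressWarnings(remove_statistical_outliers(cloud))
    removed <- attr(cloud, "removed_count")
    cloud <- apply_height_rules(cloud, rules)
    v <- integrate_volume(cloud, rules)
    capped <- cap_volume(v, rules)
    tibble(fine_category = category, volume_mL = capped$volume_mL,
           card_found = TRUE, capped = capped$capped,
           fallback_serving = FALSE, outliers_removed = removed)
  },
  mealmetry_empty_item = function(e) fallback(),
  mealmetry_empty_after_rules = function(e) fallback(),
  mealmetry_insufficient_points = function(e) fallback())
  res
}
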