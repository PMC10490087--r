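#' Parametric food solids
#'
#' Constructors for the parametric solids the synthetic tabletop renderer
#' supports. Every solid rests on the table plane (base at z = 0) and is
#' placed at plan-view position `(x, y)` with an optional rotation `yaw_deg`
#' about the vertical axis. All dimensions are millimetres.
#'
#' Closed-form volumes:
#' * cuboid: `w * d * h`
#' * cylinder: `pi * r^2 * h`
#' * spherical cap (sphere radius `R`, cap height `h`): `pi * h^2 * (3R - h) / 3`
#' * conical frustum (base radius `r1`, top radius `r2`): `pi * h * (r1^2 + r1 r2 + r2^2) / 3`
#'
#' @param width,depth,height Cuboid edge lengths (mm).
#' @param radius Cylinder radius, or sphere radius for the spherical cap (mm).
#' @param radius_bottom,radius_top Frustum radii at the base and top (mm).
#' @param x,y Plan-view placement of the solid centre (mm).
#' @param yaw_deg Rotation about the vertical axis (degrees).
#' @param category Fine taxonomy label carried through to recognition and
#'   nutrient lookup.
#' @return A `food_solid` list.
#' @name food_solids
NULL

new_solid <- function(kind, params, x, y, yaw_deg, category) {
  structure(list(kind = kind, params = params, x = x, y = y,
                 yaw_deg = yaw_deg, category = category),
            class = "food_solid")
}

#' @rdname food_solids
#' @export
solid_cuboid <- function(width, depth, height, x = 0, y = 0, yaw_deg = 0,
                         category = NA_character_) {
  new_solid("cuboid", c(width = width, depth = depth, height = height),
            x, y, yaw_deg, category)
}

#' @rdname food_solids
#' @export
solid_cylinder <- function(radius, height, x = 0, y = 0, yaw_deg = 0,
                           category = NA_character_) {
  new_solid("cylinder", c(radius = radius, height = height),
            x, y, yaw_deg, category)
}

#' @rdname food_solids
#' @export
solid_spherical_cap <- function(radius, height, x = 0, y = 0, yaw_deg = 0,
                                category = NA_character_) {
  new_solid("spherical_cap", c(radius = radius, height = height),
            x, y, yaw_deg, category)
}

#' @rdname food_solids
#' @export
solid_frustum <- function(radius_bottom, radius_top, height, x = 0, y = 0,
                          yaw_deg = 0, category = NA_character_) {
  new_solid("frustum",
            c(radius_bottom = radius_bottom, radius_top = radius_top,
              height = height),
            x, y, yaw_deg, category)
}

validate_solid <- function(solid, i) {
  p <- solid$params
  bad <- function(msg) {
    abort(sprintf("solid %d (%s): %s", i, solid$kind, msg),
          class = "mealmetry_bad_solid")
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    bad("all shape parameters must be strictly positive")
  }
  if (solid$kind == "spherical_cap" && p[["height"]] > 2 * p[["radius"]]) {
    bad("cap height cannot exceed the sphere diameter")
  }
  invisible(solid)
}

# conservative plan-view footprint radius used for the overlap check
footprint_radius <- function(solid) {
  p <- solid$params
  switch(solid$kind,
    cuboid = sqrt(p[["width"]]^2 + p[["depth"]]^2) / 2,
    cylinder = p[["radius"]],
    spherical_cap = {
      R <- p[["radius"]]; h <- p[["height"]]
      sqrt(max(h * (2 * R - h), R^2))  # cap footprint; equator if h > R
    },
    frustum = max(p[["radius_bottom"]], p[["radius_top"]])
  )
}

solid_volume_mL <- function(solid) {
  p <- solid$params
  v_mm3 <- switch(solid$kind,
    cuboid = p[["width"]] * p[["depth"]] * p[["height"]],
    cylinder = pi * p[["radius"]]^2 * p[["height"]],
    spherical_cap = pi * p[["height"]]^2 * (3 * p[["radius"]] - p[["height"]]) / 3,
    frustum = pi * p[["height"]] *
      (p[["radius_bottom"]]^2 + p[["radius_bottom"]] * p[["radius_top"]] +
         p[["radius_top"]]^2) / 3
  )
  v_mm3 / 1000
}

#' Specify a synthetic tabletop scene
#'
#' A scene is a flat table at z = 0 carrying a zero-thickness reference card
#' and a set of parametric food solids. The card is modelled flush with the
#' table plane; its default size is the credit-card format 85.6 x 54.0 mm.
#'
#' @param solids List of [food_solids].
#' @param card_pose Numeric `c(x, y, yaw_deg)`: plan-view centre and rotation
#'   of the card on the table (mm, degrees).
#' @param card_size Numeric `c(width_mm, height_mm)`, width >= height.
#' @param table_extent Side length of the square table (mm), centred at the
#'   origin.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(solids = list(), card_pose = c(-90, -55, 0),
                       card_size = c(85.6, 54.0), table_extent = 600) {
  stopifnot(length(card_pose) == 3, length(card_size) == 2, table_extent > 0)
  if (any(card_size <= 0) || card_size[1] < card_size[2]) {
    abort("card_size must be positive with width >= height (landscape)",
          class = "mealmetry_bad_scene")
  }
  if (inherits(solids, "food_solid")) solids <- list(solids)
  structure(
    list(solids = solids, card_pose = as.numeric(card_pose),
         card_size = as.numeric(card_size), table_extent = table_extent),
    class = "scene_spec"
  )
}

card_corners_world <- function(spec) {
  w <- spec$card_size[1]; h <- spec$card_size[2]
  yaw <- spec$card_pose[3] * pi / 180
  Rz <- matrix(c(cos(yaw), -sin(yaw), sin(yaw), cos(yaw)), 2, 2, byrow = TRUE)
  # order: top-left, top-right, bottom-right, bottom-left in the card frame
  local <- rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2),
                 c(w / 2, h / 2), c(-w / 2, h / 2))
  world2 <- local %*% t(Rz) +
    matrix(spec$card_pose[1:2], 4, 2, byrow = TRUE)
  cbind(world2, 0)
}

#' Build a scene with analytic ground-truth volumes
#'
#' Validates a [scene_spec()] and attaches the closed-form volume of every
#' solid plus the 3-D world coordinates of the card corners. The analytic
#' volumes are the ground truth against which the whole volume pipeline is
#' tested.
#'
#' @param spec A `scene_spec`.
#' @return A `scene`: the spec plus `analytic_volume_mL` (one per solid) and
#'   `card_corner_world` (4 x 3 matrix, mm).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  for (i in seq_along(spec$solids)) validate_solid(spec$solids[[i]], i)

  # pairwise plan-view overlap checks (conservative bounding discs)
  centres <- map(spec$solids, ~c(.x$x, .x$y))
  radii <- map_dbl(spec$solids, footprint_radius)
  ns <- length(spec$solids)
  if (ns >= 2) {
    for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
      d <- sqrt(sum((centres[[i]] - centres[[j]])^2))
      if (d < radii[i] + radii[j]) {
        abort(sprintf("solids %d and %d overlap in plan view", i, j),
              class = "mealmetry_bad_scene")
      }
    }
  }
  card_r <- sqrt(sum(spec$card_size^2)) / 2
  for (i in seq_len(ns)) {
    d <- sqrt(sum((spec$card_pose[1:2] - centres[[i]])^2))
    if (d < card_r + radii[i]) {
      abort(sprintf("solid %d overlaps the reference card in plan view", i),
            class = "mealmetry_bad_scene")
    }
  }
  half <- spec$table_extent / 2
  for (i in seq_len(ns)) {
    if (any(abs(centres[[i]]) + radii[i] > half)) {
      abort(sprintf("solid %d extends beyond the table", i),
            class = "mealmetry_bad_scene")
    }
  }

  structure(
    list(spec = spec,
         analytic_volume_mL = map_dbl(spec$solids, solid_volume_mL),
         card_corner_world = card_corners_world(spec)),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d solid(s), card %.1fx%.1f mm\n",
              length(x$spec$solids), x$spec$card_size[1], x$spec$card_size[2]))
  if (length(x$spec$solids)) {
    for (i in seq_along(x$spec$solids)) {
      s <- x$spec$solids[[i]]
      cat(sprintf("  %d: %s [%s] %.1f mL at (%.0f, %.0f)\n", i, s$kind,
                  s$category, x$analytic_volume_mL[i], s$x, s$y))
    }
  }
  invisible(x)
}
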