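# Shared fixture builders and independent numeric oracles.

default_cam <- function(width = 640, height = 480, fx = 800,
                        distance = 400, elevation = 90) {
  camera_at(distance_mm = distance, elevation_deg = elevation,
            fx = fx, width = width, height = height)
}

one_solid_scene <- function(solid) {
  make_scene(scene_spec(solids = list(solid)))
}

# Independent volume oracle: midpoint column integration of the solid's
# height function over its footprint, 0.25 mm grid. Never uses the
# closed forms under test.
oracle_volume_mL <- function(solid, step = 0.25) {
  p <- solid$params
  half <- switch(solid$kind,
    cuboid = c(p[["width"]], p[["depth"]]) / 2,
    cylinder = rep(p[["radius"]], 2),
    spherical_cap = {
      R <- p[["radius"]]; h <- p[["height"]]
      rep(sqrt(h * (2 * R - h)), 2)
    },
    frustum = rep(max(p[["radius_bottom"]], p[["radius_top"]]), 2)
  )
  xs <- seq(-half[1] + step / 2, half[1] - step / 2, by = step)
  ys <- seq(-half[2] + step / 2, half[2] - step / 2, by = step)
  g <- expand.grid(x = xs, y = ys)
  hgt <- switch(solid$kind,
    cuboid = ifelse(abs(g$x) <= p[["width"]] / 2 &
                      abs(g$y) <= p[["depth"]] / 2, p[["height"]], 0),
    cylinder = ifelse(g$x^2 + g$y^2 <= p[["radius"]]^2, p[["height"]], 0),
    spherical_cap = {
      R <- p[["radius"]]; h <- p[["height"]]
      rho2 <- g$x^2 + g$y^2
      top <- (h - R) + sqrt(pmax(R^2 - rho2, 0))
      ifelse(rho2 <= h * (2 * R - h), pmax(top, 0), 0)
    },
    frustum = {
      r1 <- p[["radius_bottom"]]; r2 <- p[["radius_top"]]; h <- p[["height"]]
      rho <- sqrt(g$x^2 + g$y^2)
      ifelse(rho <= min(r1, r2), h,
             ifelse(rho <= max(r1, r2),
                    pmin(pmax(h * (r1 - rho) / (r1 - r2), 0), h), 0))
    }
  )
  sum(hgt) * step^2 / 1000
}

# transform a camera-frame cloud back to world coordinates
cloud_to_world <- function(cloud, camera) {
  P <- cbind(cloud$x, cloud$y, cloud$z)
  Pw <- sweep(P, 2, camera$translation) %*% camera$rotation
  tibble::tibble(x = Pw[, 1], y = Pw[, 2], z = Pw[, 3])
}

# unsigned distance to the surface of an axis-aligned box with base z = 0
box_surface_distance <- function(px, py, pz, w, d, h) {
  qx <- abs(px) - w / 2
  qy <- abs(py) - d / 2
  qz <- abs(pz - h / 2) - h / 2
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
  inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
  abs(outside + inside)
}

secondary_table <- function() {
  load_nutrient_table(system.file("extdata", "nutrients_secondary.csv",
                                  package = "mealmetry"))
}

# horizontal-baseline stereo rig: second camera displaced along camera x
translated_camera <- function(camera, baseline_world) {
  pos <- camera_centre(camera) + baseline_world
  camera_model(camera$fx, camera$fy, camera$cx, camera$cy,
               camera$width, camera$height,
               rotation = camera$rotation,
               translation = as.numeric(-camera$rotation %*% pos),
               elevation_deg = camera$elevation_deg)
}
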