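#' Pinhole camera model
#'
#' A calibrated pinhole camera. World coordinates are millimetres with the
#' table plane at z = 0 and +z up; camera coordinates follow the usual
#' computer-vision convention (+z along the optical axis, +x right, +y down
#' in the image). Integer pixel `(u, v)` is the centre of its cell, 0-based,
#' `u` rightward and `v` downward.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @param width,height Image size in pixels.
#' @param rotation 3x3 orthonormal matrix mapping world to camera
#'   directions (rows are the camera x/y/z axes expressed in world frame).
#' @param translation Length-3 vector, `Xc = R Xw + t` (mm).
#' @param elevation_deg Viewing angle of the optical axis from horizontal,
#'   recorded for bookkeeping (90 = looking straight down).
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, width, height,
                         rotation = diag(3), translation = c(0, 0, 0),
                         elevation_deg = NA_real_) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    abort("principal point must lie inside the image", class = "mealmetry_bad_camera")
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    abort("rotation must be a proper orthonormal 3x3 matrix",
          class = "mealmetry_bad_camera")
  }
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         width = as.integer(width), height = as.integer(height),
         rotation = rotation, translation = as.numeric(translation),
         elevation_deg = elevation_deg),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, fx=%.1f fy=%.1f, elevation=%s deg\n",
              x$width, x$height, x$fx, x$fy, format(x$elevation_deg)))
  invisible(x)
}

#' Place a camera looking at a point from a given elevation
#'
#' Positions the camera at `distance_mm` from `target` along the direction
#' given by `elevation_deg` (angle from the horizontal; 90 looks straight
#' down) and `azimuth_deg`, with the optical axis through `target`.
#'
#' @param target Length-3 world point the optical axis passes through (mm).
#' @param distance_mm Distance from the camera centre to `target` (> 0).
#' @param elevation_deg Elevation of the view direction above horizontal.
#' @param azimuth_deg Azimuth of the camera position, degrees.
#' @inheritParams camera_model
#' @return A `camera_model`.
#' @export
camera_at <- function(target = c(0, 0, 0), distance_mm = 400,
                      elevation_deg = 90, azimuth_deg = -90,
                      fx = 800, fy = fx, width = 640, height = 480,
                      cx = (width - 1) / 2, cy = (height - 1) / 2) {
  stopifnot(distance_mm > 0)
  e <- elevation_deg * pi / 180
  a <- azimuth_deg * pi / 180
  pos <- target + distance_mm * c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
  z_cam <- (target - pos) / distance_mm
  x_cam <- c(-sin(a), cos(a), 0)          # horizontal, well-defined at e = 90
  y_cam <- pracma_cross(z_cam, x_cam)
  R <- rbind(x_cam, y_cam, z_cam, deparse.level = 0)
  camera_model(fx, fy, cx, cy, width, height,
               rotation = R, translation = as.numeric(-R %*% pos),
               elevation_deg = elevation_deg)
}

# cross product (kept local; avoids importing pracma for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Camera centre in world coordinates
#' @param camera A `camera_model`.
#' @return Length-3 numeric vector (mm).
#' @export
camera_centre <- function(camera) {
  as.numeric(-t(camera$rotation) %*% camera$translation)
}

#' Project world points to pixel coordinates
#'
#' @param camera A `camera_model`.
#' @param points Data frame or matrix with columns/cols x, y, z (world mm).
#' @return A tibble with columns `u`, `v` (pixels, 0-based) and `z_cam`
#'   (depth along the optical axis, mm).
#' @export
project_points <- function(camera, points) {
  P <- as_point_matrix(points)
  Xc <- P %*% t(camera$rotation) +
    matrix(camera$translation, nrow(P), 3, byrow = TRUE)
  tibble(
    u = camera$fx * Xc[, 1] / Xc[, 3] + camera$cx,
    v = camera$fy * Xc[, 2] / Xc[, 3] + camera$cy,
    z_cam = Xc[, 3]
  )
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(unname(points))
  }
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  cbind(points$x, points$y, points$z)
}

#' Camera intrinsic matrix
#' @param camera A `camera_model`.
#' @return 3x3 upper-triangular intrinsic matrix K.
#' @export
intrinsic_matrix <- function(camera) {
  matrix(c(camera$fx, 0, camera$cx,
           0, camera$fy, camera$cy,
           0, 0, 1), 3, 3, byrow = TRUE)
}
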