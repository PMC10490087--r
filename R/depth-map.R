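#' Metric depth maps
#'
#' A depth map stores, for every pixel, the distance from the camera centre
#' to the scene along the optical axis (not the ray length), in millimetres.
#' Invalid pixels (no surface, dropouts) are flagged in `valid` and excluded
#' from every statistic; their stored value is 0.
#'
#' @param values Numeric matrix (height x width), mm.
#' @param valid Logical matrix of the same shape; defaults to finite, > 0.
#' @return A `depth_map`.
#' @export
depth_map <- function(values, valid = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- is.finite(values) & values > 0
  stopifnot(is.logical(valid), all(dim(valid) == dim(values)))
  if (any(valid & (!is.finite(values) | values <= 0))) {
    abort("valid depth values must be finite and > 0",
          class = "mealmetry_bad_depth")
  }
  values[!valid] <- 0
  structure(list(values = values, valid = valid, units = "mm"),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<depth_map> %dx%d px, %.1f%% valid, range %s mm\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid),
              if (length(v)) sprintf("[%.1f, %.1f]", min(v), max(v)) else "-"))
  invisible(x)
}

#' Add synthetic degradation to a depth map
#'
#' Perturbs every valid pixel with zero-mean Gaussian noise and replaces a
#' fixed fraction of valid pixels with gross outliers drawn uniformly over
#' an implausibly wide depth range. The outlier count is
#' `round(outlier_frac * n_valid)`, so it is deterministic given the map.
#'
#' @param depth A [depth_map()].
#' @param sigma_mm Gaussian noise standard deviation (mm, >= 0).
#' @param outlier_frac Fraction of valid pixels replaced by outliers, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the map bit for bit.
#' @return A `depth_map` of the same shape.
#' @export
add_depth_noise <- function(depth, sigma_mm = 0, outlier_frac = 0, seed = 1L) {
  stopifnot(inherits(depth, "depth_map"), sigma_mm >= 0,
            outlier_frac >= 0, outlier_frac < 1)
  if (sigma_mm == 0 && outlier_frac == 0) return(depth)
  values <- depth$values
  idx <- which(depth$valid)
  withr::with_seed(as.integer(seed), {
    if (sigma_mm > 0) {
      values[idx] <- values[idx] + rnorm(length(idx), sd = sigma_mm)
    }
    n_out <- round(outlier_frac * length(idx))
    if (n_out > 0) {
      v <- depth$values[idx]
      pick <- sample(idx, n_out)
      values[pick] <- runif(n_out, 0.5 * min(v), 1.5 * max(v))
    }
  })
  values[idx] <- pmax(values[idx], 1e-3)  # keep valid pixels strictly positive
  depth_map(values, depth$valid)
}

#' Read and write depth rasters
#'
#' Depth maps are serialised as single-channel 16-bit TIFF with value =
#' millimetres (quantised to 1/16 mm) and 0 marking invalid pixels, plus a
#' JSON sidecar (`<path>.json`) carrying the camera model when one is given.
#'
#' @param depth A [depth_map()].
#' @param path Output path (`.tif`).
#' @param camera Optional [camera_model()] stored in the sidecar.
#' @return `write_depth()` returns `path` invisibly; `read_depth()` returns a
#'   `depth_map` with attribute `"camera"` when a sidecar is present.
#' @export
write_depth <- function(depth, path, camera = NULL) {
  stopifnot(inherits(depth, "depth_map"))
  q <- depth$values * 16   # 1/16 mm resolution, max ~4 m in 16 bits
  if (any(q[depth$valid] >= 65536)) {
    abort("depth exceeds the 16-bit serialisation range (4095 mm)")
  }
  q[!depth$valid] <- 0
  tiff::writeTIFF(round(q) / 65535, path, bits.per.sample = 16)
  if (!is.null(camera)) {
    jsonlite::write_json(
      list(fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
           width = camera$width, height = camera$height,
           rotation = camera$rotation, translation = camera$translation,
           elevation_deg = camera$elevation_deg),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  values <- raw * 65535 / 16
  d <- depth_map(values, values > 0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(d, "camera") <- camera_model(
      j$fx, j$fy, j$cx, j$cy, j$width, j$height,
      rotation = matrix(unlist(j$rotation), 3, 3),
      translation = j$translation, elevation_deg = j$elevation_deg)
  }
  d
}

#' Write and read per-item index masks
#'
#' Masks are stored as an 8-bit indexed raster (0 = background, k = item k).
#'
#' @param index Integer matrix of item indices (0 = background).
#' @param path Output `.tif` path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the matrix.
#' @export
write_mask <- function(index, path) {
  stopifnot(max(index, na.rm = TRUE) < 256)
  m <- index
  m[is.na(m)] <- 0
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
}
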