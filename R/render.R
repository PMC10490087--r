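#' Render a depth map of a synthetic scene
#'
#' Exact ray-casting renderer for [make_scene()] scenes. For every pixel the
#' depth is the analytic ray/solid or ray/plane intersection distance along
#' the optical axis; there is no sampling approximation, so renders serve as
#' ground-truth fixtures for the whole measurement pipeline. The intensity
#' channel carries a procedural texture anchored to world coordinates (so it
#' is consistent across viewpoints, which is what stereo matching needs);
#' the card is rendered as a distinct near-white intensity band.
#'
#' @param scene A `scene` from [make_scene()].
#' @param camera A [camera_model()]; it must see all four card corners.
#' @return A `render_output` list: `depth` ([depth_map()]), `index` (integer
#'   matrix, 0 = table/card, k = k-th solid, NA = off-table), `item_masks`
#'   (list of logical matrices), `card_mask`, `card_corners_px` (4 x 2, exact
#'   pinhole projections, 0-based pixels), `intensity` (matrix in `[0, 1]`),
#'   plus the camera.
#' @export
render_depth <- function(scene, camera) {
  stopifnot(inherits(scene, "scene"), inherits(camera, "camera_model"))
  w <- camera$width; h <- camera$height
  if (w < 64 || h < 64) {
    abort("image size must be at least 64x64", class = "mealmetry_bad_camera")
  }
  cc <- project_points(camera, scene$card_corner_world)
  if (any(cc$z_cam <= 0) || any(cc$u < 0) || any(cc$u > w - 1) ||
      any(cc$v < 0) || any(cc$v > h - 1)) {
    abort("reference card is not fully inside the camera frustum",
          class = "mealmetry_card_outside")
  }

  n <- w * h
  U <- rep(0:(w - 1), each = h)     # column-major flattening
  V <- rep(0:(h - 1), times = w)
  # world-frame ray directions scaled so the parameter equals camera depth
  Dc <- cbind((U - camera$cx) / camera$fx, (V - camera$cy) / camera$fy, 1)
  D <- Dc %*% camera$rotation        # = t(R) %*% d per row
  o <- camera_centre(camera)

  # table plane z = 0
  t_plane <- ifelse(abs(D[, 3]) > 1e-12, -o[3] / D[, 3], Inf)
  t_plane[t_plane <= 1e-9] <- Inf
  px <- o[1] + t_plane * D[, 1]
  py <- o[2] + t_plane * D[, 2]
  half <- scene$spec$table_extent / 2
  on_table <- is.finite(t_plane) & abs(px) <= half & abs(py) <= half
  t_plane[!on_table] <- Inf

  solids <- scene$spec$solids
  ns <- length(solids)
  t_best <- t_plane
  idx <- ifelse(is.finite(t_plane), 0L, NA_integer_)
  for (k in seq_len(ns)) {
    tk <- intersect_solid(solids[[k]], o, D)
    better <- tk < t_best
    t_best[better] <- tk[better]
    idx[better] <- k
  }

  valid <- is.finite(t_best)
  depth_vals <- ifelse(valid, t_best, 0)

  # card membership of plane hits
  in_card <- rep(FALSE, n)
  plane_hit <- valid & idx == 0L
  if (any(plane_hit)) {
    yaw <- scene$spec$card_pose[3] * pi / 180
    dx <- px[plane_hit] - scene$spec$card_pose[1]
    dy <- py[plane_hit] - scene$spec$card_pose[2]
    xl <- cos(yaw) * dx + sin(yaw) * dy
    yl <- -sin(yaw) * dx + cos(yaw) * dy
    in_card[plane_hit] <- abs(xl) <= scene$spec$card_size[1] / 2 &
      abs(yl) <= scene$spec$card_size[2] / 2
  }

  # intensity from the world-anchored texture of each hit point
  hit <- cbind(o[1] + t_best * D[, 1], o[2] + t_best * D[, 2],
               o[3] + t_best * D[, 3])
  tex <- world_texture(hit)
  intensity <- rep(0, n)
  is_table <- valid & idx == 0L & !in_card
  is_food <- valid & idx > 0L
  intensity[is_table] <- 0.15 + 0.50 * tex[is_table]
  intensity[is_food] <- 0.20 + 0.60 * tex[is_food]
  intensity[in_card] <- 0.90 + 0.10 * tex[in_card]

  as_m <- function(x) matrix(x, h, w)
  structure(
    list(
      depth = depth_map(as_m(depth_vals), as_m(valid)),
      index = as_m(idx),
      item_masks = lapply(seq_len(ns), function(k) as_m(!is.na(idx) & idx == k)),
      card_mask = as_m(in_card),
      card_corners_px = cbind(u = cc$u, v = cc$v),
      intensity = as_m(intensity),
      camera = camera
    ),
    class = "render_output"
  )
}

# deterministic multi-frequency texture of world position (mm); range [0, 1]
world_texture <- function(P) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  v <- 0.5 +
    0.25 * sin(0.55 * x + 0.35 * y + 0.90 * z) +
    0.15 * sin(1.30 * x - 0.70 * y + 0.40 * z + 1.0) +
    0.10 * cos(0.45 * y + 1.10 * z + 2.0)
  v[!is.finite(v)] <- 0
  pmin(pmax(v, 0), 1)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# smallest positive ray parameter hitting the solid, Inf for a miss
intersect_solid <- function(solid, o, D) {
  Rz <- rot_z(-solid$yaw_deg)
  ol <- as.numeric(Rz %*% (o - c(solid$x, solid$y, 0)))
  Dl <- D %*% t(Rz)
  p <- solid$params
  switch(solid$kind,
    cuboid = intersect_box(ol, Dl, p[["width"]], p[["depth"]], p[["height"]]),
    cylinder = intersect_frustum_like(ol, Dl, p[["radius"]], p[["radius"]],
                                      p[["height"]]),
    frustum = intersect_frustum_like(ol, Dl, p[["radius_bottom"]],
                                     p[["radius_top"]], p[["height"]]),
    spherical_cap = intersect_cap(ol, Dl, p[["radius"]], p[["height"]])
  )
}

intersect_box <- function(o, D, w, d, h) {
  lo <- c(-w / 2, -d / 2, 0); hi <- c(w / 2, d / 2, h)
  t_enter <- rep(-Inf, nrow(D)); t_exit <- rep(Inf, nrow(D))
  for (ax in 1:3) {
    inv <- 1 / D[, ax]
    t1 <- (lo[ax] - o[ax]) * inv
    t2 <- (hi[ax] - o[ax]) * inv
    a <- pmin(t1, t2); b <- pmax(t1, t2)
    a[is.nan(a)] <- -Inf; b[is.nan(b)] <- Inf
    t_enter <- pmax(t_enter, a); t_exit <- pmin(t_exit, b)
  }
  ok <- t_enter <= t_exit & t_enter > 1e-9
  ifelse(ok, t_enter, Inf)
}

# cylinder is the r1 == r2 special case of the lateral-surface quadratic
intersect_frustum_like <- function(o, D, r1, r2, h) {
  s <- (r2 - r1) / h
  A <- D[, 1]^2 + D[, 2]^2 - s^2 * D[, 3]^2
  B <- 2 * (o[1] * D[, 1] + o[2] * D[, 2] - s * D[, 3] * (r1 + s * o[3]))
  C <- o[1]^2 + o[2]^2 - (r1 + s * o[3])^2
  z_ok <- function(t) {
    z <- o[3] + t * D[, 3]
    z >= -1e-9 & z <= h + 1e-9
  }
  t_side <- quad_smallest(A, B, C, z_ok)
  t_top <- disc_hit(o, D, h, r2)
  t_bot <- disc_hit(o, D, 0, r1)
  pmin(t_side, t_top, t_bot)
}

intersect_cap <- function(o, D, R, h) {
  cz <- h - R
  A <- rowSums(D^2)
  B <- 2 * (o[1] * D[, 1] + o[2] * D[, 2] + (o[3] - cz) * D[, 3])
  C <- o[1]^2 + o[2]^2 + (o[3] - cz)^2 - R^2
  z_ok <- function(t) (o[3] + t * D[, 3]) >= -1e-9
  t_sph <- quad_smallest(A, B, C, z_ok)
  a <- sqrt(h * (2 * R - h))
  pmin(t_sph, disc_hit(o, D, 0, a))
}

disc_hit <- function(o, D, z0, r) {
  t <- ifelse(abs(D[, 3]) > 1e-12, (z0 - o[3]) / D[, 3], Inf)
  x <- o[1] + t * D[, 1]; y <- o[2] + t * D[, 2]
  ok <- is.finite(t) & t > 1e-9 & (x^2 + y^2) <= r^2
  ifelse(ok, t, Inf)
}

# smallest root of A t^2 + B t + C = 0 with t > 0 and valid_fn(t); Inf if none
quad_smallest <- function(A, B, C, valid_fn) {
  n <- length(B)
  A <- rep_len(A, n)
  C <- rep_len(C, n)
  out <- rep(Inf, n)
  lin <- abs(A) < 1e-12
  if (any(lin)) {
    t <- ifelse(abs(B[lin]) > 1e-12, -C[lin] / B[lin], Inf)
    out[lin] <- t
  }
  q <- !lin
  if (any(q)) {
    disc <- B[q]^2 - 4 * A[q] * C[q]
    sq <- sqrt(pmax(disc, 0))
    r1 <- (-B[q] - sq) / (2 * A[q])
    r2 <- (-B[q] + sq) / (2 * A[q])
    r1[disc < 0] <- Inf; r2[disc < 0] <- Inf
    idx <- which(q)
    cand <- cbind(r1, r2)
    res <- rep(Inf, length(idx))
    for (j in 1:2) {
      t <- rep(Inf, n)
      t[idx] <- cand[, j]
      ok <- is.finite(t) & t > 1e-9 & valid_fn(t)
      res <- pmin(res, ifelse(ok[idx], t[idx], Inf))
    }
    out[idx] <- res
  }
  out
}

#' Render a two-view stereo pair with ground-truth correspondences
#'
#' Renders the scene from two cameras (defaults mimic a hand-held capture at
#' 90 and 75 degrees elevation) and returns exact pixel correspondences for
#' a set of scene keypoints: the card corners, card edge midpoints and
#' centre, and per-solid top-surface keypoints. The off-plane solid
#' keypoints matter: correspondences confined to the table plane are a
#' degenerate input for fundamental-matrix estimation.
#'
#' @param scene A `scene`.
#' @param cam_a,cam_b Two [camera_model()]s; both must see the full card.
#' @return List with `a` and `b` (two `render_output`s) and
#'   `correspondences`: a tibble with world coordinates (`x`, `y`, `z`) and
#'   the exact projections `ua`, `va`, `ub`, `vb` (0-based pixels).
#' @export
render_stereo <- function(scene, cam_a, cam_b) {
  ra <- render_depth(scene, cam_a)
  rb <- render_depth(scene, cam_b)
  kp <- scene_keypoints(scene)
  pa <- project_points(cam_a, kp)
  pb <- project_points(cam_b, kp)
  inb <- function(p, cam) {
    p$z_cam > 0 & p$u >= 0 & p$u <= cam$width - 1 & p$v >= 0 &
      p$v <= cam$height - 1
  }
  keep <- inb(pa, cam_a) & inb(pb, cam_b)
  corr <- tibble(
    name = attr(kp, "names_kp"), x = kp[, 1], y = kp[, 2], z = kp[, 3],
    ua = pa$u, va = pa$v, ub = pb$u, vb = pb$v
  )[keep, ]
  list(a = ra, b = rb, correspondences = corr)
}

scene_keypoints <- function(scene) {
  cw <- scene$card_corner_world
  mids <- (cw + cw[c(2, 3, 4, 1), ]) / 2
  centre <- matrix(colMeans(cw), 1, 3)
  pts <- rbind(cw, mids, centre)
  nms <- c(paste0("card_corner_", 1:4), paste0("card_mid_", 1:4), "card_centre")
  for (k in seq_along(scene$spec$solids)) {
    s <- scene$spec$solids[[k]]
    p <- s$params
    top <- switch(s$kind,
      cuboid = {
        w2 <- 0.4 * p[["width"]]; d2 <- 0.4 * p[["depth"]]; h <- p[["height"]]
        rbind(c(0, 0, h), c(w2, d2, h), c(-w2, d2, h), c(w2, -d2, h),
              c(-w2, -d2, h))
      },
      cylinder = top_ring(0.7 * p[["radius"]], p[["height"]]),
      frustum = top_ring(0.7 * p[["radius_top"]], p[["height"]]),
      spherical_cap = {
        R <- p[["radius"]]; h <- p[["height"]]
        a <- 0.6 * sqrt(h * (2 * R - h))
        zr <- (h - R) + sqrt(R^2 - a^2)
        rbind(c(0, 0, h), c(a, 0, zr), c(-a, 0, zr), c(0, a, zr), c(0, -a, zr))
      }
    )
    Rz <- rot_z(s$yaw_deg)
    world <- top %*% t(Rz) +
      matrix(c(s$x, s$y, 0), nrow(top), 3, byrow = TRUE)
    pts <- rbind(pts, world)
    nms <- c(nms, paste0("solid", k, "_kp", seq_len(nrow(top))))
  }
  attr(pts, "names_kp") <- nms
  pts
}

top_ring <- function(r, h) {
  rbind(c(0, 0, h), c(r, 0, h), c(-r, 0, h), c(0, r, h), c(0, -r, h))
}
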