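#' Rectify a two-view pair from ground-truth correspondences
#'
#' Estimates the fundamental matrix from the supplied correspondences with
#' the normalised 8-point algorithm, upgrades it to an essential matrix with
#' the known intrinsics, decomposes the relative pose (cheirality-tested on
#' the correspondences), and derives calibrated rectifying homographies that
#' align corresponding points on equal rows. With a calibrated rectification
#' the classic relation `Z = f * B / d` is exact in the rectified frame,
#' which keeps the disparity-to-depth conversion honest.
#'
#' @param correspondences Data frame with columns `ua`, `va`, `ub`, `vb`
#'   (matched pixel coordinates in views a and b); at least 8 rows.
#' @param camera_a,camera_b The two [camera_model()]s (intrinsics used).
#' @param image_a,image_b Optional intensity matrices to warp.
#' @return A `rectified_pair`: `homography_a`, `homography_b` (3x3 warps
#'   pixel_orig -> pixel_rect), `rect_a`, `rect_b` (warped images or NULL),
#'   `row_epsilon_px` (max residual row misalignment over the
#'   correspondences), `f_new` (rectified focal, px), `t_unit` (unit
#'   baseline vector in frame a), `R_rect` (rotation frame a -> rectified),
#'   `cx_new`, `cy_new`, and the rectified correspondences.
#' @export
rectify_pair <- function(correspondences, camera_a, camera_b,
                         image_a = NULL, image_b = NULL) {
  corr <- as_tibble(correspondences)
  stopifnot(all(c("ua", "va", "ub", "vb") %in% names(corr)))
  if (nrow(corr) < 8) {
    abort("at least 8 correspondences are required for rectification",
          class = "mealmetry_rectification_failed")
  }
  pa <- cbind(corr$ua, corr$va)
  pb <- cbind(corr$ub, corr$vb)
  FF <- eight_point(pa, pb)
  Ka <- intrinsic_matrix(camera_a)
  Kb <- intrinsic_matrix(camera_b)
  E <- t(Kb) %*% FF %*% Ka
  sv <- svd(E)
  E <- sv$u %*% diag(c(1, 1, 0)) %*% t(sv$v)
  rel <- decompose_essential(E, Ka, Kb, pa, pb)
  if (is.null(rel)) {
    abort("degenerate correspondences; relative pose unsolvable",
          class = "mealmetry_rectification_failed")
  }
  R <- rel$R; t_unit <- rel$t   # x_b = R x_a + t

  # rectifying rotation: new x-axis along the baseline (frame a)
  b <- as.numeric(-t(R) %*% t_unit)       # camera b centre in frame a
  r1 <- b / sqrt(sum(b^2))
  r2 <- pracma_cross(c(0, 0, 1), r1)
  n2 <- sqrt(sum(r2^2))
  if (n2 < 1e-9) r2 <- c(0, 1, 0) else r2 <- r2 / n2
  r3 <- pracma_cross(r1, r2)
  R_rect <- rbind(r1, r2, r3, deparse.level = 0)

  f_new <- (camera_a$fx + camera_a$fy) / 2
  cx_new <- camera_a$cx; cy_new <- camera_a$cy
  K_new <- matrix(c(f_new, 0, cx_new, 0, f_new, cy_new, 0, 0, 1),
                  3, 3, byrow = TRUE)
  Ha <- K_new %*% R_rect %*% solve(Ka)
  Hb <- K_new %*% R_rect %*% t(R) %*% solve(Kb)

  ra <- apply_homography(Ha, pa)
  rb <- apply_homography(Hb, pb)
  row_eps <- max(abs(ra[, 2] - rb[, 2]))

  rect_a <- if (!is.null(image_a)) warp_image(image_a, Ha) else NULL
  rect_b <- if (!is.null(image_b)) warp_image(image_b, Hb) else NULL

  structure(
    list(homography_a = Ha, homography_b = Hb,
         rect_a = rect_a, rect_b = rect_b,
         row_epsilon_px = row_eps,
         f_new = f_new, cx_new = cx_new, cy_new = cy_new,
         R_rect = R_rect, t_unit = t_unit, baseline_dir = b,
         corr_rect = tibble(ua = ra[, 1], va = ra[, 2],
                            ub = rb[, 1], vb = rb[, 2])),
    class = "rectified_pair"
  )
}

# normalised 8-point estimate of the fundamental matrix (x_b' F x_a = 0)
eight_point <- function(pa, pb) {
  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
           3, 3, byrow = TRUE)
  }
  Ta <- norm_t(pa); Tb <- norm_t(pb)
  qa <- cbind(pa, 1) %*% t(Ta)
  qb <- cbind(pb, 1) %*% t(Tb)
  A <- cbind(qb[, 1] * qa[, 1], qb[, 1] * qa[, 2], qb[, 1],
             qb[, 2] * qa[, 1], qb[, 2] * qa[, 2], qb[, 2],
             qa[, 1], qa[, 2], 1)
  f <- svd(A, nv = 9)$v[, 9]
  FF <- matrix(f, 3, 3, byrow = TRUE)
  sv <- svd(FF)
  FF <- sv$u %*% diag(c(sv$d[1:2], 0)) %*% t(sv$v)
  t(Tb) %*% FF %*% Ta
}

decompose_essential <- function(E, Ka, Kb, pa, pb) {
  sv <- svd(E)
  U <- sv$u; V <- sv$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  cands <- list(
    list(R = U %*% W %*% t(V), t = U[, 3]),
    list(R = U %*% W %*% t(V), t = -U[, 3]),
    list(R = U %*% t(W) %*% t(V), t = U[, 3]),
    list(R = U %*% t(W) %*% t(V), t = -U[, 3])
  )
  xa <- t(solve(Ka, t(cbind(pa, 1))))
  xb <- t(solve(Kb, t(cbind(pb, 1))))
  best <- NULL; best_n <- -1
  for (cand in cands) {
    z <- triangulate_depths(cand$R, cand$t, xa, xb)
    n_front <- sum(z$za > 0 & z$zb > 0)
    if (n_front > best_n) { best_n <- n_front; best <- cand }
  }
  if (best_n < nrow(pa) * 0.75) return(NULL)
  best
}

# midpoint triangulation depths for the cheirality test
triangulate_depths <- function(R, t, xa, xb) {
  n <- nrow(xa)
  za <- numeric(n); zb <- numeric(n)
  for (i in seq_len(n)) {
    # solve za * xa_i = R' (zb * xb_i - t) in least squares
    A <- cbind(xa[i, ], -t(R) %*% xb[i, ])
    rhs <- -as.numeric(t(R) %*% t)
    s <- tryCatch(qr.solve(A, rhs), error = function(e) c(NA, NA))
    za[i] <- s[1]; zb[i] <- s[2]
  }
  list(za = za, zb = zb)
}

apply_homography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  cbind(q[, 1] / q[, 3], q[, 2] / q[, 3])
}

# inverse-mapped bilinear warp; pixels sampling outside the source are NA
warp_image <- function(img, H, width = ncol(img), height = nrow(img)) {
  U <- rep(0:(width - 1), each = height)
  V <- rep(0:(height - 1), times = width)
  src <- apply_homography(solve(H), cbind(U, V))
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  h <- nrow(img); w <- ncol(img)
  inside <- x0 >= 0 & x0 <= w - 2 & y0 >= 0 & y0 <= h - 2
  out <- rep(NA_real_, length(x))
  i <- which(inside)
  idx <- function(r, c) (c) * h + r + 1  # 0-based row r, col c
  g <- img
  out[i] <-
    (1 - fx[i]) * (1 - fy[i]) * g[idx(y0[i], x0[i])] +
    fx[i] * (1 - fy[i]) * g[idx(y0[i], x0[i] + 1)] +
    (1 - fx[i]) * fy[i] * g[idx(y0[i] + 1, x0[i])] +
    fx[i] * fy[i] * g[idx(y0[i] + 1, x0[i] + 1)]
  matrix(out, height, width)
}

#' Block-matching disparity between a rectified pair
#'
#' For every pixel of the left (view a) rectified image, finds the integer
#' disparity `d` in `[0, max_disp]` minimising the sum of absolute
#' differences over a square block against the right image shifted by `d`.
#' The sign convention is left x minus right x, so disparities are
#' non-negative for points in front of the camera. Pixels whose best and
#' second-best costs (outside the immediate neighbourhood of the best) are
#' nearly tied are marked invalid: they are textureless or ambiguous.
#' Integer disparities only; this keeps the quantisation error bound exact.
#'
#' @param pair A `rectified_pair` with warped images, or a list with
#'   elements `rect_a`, `rect_b`.
#' @param block_px Odd block size >= 3.
#' @param max_disp Maximum disparity searched (>= 1).
#' @param margin_frac Uniqueness margin as a fraction of the best cost.
#' @return A `disparity_map`: `values` (px) and `valid` matrices.
#' @export
compute_disparity <- function(pair, block_px = 11, max_disp = NULL,
                              margin_frac = 0.05) {
  stopifnot(block_px >= 3, block_px %% 2 == 1)
  L <- pair$rect_a; R <- pair$rect_b
  stopifnot(is.matrix(L), is.matrix(R), all(dim(L) == dim(R)))
  if (is.null(max_disp)) max_disp <- floor(ncol(L) / 4)
  stopifnot(max_disp >= 1)
  h <- nrow(L); w <- ncol(L)
  r <- (block_px - 1) / 2
  Lz <- L; Lz[is.na(Lz)] <- 0
  Rz <- R; Rz[is.na(Rz)] <- 0
  eps_abs <- 1e-6 * block_px^2

  pass <- function(exclude_best = NULL, best_d = NULL) {
    best_cost <- matrix(Inf, h, w)
    arg <- matrix(NA_integer_, h, w)
    for (d in 0:max_disp) {
      ad <- matrix(Inf, h, w)
      if (d < w) {
        ad[, (d + 1):w] <- abs(Lz[, (d + 1):w, drop = FALSE] -
                                 Rz[, 1:(w - d), drop = FALSE])
      }
      cost <- box_sum(ad, r)
      if (!is.null(exclude_best)) {
        cost[abs(best_d - d) <= 1] <- Inf
      }
      upd <- cost < best_cost
      best_cost[upd] <- cost[upd]
      arg[upd] <- d
    }
    list(cost = best_cost, d = arg)
  }

  first <- pass()
  second <- pass(exclude_best = TRUE, best_d = first$d)
  margin <- margin_frac * first$cost + eps_abs
  # a saturated second-best means the search range was truncated at the
  # border: uniqueness cannot be verified there
  valid <- is.finite(first$cost) & first$cost < 1e5 & second$cost < 1e5 &
    (second$cost - first$cost) >= margin &
    !is.na(first$d)
  # undefined borders and pixels sampling outside the warp are invalid
  valid[is.na(L)] <- FALSE
  valid[, seq_len(min(r, w))] <- FALSE
  valid[, (w - r + 1):w] <- FALSE
  valid[seq_len(min(r, h)), ] <- FALSE
  valid[(h - r + 1):h, ] <- FALSE
  values <- matrix(0, h, w)
  values[valid] <- first$d[valid]
  structure(list(values = values, valid = valid), class = "disparity_map")
}

# sliding block sum with radius r (window 2r+1), Inf-aware via saturation
box_sum <- function(M, r) {
  h <- nrow(M); w <- ncol(M)
  M[!is.finite(M)] <- 1e6   # saturate so borders never win
  # cumulative sums down columns
  cs <- rbind(0, apply(M, 2, cumsum))
  lo <- pmax(1, (1:h) - r); hi <- pmin(h, (1:h) + r)
  Vr <- cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, t(apply(Vr, 1, cumsum)))
  lo2 <- pmax(1, (1:w) - r); hi2 <- pmin(w, (1:w) + r)
  cs2[, hi2 + 1, drop = FALSE] - cs2[, lo2, drop = FALSE]
}

#' Convert disparity to metric depth
#'
#' `Z = focal_px * baseline_mm / d` for valid pixels with `d > 0`;
#' non-positive disparities are invalid (no division error). Depth is
#' strictly decreasing in disparity for fixed focal and baseline.
#'
#' @param disp A `disparity_map`.
#' @param focal_px Rectified focal length in pixels (> 0).
#' @param baseline_mm Stereo baseline in millimetres (> 0).
#' @return A [depth_map()] in the rectified frame.
#' @export
disparity_to_depth <- function(disp, focal_px, baseline_mm) {
  stopifnot(inherits(disp, "disparity_map"), focal_px > 0, baseline_mm > 0)
  valid <- disp$valid & disp$values > 0
  Z <- matrix(0, nrow(disp$values), ncol(disp$values))
  Z[valid] <- focal_px * baseline_mm / disp$values[valid]
  depth_map(Z, valid)
}

#' Geometry-based depth back-end: stereo pair to first-view depth map
#'
#' The full geometry chain: card poses in both views give the metric
#' baseline, correspondences give the rectification, block matching gives
#' disparity, and `Z = f B / d` gives depth in the rectified frame, which is
#' finally resampled into the first view's pixel grid (depth along the first
#' camera's optical axis) so the volume pipeline can consume it like any
#' provider depth map.
#'
#' @param stereo Output of [render_stereo()] (or a compatible list with
#'   `a`, `b`, `correspondences`).
#' @param camera_a,camera_b The two cameras.
#' @param spec A [card_spec()].
#' @param block_px,margin_frac Block-matching parameters.
#' @return A [depth_map()] in view a's pixel grid (mm).
#' @export
stereo_depth_map <- function(stereo, camera_a, camera_b, spec = card_spec(),
                             block_px = 11, margin_frac = 0.05) {
  corr <- stereo$correspondences
  # card poses in each view anchor the metric baseline
  cc <- corr[grepl("^card_corner_", corr$name), ]
  stopifnot(nrow(cc) == 4)
  pose_a <- estimate_pose(cbind(cc$ua, cc$va), spec, camera_a)
  pose_b <- estimate_pose(cbind(cc$ub, cc$vb), spec, camera_b)
  ca <- as.numeric(-t(pose_a$rotation) %*% pose_a$translation)
  cb <- as.numeric(-t(pose_b$rotation) %*% pose_b$translation)
  baseline_mm <- sqrt(sum((ca - cb)^2))

  pair <- rectify_pair(corr, camera_a, camera_b,
                       stereo$a$intensity, stereo$b$intensity)
  # search range from the rectified correspondences themselves
  d_corr <- pair$corr_rect$ua - pair$corr_rect$ub
  max_disp <- ceiling(max(d_corr) * 1.3) + 8
  disp <- compute_disparity(pair, block_px = block_px, max_disp = max_disp,
                            margin_frac = margin_frac)
  depth_rect <- disparity_to_depth(disp, pair$f_new, baseline_mm)

  unrectify_depth(depth_rect, pair, camera_a)
}

# resample rectified depth into the original first-view grid, converting
# rectified-frame depth to depth along the original optical axis
unrectify_depth <- function(depth_rect, pair, camera_a) {
  h <- camera_a$height; w <- camera_a$width
  U <- rep(0:(w - 1), each = h)
  V <- rep(0:(h - 1), times = w)
  pr <- apply_homography(pair$homography_a, cbind(U, V))
  ur <- round(pr[, 1]); vr <- round(pr[, 2])
  hr <- nrow(depth_rect$values); wr <- ncol(depth_rect$values)
  ok <- ur >= 0 & ur <= wr - 1 & vr >= 0 & vr <= hr - 1
  lin <- ur[ok] * hr + vr[ok] + 1
  z <- rep(0, length(U)); vld <- rep(FALSE, length(U))
  vld[ok] <- depth_rect$valid[lin]
  z[ok] <- depth_rect$values[lin]
  # rectified z -> depth along original axis: X_a = R_rect' X_rect
  sel <- vld
  if (any(sel)) {
    xr <- (pr[sel, 1] - pair$cx_new) / pair$f_new * z[sel]
    yr <- (pr[sel, 2] - pair$cy_new) / pair$f_new * z[sel]
    za <- pair$R_rect[1, 3] * xr + pair$R_rect[2, 3] * yr +
      pair$R_rect[3, 3] * z[sel]
    z[sel] <- za
    bad <- z < 1e-6 & vld
    vld[bad] <- FALSE; z[bad] <- 0
  }
  depth_map(matrix(z, h, w), matrix(vld, h, w))
}
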