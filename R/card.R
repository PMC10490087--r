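#' Reference card specification
#'
#' Physical dimensions of the fiducial card placed beside the meal. By
#' convention width >= height (landscape ordering). The default is the
#' credit-card format.
#'
#' @param width_mm,height_mm Card dimensions in millimetres.
#' @return A `card_spec`.
#' @export
card_spec <- function(width_mm = 85.6, height_mm = 54.0) {
  stopifnot(width_mm > 0, height_mm > 0)
  if (width_mm < height_mm) {
    abort("card width must be >= height (landscape convention)",
          class = "mealmetry_bad_card_spec")
  }
  structure(list(width_mm = width_mm, height_mm = height_mm),
            class = "card_spec")
}

#' Detect the reference card in an intensity image
#'
#' Baseline detector for the synthetic renderer's card appearance: the card
#' is a distinct near-white intensity band. Pixels above `threshold` are
#' grouped into connected components; each component's convex hull is
#' simplified to a quadrilateral and scored by rectangularity (component
#' area / quadrilateral area) times area. The best-scoring plausible
#' quadrilateral wins. Real-image card detection is a pluggable interface:
#' any `card_detection` built from externally supplied corners can be fed to
#' [estimate_pose()].
#'
#' @param intensity Numeric matrix in `[0, 1]` (single channel).
#' @param threshold Intensity threshold separating the card band.
#' @param min_area_px Minimum plausible component area in pixels.
#' @param min_rectangularity Minimum plausible rectangularity score.
#' @return A `card_detection` with `corners_px` (4 x 2 matrix, columns u, v,
#'   0-based pixels, ordered around the quadrilateral starting on a long
#'   edge) and `confidence` in `[0, 1]`. Raises a condition of class
#'   `mealmetry_card_not_found` when no plausible card is present; callers
#'   are expected to catch it and fall back to standard servings.
#' @export
detect_card <- function(intensity, threshold = 0.85, min_area_px = 200,
                        min_rectangularity = 0.7) {
  stopifnot(is.matrix(intensity))
  bin <- intensity >= threshold
  if (!any(bin)) {
    abort("no card-like region found", class = "mealmetry_card_not_found")
  }
  labels <- label_components(bin)
  best <- NULL
  for (lab in seq_len(max(labels))) {
    px <- which(labels == lab, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area_px) next
    u <- px[, 2] - 1; v <- px[, 1] - 1
    quad <- hull_quadrilateral(u, v)
    if (is.null(quad)) next
    qa <- polygon_area(quad)
    if (qa <= 0) next
    rect <- min(area / qa, 1)
    if (rect < min_rectangularity) next
    score <- rect * area
    if (is.null(best) || score > best$score) {
      best <- list(quad = quad, rect = rect, score = score, lab = lab)
    }
  }
  if (is.null(best)) {
    abort("no card-like region found", class = "mealmetry_card_not_found")
  }
  corners <- order_corners(expand_quad(best$quad))
  corners <- refine_corners(corners, bin, labels, best$lab)
  structure(list(corners_px = corners, confidence = best$rect),
            class = "card_detection")
}

# two-pass connected-component labelling (4-connectivity) on row runs
label_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  prev_runs <- NULL  # matrix: start col, end col, label
  for (r in seq_len(h)) {
    row <- bin[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    runs <- cbind(starts[rl$values], ends[rl$values], 0L)
    for (i in seq_len(nrow(runs))) {
      lab <- 0L
      if (!is.null(prev_runs)) {
        for (j in seq_len(nrow(prev_runs))) {
          if (runs[i, 1] <= prev_runs[j, 2] && runs[i, 2] >= prev_runs[j, 1]) {
            plab <- find(prev_runs[j, 3])
            if (lab == 0L) lab <- plab
            else if (plab != lab) parent[plab] <- find(lab)
          }
        }
      }
      if (lab == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab <- nxt
      }
      runs[i, 3] <- lab
      labels[r, runs[i, 1]:runs[i, 2]] <- lab
    }
    prev_runs <- runs
  }
  if (nxt == 0L) return(labels)
  # path-compress and relabel densely
  roots <- vapply(seq_len(nxt), find, integer(1))
  dense <- match(roots, unique(roots))
  mask <- labels > 0L
  labels[mask] <- dense[labels[mask]]
  labels
}

# simplify the convex hull of a pixel set to 4 vertices (Visvalingam)
hull_quadrilateral <- function(u, v) {
  if (length(u) < 4) return(NULL)
  hull <- grDevices::chull(u, v)
  pts <- cbind(u[hull], v[hull])
  while (nrow(pts) > 4) {
    n <- nrow(pts)
    a <- pts[c(n, 1:(n - 1)), ]; b <- pts; c <- pts[c(2:n, 1), ]
    area <- abs((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
                  (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
    pts <- pts[-which.min(area), , drop = FALSE]
  }
  if (nrow(pts) < 4) return(NULL)
  pts
}

polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# pixel centres underestimate the card outline by about half a pixel
expand_quad <- function(quad) {
  ctr <- colMeans(quad)
  quad + 0.5 * sign(sweep(quad, 2, ctr))
}

# sub-pixel refinement: fit a total-least-squares line to the boundary
# pixels of each edge, push it outward by the half-pixel sampling bias,
# and intersect adjacent lines
refine_corners <- function(corners, bin, labels, lab) {
  h <- nrow(bin); w <- ncol(bin)
  comp <- labels == lab
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- comp
  inner <- pad[2:(h + 1), 2:(w + 1)]
  nb <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge_px <- which(inner & !nb, arr.ind = TRUE)
  bu <- edge_px[, 2] - 1; bv <- edge_px[, 1] - 1
  ctr <- colMeans(corners)
  lines <- vector("list", 4)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    e <- b - a; len <- sqrt(sum(e^2)); e <- e / len
    nrm <- c(-e[2], e[1])
    du <- bu - a[1]; dv <- bv - a[2]
    s <- du * e[1] + dv * e[2]
    d <- du * nrm[1] + dv * nrm[2]
    sel <- abs(d) < 1.5 & s > 0.12 * len & s < 0.88 * len
    if (sum(sel) < 4) return(corners)
    p <- cbind(bu[sel], bv[sel])
    mu <- colMeans(p)
    ev <- eigen(cov(p))$vectors[, 1]
    nfit <- c(-ev[2], ev[1])
    # outward = away from the quad centre; boundary centres sit ~0.5 px inside
    if (sum((mu - ctr) * nfit) < 0) nfit <- -nfit
    lines[[i]] <- list(n = nfit, c = sum(nfit * mu) + 0.5)
  }
  out <- corners
  for (i in 1:4) {
    l1 <- lines[[((i - 2) %% 4) + 1]]  # edge ending at corner i
    l2 <- lines[[i]]                   # edge starting at corner i
    A <- rbind(l1$n, l2$n)
    if (abs(det(A)) < 1e-9) return(corners)
    out[i, ] <- solve(A, c(l1$c, l2$c))
  }
  out
}

# consistent cyclic order starting on a long edge; the residual two-fold
# ambiguity of a plain rectangle is resolved by a deterministic tie-break
order_corners <- function(quad) {
  ctr <- colMeans(quad)
  ang <- atan2(quad[, 2] - ctr[2], quad[, 1] - ctr[1])
  quad <- quad[order(ang), , drop = FALSE]
  edge_len <- sqrt(rowSums((quad[c(2:4, 1), ] - quad)^2))
  starts <- if (edge_len[1] + edge_len[3] >= edge_len[2] + edge_len[4]) {
    c(1, 3)
  } else {
    c(2, 4)
  }
  # between the two long-edge starts, pick the corner closer to the origin
  d <- rowSums(quad[starts, ]^2)
  s <- starts[which.min(d)]
  idx <- ((s - 1 + 0:3) %% 4) + 1
  out <- quad[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}

#' Recover the card pose from detected corners
#'
#' Solves the planar pose from the homography between the metric card
#' rectangle and the detected pixel corners (direct linear transform,
#' decomposed with the camera intrinsics). Of the two algebraic solutions
#' the one with the card in front of the camera and its normal facing the
#' camera is returned.
#'
#' @param detection A `card_detection` (or a 4 x 2 matrix of corner pixels
#'   ordered around the quadrilateral starting on a long edge).
#' @param spec A [card_spec()].
#' @param camera A [camera_model()] (its intrinsics are used).
#' @return A `card_pose`: `plane_normal` (unit, camera frame, pointing from
#'   the card toward the camera), `plane_point` (card centre, camera frame,
#'   mm), `centre_distance_mm`, `centre_depth_mm` (optical-axis depth of the
#'   centre), and the rigid card-to-camera transform (`rotation`,
#'   `translation`) with +z on the camera side of the card plane.
#' @export
estimate_pose <- function(detection, spec, camera) {
  corners <- if (inherits(detection, "card_detection")) {
    detection$corners_px
  } else {
    as.matrix(detection)
  }
  stopifnot(nrow(corners) == 4, ncol(corners) == 2)
  if (polygon_area(corners) < 1e-6) {
    abort("card corners are collinear; pose is unsolvable",
          class = "mealmetry_pose_unsolvable")
  }
  W <- spec$width_mm; Hc <- spec$height_mm
  obj <- rbind(c(0, 0), c(W, 0), c(W, Hc), c(0, Hc))
  H <- homography_dlt(obj, corners)
  K <- intrinsic_matrix(camera)
  M <- solve(K, H)
  lambda <- 2 / (sqrt(sum(M[, 1]^2)) + sqrt(sum(M[, 2]^2)))
  r1 <- lambda * M[, 1]; r2 <- lambda * M[, 2]; t <- lambda * M[, 3]
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  R0 <- cbind(r1, r2, pracma_cross(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  # ensure the camera sits on the +z side of the card frame
  cam_in_card <- as.numeric(-t(R) %*% t)
  if (cam_in_card[3] < 0) R <- R %*% diag(c(1, -1, -1))
  centre <- as.numeric(R %*% c(W / 2, Hc / 2, 0) + t)
  normal <- R[, 3]
  if (sum(normal * centre) > 0) normal <- -normal
  structure(
    list(plane_normal = normal, plane_point = centre,
         centre_distance_mm = sqrt(sum(centre^2)),
         centre_depth_mm = centre[3],
         rotation = R, translation = t),
    class = "card_pose"
  )
}

homography_dlt <- function(obj, img) {
  # normalise both point sets for conditioning
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / mean(d)
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(T = T, p = cbind(p, 1) %*% t(T))
  }
  a <- norm_pts(obj); b <- norm_pts(img)
  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    X <- a$p[i, ]; x <- b$p[i, 1]; y <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  h <- svd(A, nv = 9)$v[, 9]
  H <- solve(b$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

#' Align a depth map to metric scale using the card pose
#'
#' The card pose predicts the true optical-axis depth of the card centre;
#' dividing it by the median observed depth over the card region gives the
#' single scale factor that converts a provider's depth map (which may be in
#' arbitrary units) to millimetres. The median makes the alignment robust to
#' speckle outliers. Providers that are already metric get a scale of about
#' 1, which is still applied.
#'
#' @param depth A [depth_map()] (any consistent units).
#' @param pose A `card_pose` from [estimate_pose()].
#' @param card_region_mask Logical matrix marking card pixels.
#' @return List with `scale` (unitless) and `aligned` (a metric
#'   [depth_map()], mm).
#' @export
metric_align <- function(depth, pose, card_region_mask) {
  stopifnot(inherits(depth, "depth_map"), inherits(pose, "card_pose"))
  sel <- card_region_mask & depth$valid
  if (!any(sel)) {
    abort("no valid depth on the card region; alignment impossible",
          class = "mealmetry_alignment_impossible")
  }
  med <- median(depth$values[sel])
  scale <- pose$centre_depth_mm / med
  list(scale = scale, aligned = depth_map(depth$values * scale, depth$valid))
}
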