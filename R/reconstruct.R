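#' Epipolar correspondence between two projections
#'
#' For every segment present in both views, finds an order-preserving
#' correspondence between the two projected centerlines by dynamic
#' programming over monotone alignments, with the per-pair cost equal to the
#' epipolar residual: the pixel distance from the point in view B to the
#' epipolar line of its partner in view A.  Vessel centerlines are ordered
#' curves, so the monotone alignment is the globally optimal matching and is
#' deterministic.
#'
#' @param projA,projB `view_projection` objects from the same gantry pair.
#' @param gantry The [gantry_geometry()] used to acquire them.
#' @return A tibble of matches (`segment`, indices `i`, `j`, pixel
#'   coordinates and widths in both views, `residual` in px), with segment
#'   parenthood metadata attached.  Segments visible in only one view are
#'   excluded with a warning, mirroring the exclusion of vessels not
#'   identifiable in both angiographic views.
#' @export
correspond_points <- function(projA, projB, gantry) {
  stopifnot(inherits(projA, "view_projection"),
            inherits(projB, "view_projection"))
  camA <- gantry_camera(gantry, projA$view)
  camB <- gantry_camera(gantry, projB$view)
  common <- intersect(names(projA$segments), names(projB$segments))
  only <- setdiff(union(names(projA$segments), names(projB$segments)), common)
  if (length(only) > 0)
    warn(paste0("segments visible in only one view excluded: ",
                paste(only, collapse = ", ")))
  out <- lapply(common, function(id) {
    sa <- projA$segments[[id]]
    sb <- projB$segments[[id]]
    R <- epipolar_residuals(sa$uv, camA, camB)  # nA x nB
    res <- abs(R$a %*% rbind(t(sb$uv), 1))      # line-point distances
    path <- dtw_path(res)
    tibble(
      segment = id, i = path[, 1], j = path[, 2],
      uA = sa$uv[path[, 1], 1], vA = sa$uv[path[, 1], 2],
      uB = sb$uv[path[, 2], 1], vB = sb$uv[path[, 2], 2],
      widthA = sa$width[path[, 1]], widthB = sb$width[path[, 2]],
      residual = res[cbind(path[, 1], path[, 2])]
    )
  })
  matches <- bind_rows(out)
  meta <- bind_rows(lapply(common, function(id) {
    s <- projA$segments[[id]]
    tibble(segment = id, parent = s$parent, parent_frac = s$parent_frac)
  }))
  attr(matches, "segment_meta") <- meta
  attr(matches, "views") <- c(projA$view, projB$view)
  matches
}

# epipolar lines in view B for pixels of view A: each row a normalized line
# (a, b, c) with a^2 + b^2 = 1 so that |a u + b v + c| is the px distance
epipolar_residuals <- function(uvA, camA, camB) {
  dirs <- pixel_ray(uvA, camA)
  p1 <- sweep(dirs * 0.5 * camA$sod, 2, camA$S, `+`)
  p2 <- sweep(dirs * 1.6 * camA$sod, 2, camA$S, `+`)
  q1 <- project_points(p1, camB)$uv
  q2 <- project_points(p2, camB)$uv
  d <- q2 - q1
  nrm <- sqrt(rowSums(d^2))
  a <- cbind(-d[, 2], d[, 1]) / nrm
  cc <- -(a[, 1] * q1[, 1] + a[, 2] * q1[, 2])
  list(a = cbind(a, cc))
}

# monotone alignment (dynamic time warping); returns strictly-increasing
# matched index pairs (the diagonal steps of the optimal path)
dtw_path <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  move <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    dim1 <- D[i, ]
    for (j in seq_len(m)) {
      best <- D[i, j]; mv <- 1L               # diagonal
      if (D[i, j + 1] < best) { best <- D[i, j + 1]; mv <- 2L }  # skip in A
      if (D[i + 1, j] < best) { best <- D[i + 1, j]; mv <- 3L }  # skip in B
      D[i + 1, j + 1] <- cost[i, j] + best
      move[i + 1, j + 1] <- mv
    }
  }
  path <- matrix(0L, 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    mv <- move[i + 1, j + 1]
    if (mv == 1L) { path <- rbind(c(i, j), path); i <- i - 1; j <- j - 1 }
    else if (mv == 2L) i <- i - 1
    else j <- j - 1
  }
  path
}

#' Triangulate matched points into a 3D centerline tree
#'
#' Each matched pixel pair is back-projected to a ray from its view's X-ray
#' source; the 3D point is the midpoint of the common perpendicular between
#' the two rays, and the length of that perpendicular (the ray miss distance)
#' is recorded as a per-point triangulation gap.  Pairs whose rays are nearly
#' parallel (angle below `min_angle` degrees, foreshortened geometry) are not
#' triangulated directly but interpolated from their neighbours along the
#' segment.  Tree topology is inherited from the segment labels carried
#' through projection.
#'
#' @param matches Output of [correspond_points()].
#' @param gantry The gantry geometry.
#' @param min_angle Minimum ray crossing angle (degrees).
#' @return A `vessel_tree` with centerlines only (radii unset); the matches
#'   (with per-point `gap` in mm) are attached as attribute `"matches"`.
#' @export
triangulate_matches <- function(matches, gantry, min_angle = 1) {
  meta <- attr(matches, "segment_meta")
  views <- attr(matches, "views")
  camA <- gantry_camera(gantry, views[1])
  camB <- gantry_camera(gantry, views[2])
  dA <- pixel_ray(cbind(matches$uA, matches$vA), camA)
  dB <- pixel_ray(cbind(matches$uB, matches$vB), camB)
  w0 <- matrix(camA$S - camB$S, nrow(matches), 3, byrow = TRUE)
  b <- rowSums(dA * dB)
  d <- rowSums(dA * w0)
  e <- rowSums(dB * w0)
  denom <- 1 - b^2
  crossang <- acos(pmin(1, abs(b))) * 180 / pi
  ok <- crossang >= min_angle
  t1 <- (b * e - d) / denom
  t2 <- (e - b * d) / denom
  P1 <- sweep(dA * t1, 2, camA$S, `+`)
  P2 <- sweep(dB * t2, 2, camB$S, `+`)
  mid <- (P1 + P2) / 2
  gap <- sqrt(rowSums((P1 - P2)^2))
  matches$gap <- gap
  matches$x <- mid[, 1]; matches$y <- mid[, 2]; matches$z <- mid[, 3]
  matches$foreshortened <- !ok
  segs <- list()
  for (id in unique(matches$segment)) {
    rows <- matches[matches$segment == id, ]
    pts <- cbind(rows$x, rows$y, rows$z)
    if (any(rows$foreshortened)) {
      idx <- seq_len(nrow(pts))
      for (c0 in 1:3)
        pts[rows$foreshortened, c0] <- approx(
          idx[!rows$foreshortened], pts[!rows$foreshortened, c0],
          xout = idx[rows$foreshortened], rule = 2)$y
    }
    keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-9)
    pts <- pts[keep, , drop = FALSE]
    mrow <- meta[meta$segment == id, ]
    segs[[id]] <- new_segment(id, pts, rep(NA_real_, nrow(pts)),
                              parent = mrow$parent,
                              parent_frac = mrow$parent_frac)
    attr(segs[[id]], "match_rows") <- which(matches$segment == id)[keep]
  }
  root <- names(segs)[vapply(segs, function(s) is.na(s$parent), logical(1))][1]
  tr <- new_vessel_tree(segs, root)
  attr(tr, "matches") <- matches
  tr
}

#' Recover cross-sectional radii from projected widths
#'
#' The radius at each reconstructed 3D point is `width * pixel / (2 *
#' magnification)` where the magnification is recomputed from the point's
#' reconstructed depth along each view axis; the two per-view estimates are
#' averaged and their relative disagreement recorded.
#'
#' @param tree Centerline tree from [triangulate_matches()].
#' @param gantry The gantry geometry.
#' @param disagreement_warn Relative per-view radius disagreement above which
#'   a message is emitted.
#' @return The tree with radii filled in; per-point per-view disagreement is
#'   attached to each segment as attribute `"radius_disagreement"`.
#' @export
recover_diameters <- function(tree, gantry, disagreement_warn = 0.1) {
  matches <- attr(tree, "matches")
  if (is.null(matches)) abort("tree carries no match attribute; run triangulate_matches() first")
  if (any(matches$widthA <= 0) || any(matches$widthB <= 0))
    abort("non-positive projected width")
  views <- attr(matches, "views")
  camA <- gantry_camera(gantry, views[1])
  camB <- gantry_camera(gantry, views[2])
  P <- cbind(matches$x, matches$y, matches$z)
  magA <- camA$sid / drop(sweep(P, 2, camA$S) %*% camA$zv)
  magB <- camB$sid / drop(sweep(P, 2, camB$S) %*% camB$zv)
  rA <- matches$widthA * camA$pixel / (2 * magA)
  rB <- matches$widthB * camB$pixel / (2 * magB)
  r <- (rA + rB) / 2
  disag <- abs(rA - rB) / pmax(r, 1e-9)
  if (mean(disag) > disagreement_warn)
    inform(sprintf(
      "per-view radius estimates disagree by %.1f%% on average", 100 * mean(disag)))
  for (id in names(tree$segments)) {
    rows <- attr(tree$segments[[id]], "match_rows")
    tree$segments[[id]]$radii <- r[rows]
    attr(tree$segments[[id]], "radius_disagreement") <- disag[rows]
  }
  tree
}

#' Full two-view reconstruction
#'
#' Convenience wrapper: [correspond_points()], [triangulate_matches()],
#' [recover_diameters()].
#'
#' @inheritParams correspond_points
#' @param min_angle Passed to [triangulate_matches()].
#' @return A reconstructed `vessel_tree` with radii.
#' @export
reconstruct_tree <- function(projA, projB, gantry, min_angle = 1) {
  m <- correspond_points(projA, projB, gantry)
  tr <- triangulate_matches(m, gantry, min_angle = min_angle)
  recover_diameters(tr, gantry)
}

#' Score a reconstruction against ground truth
#'
#' Both centerlines are resampled to `n_resample` points at equal arclength
#' fractions per segment; the report carries the per-segment centerline RMSE
#' (mm) and mean absolute diameter error (mm).
#'
#' @param recon,truth `vessel_tree` objects with matching segment labels.
#' @param n_resample Resampling points per segment.
#' @return A `reconstruction_report` tibble.
#' @export
evaluate_reconstruction <- function(recon, truth, n_resample = 200) {
  un <- c(setdiff(names(recon$segments), names(truth$segments)),
          setdiff(names(truth$segments), names(recon$segments)))
  if (length(un) > 0)
    abort(paste0("unmatched segment labels: ", paste(unique(un), collapse = ", ")))
  fr <- seq(0, 1, length.out = n_resample)
  rows <- lapply(names(truth$segments), function(id) {
    st <- truth$segments[[id]]
    sr <- recon$segments[[id]]
    Lt <- max(arclengths(st$points)); Lr <- max(arclengths(sr$points))
    it <- interp_polyline(st$points, fr * Lt, st$radii)
    ir <- interp_polyline(sr$points, fr * Lr, sr$radii)
    d2 <- rowSums((it$points - ir$points)^2)
    diam_err <- if (all(is.finite(ir$values)))
      mean(abs(2 * it$values - 2 * ir$values)) else NA_real_
    tibble(segment = id, rmse = sqrt(mean(d2)),
           diameter_mae = diam_err, n_points = nrow(sr$points))
  })
  out <- bind_rows(rows)
  class(out) <- c("reconstruction_report", class(out))
  out
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("<reconstruction_report> %d segments, mean RMSE %.4g mm\n",
              nrow(x), mean(x$rmse)))
  NextMethod()
}
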