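#' C-arm gantry geometry for a biplane acquisition
#'
#' Describes the two views of a biplane (or sequential two-view) angiographic
#' acquisition.  Angles follow the clinical convention: the primary angle
#' `alpha` rotates the source-detector axis about the patient's head-foot
#' axis (positive = LAO, negative = RAO) and the secondary angle `beta` about
#' the rotated left-right axis (positive = cranial, negative = caudal); the
#' composition order is primary-then-secondary.  The isocenter is the world
#' origin; world coordinates are right-handed with x toward the patient's
#' left, y anterior and z cranial.  Detector pixel (0,0) is top-left with
#' pixel centers at half-integer offsets.
#'
#' @param view1,view2 Lists with elements `alpha`, `beta` (degrees), `sod`
#'   (source-isocenter distance, mm), `sid` (source-detector distance, mm),
#'   `pixel` (mm/pixel) and `detector` (c(nu, nv) pixels).
#' @return A `gantry_geometry` object.  Construction fails unless the two
#'   view axes are separated by more than 45 degrees, the geometric condition
#'   required for a well-posed two-view reconstruction.
#' @export
gantry_geometry <- function(
    view1 = list(alpha = -30, beta = 0),
    view2 = list(alpha = 40, beta = 20)) {
  fill <- function(v) {
    utils::modifyList(list(alpha = 0, beta = 0, sod = 750, sid = 1000,
                           pixel = 0.2, detector = c(1024, 1024)), v)
  }
  g <- structure(list(views = list(fill(view1), fill(view2))),
                 class = "gantry_geometry")
  for (v in g$views) {
    if (v$sod <= 0 || v$sid <= 0 || v$pixel <= 0)
      abort("gantry distances and pixel size must be positive")
    if (v$sid < v$sod)
      abort("source-detector distance must be at least the source-isocenter distance")
  }
  sep <- gantry_separation(g)
  if (sep <= 45)
    abort(sprintf(
      "gantry view separation is %.1f degrees; biplane reconstruction requires separation angles > 45 degrees",
      sep))
  g
}

#' Angular separation between the two view axes (degrees)
#' @param gantry A `gantry_geometry`.
#' @export
gantry_separation <- function(gantry) {
  z1 <- gantry_camera(gantry, 1)$zv
  z2 <- gantry_camera(gantry, 2)$zv
  acos(pmin(1, pmax(-1, sum(z1 * z2)))) * 180 / pi
}

# camera frame of view k: source position S, detector in-plane axes xv, yv,
# axis zv (source towards detector), plus sid/pixel/principal point
gantry_camera <- function(gantry, k) {
  v <- gantry$views[[k]]
  R <- rot_z(v$alpha) %*% rot_x(v$beta)
  zv <- drop(R %*% c(0, 1, 0))    # source sits anterior for alpha=beta=0
  xv <- drop(R %*% c(1, 0, 0))
  yv <- drop(R %*% c(0, 0, -1))   # image v grows caudally
  S <- -v$sod * zv
  list(S = S, xv = xv, yv = yv, zv = zv, sod = v$sod, sid = v$sid,
       pixel = v$pixel, detector = v$detector,
       center = v$detector / 2)
}

# perspective projection of 3D points (mm) into view k: pixel coords and
# per-point magnification
project_points <- function(P, cam) {
  Q <- sweep(P, 2, cam$S)
  t <- Q %*% cam$zv
  if (any(t <= 0)) abort("point behind the X-ray source")
  m <- cam$sid / drop(t)
  u <- cam$center[1] + (Q %*% cam$xv) * m / cam$pixel
  v <- cam$center[2] + (Q %*% cam$yv) * m / cam$pixel
  list(uv = cbind(drop(u), drop(v)), mag = m)
}

# back-project a pixel to a world ray from the source of view k
pixel_ray <- function(uv, cam) {
  iu <- (uv[, 1] - cam$center[1]) * cam$pixel
  iv <- (uv[, 2] - cam$center[2]) * cam$pixel
  dirs <- outer(rep(cam$sid, nrow(uv)), cam$zv) + outer(iu, cam$xv) +
    outer(iv, cam$yv)
  dirs / sqrt(rowSums(dirs^2))
}

#' Project a vessel tree onto the two gantry views
#'
#' Cone-beam (perspective) projection: each centerline point is projected
#' along the ray from the X-ray point source to the detector plane, and the
#' projected vessel width at that point is `2 * radius * magnification /
#' pixel`, where the local magnification is the source-detector distance over
#' the point's depth along the view axis.  Segment labels (and parenthood)
#' are retained on the projections so that reconstruction accuracy can be
#' scored per segment.
#'
#' @param tree A `vessel_tree`.
#' @param gantry A [gantry_geometry()].
#' @return A list of two `view_projection` objects.
#' @export
project_tree <- function(tree, gantry) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(gantry, "gantry_geometry"))
  lapply(1:2, function(k) {
    cam <- gantry_camera(gantry, k)
    segs <- lapply(tree$segments, function(s) {
      pr <- project_points(s$points, cam)
      if (any(pr$uv < 0) || any(pr$uv[, 1] > cam$detector[1]) ||
          any(pr$uv[, 2] > cam$detector[2]))
        abort(sprintf(
          "segment '%s' projects outside the detector in view %d", s$id, k))
      list(uv = pr$uv, width = 2 * s$radii * pr$mag / cam$pixel,
           parent = s$parent, parent_frac = s$parent_frac)
    })
    structure(list(view = k, segments = segs, detector = cam$detector,
                   pixel = cam$pixel),
              class = "view_projection")
  })
}

#' @export
print.view_projection <- function(x, ...) {
  cat(sprintf("<view_projection> view %d, %d segments, %d points\n", x$view,
              length(x$segments),
              sum(vapply(x$segments, function(s) nrow(s$uv), 1L))))
  invisible(x)
}

#' Add measurement noise to a projection
#'
#' Additive Gaussian jitter on projected centerline points and widths,
#' emulating detection error in the 2D vessel analysis.  Deterministic for a
#' fixed seed.
#'
#' @param proj A `view_projection`.
#' @param centerline_sd Jitter standard deviation on pixel coordinates.
#' @param width_sd Jitter standard deviation on projected widths (pixels).
#' @param seed Integer seed.
#' @return The degraded `view_projection`.
#' @export
degrade_projection <- function(proj, centerline_sd = 0, width_sd = 0,
                               seed = 1) {
  stopifnot(inherits(proj, "view_projection"))
  if (centerline_sd < 0 || width_sd < 0) abort("jitter sds must be >= 0")
  if (centerline_sd == 0 && width_sd == 0) return(proj)
  with_seed(seed, {
    proj$segments <- lapply(proj$segments, function(s) {
      n <- nrow(s$uv)
      s$uv <- s$uv + matrix(rnorm(2 * n, sd = centerline_sd), n, 2)
      s$width <- pmax(s$width + rnorm(n, sd = width_sd), 1e-3)
      s
    })
    proj
  })
}

#' Serialize a projection to JSON
#' @param proj A `view_projection`.
#' @param path Output path; `NULL` returns the JSON string.
#' @export
write_projection <- function(proj, path = NULL) {
  obj <- list(view = proj$view, detector = proj$detector, pixel = proj$pixel,
              segments = lapply(names(proj$segments), function(id) {
                s <- proj$segments[[id]]
                list(id = id, uv = unname(s$uv), width = s$width,
                     parent = if (is.na(s$parent)) NULL else s$parent,
                     parent_frac = if (is.na(s$parent_frac)) NULL
                                   else s$parent_frac)
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a projection from JSON
#' @param path Path or JSON string produced by [write_projection()].
#' @export
read_projection <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  segs <- list()
  for (s in obj$segments) {
    uv <- s$uv
    if (!is.matrix(uv)) uv <- do.call(rbind, lapply(uv, as.numeric))
    scalar_or <- function(x, default)
      if (is.null(x) || length(x) == 0) default else x
    segs[[s$id]] <- list(
      uv = uv,
      width = as.numeric(s$width),
      parent = scalar_or(s$parent, NA_character_),
      parent_frac = scalar_or(s$parent_frac, NA_real_))
  }
  structure(list(view = obj$view, segments = segs,
                 detector = as.numeric(obj$detector), pixel = obj$pixel),
            class = "view_projection")
}
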