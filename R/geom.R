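#' Prune or truncate branches of a vessel tree
#'
#' Implements the complete-to-matched model reduction: a complete model
#' (every identifiable side branch) is pruned down to the branch set of a
#' coarser reference by removing whole branches (with their subtrees) or
#' truncating segments at a given arclength.  Remaining geometry is left
#' bitwise unchanged, so sections of the pruned model align exactly with the
#' same sections of the complete model.
#'
#' @param tree A `vessel_tree`.
#' @param spec A list of elements `list(segment =, action = "remove")` or
#'   `list(segment =, action = "truncate", at_mm =)`, or a data frame with
#'   columns `segment`, `action`, `at_mm`.
#' @return The pruned `vessel_tree`.
#' @export
prune_tree <- function(tree, spec) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (is.data.frame(spec))
    spec <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
  if (length(spec) == 0) return(tree)
  descendants <- function(id) {
    kids <- names(Filter(function(s) identical(s$parent, id), tree$segments))
    c(kids, unlist(lapply(kids, descendants)))
  }
  for (sp in spec) {
    if (is.null(tree$segments[[sp$segment]])) {
      # tolerate re-pruning: removing an absent branch is a no-op, which
      # makes pruning idempotent
      warn(sprintf("segment '%s' not present; prune action skipped",
                   sp$segment))
      next
    }
    if (sp$action == "remove") {
      if (sp$segment == tree$root) abort("the root segment cannot be removed")
      drop_ids <- c(sp$segment, descendants(sp$segment))
      tree$segments[drop_ids] <- NULL
      tree$stenoses <- Filter(function(st) !st$segment %in% drop_ids,
                              tree$stenoses)
    } else if (sp$action == "truncate") {
      seg <- tree$segments[[sp$segment]]
      s <- arclengths(seg$points)
      L <- max(s)
      at <- sp$at_mm
      if (at <= 0 || at >= L)
        abort(sprintf("truncation arclength %.2f mm outside segment '%s' (length %.2f mm)",
                      at, sp$segment, L))
      keep <- s < at - 1e-9
      cut <- interp_polyline(seg$points, at, seg$radii)
      seg$points <- rbind(seg$points[keep, , drop = FALSE], cut$points)
      seg$radii <- c(seg$radii[keep], cut$values)
      tree$segments[[sp$segment]] <- seg
      # drop children attached beyond the cut
      frac_cut <- at / L
      gone <- names(Filter(function(o)
        identical(o$parent, sp$segment) && o$parent_frac > frac_cut,
        tree$segments))
      for (g in gone) tree$segments[c(g, descendants(g))] <- NULL
      # re-express child attachment fractions on the shortened segment
      for (id in names(tree$segments)) {
        o <- tree$segments[[id]]
        if (identical(o$parent, sp$segment))
          tree$segments[[id]]$parent_frac <- min(o$parent_frac * L / at, 1)
      }
    } else abort(sprintf("unknown prune action '%s'", sp$action))
  }
  tree
}

#' Resample tree centerlines into uniform sections
#'
#' Divides every segment centerline into sections spaced `spacing` mm apart
#' (0.3 mm by default), the resolution at which circumferentially averaged
#' shear profiles and point-to-point model comparisons are computed.  A
#' segment of length L yields `floor(L/spacing) + 1` sections.
#'
#' @param tree A `vessel_tree`.
#' @param spacing Section spacing along the centerline (mm).
#' @return Tibble with `segment`, 0-based `section` index, `arclength` (mm),
#'   section centerpoint and unit tangent; spacing stored as an attribute.
#' @export
section_centerline <- function(tree, spacing = 0.3) {
  stopifnot(inherits(tree, "vessel_tree"), spacing > 0)
  rows <- lapply(tree$segments, function(s) {
    L <- max(arclengths(s$points))
    sv <- seq(0, floor(L / spacing) * spacing, by = spacing)
    pts <- interp_polyline(s$points, sv)
    tang <- interp_polyline(s$points, pmin(sv + spacing / 4, L)) -
      interp_polyline(s$points, pmax(sv - spacing / 4, 0))
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    tibble(segment = s$id, section = seq_along(sv) - 1L, arclength = sv,
           x = pts[, 1], y = pts[, 2], z = pts[, 3],
           tx = tang[, 1], ty = tang[, 2], tz = tang[, 3])
  })
  out <- bind_rows(rows)
  attr(out, "spacing") <- spacing
  out
}

#' Symmetric Hausdorff distance between two surface meshes
#'
#' Samples points uniformly by area on each surface (seed-deterministic) and
#' computes the exact distance from each sample to the nearest triangle of
#' the other mesh; the directed distance is the maximum over samples and the
#' symmetric distance the larger of the two directions.
#'
#' @param meshA,meshB `surface_mesh` objects.
#' @param symmetric Return `max(h(A->B), h(B->A))` (default) or just
#'   `h(A->B)`.
#' @param n_samples Surface samples per direction.
#' @param seed Sampling seed.
#' @return Distance in mm; directed components as attribute `"directed"`.
#' @export
hausdorff_distance <- function(meshA, meshB, symmetric = TRUE,
                               n_samples = 10000, seed = 1) {
  stopifnot(inherits(meshA, "surface_mesh"), inherits(meshB, "surface_mesh"))
  if (nrow(meshA$triangles) == 0 || nrow(meshB$triangles) == 0)
    abort("empty mesh")
  pa <- sample_mesh_points(meshA, n_samples, seed = seed)
  hab <- max(cpp_points_to_mesh(pa, meshB$vertices, meshB$triangles))
  if (!symmetric) {
    res <- hab
    attr(res, "directed") <- c(ab = hab)
    return(res)
  }
  pb <- sample_mesh_points(meshB, n_samples, seed = seed + 1)
  hba <- max(cpp_points_to_mesh(pb, meshA$vertices, meshA$triangles))
  res <- max(hab, hba)
  attr(res, "directed") <- c(ab = hab, ba = hba)
  res
}

#' Least-squares rigid landmark registration
#'
#' N-point registration: given at least three non-collinear corresponding
#' landmark pairs, finds the rotation and translation (no scaling)
#' minimizing the RMSD of `R A + t` to `B` (Kabsch algorithm).
#'
#' @param landmarksA,landmarksB Corresponding landmark matrices (n x 3).
#' @return A `rigid_transform` list with `rotation`, `translation`, `rmsd`.
#' @export
register_npoint <- function(landmarksA, landmarksB) {
  A <- as.matrix(landmarksA); B <- as.matrix(landmarksB)
  if (nrow(A) != nrow(B)) abort("landmark counts differ")
  if (nrow(A) < 3) abort("at least 3 landmark pairs are required")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    abort("landmarks are collinear; registration is degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - drop(R %*% ca)
  resid <- sweep(A %*% t(R), 2, t, `+`) - B
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(rowSums(resid^2)))),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  sweep(as.matrix(points) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> RMSD %.4g mm\n", x$rmsd))
  invisible(x)
}

#' Cartesian distances between corresponding landmarks
#'
#' The quantitative comparison used for phantom validation: the Euclidean
#' distance at each of a set of corresponding locations, with the mean and
#' range summarized.
#'
#' @param pointsA,pointsB Corresponding n x 3 matrices (mm).
#' @return Tibble of per-point distances; mean and range as attributes.
#' @export
landmark_cartesian_distance <- function(pointsA, pointsB) {
  A <- as.matrix(pointsA); B <- as.matrix(pointsB)
  if (nrow(A) != nrow(B)) abort("landmark counts differ")
  d <- sqrt(rowSums((A - B)^2))
  out <- tibble(location = seq_along(d), distance = d)
  attr(out, "mean") <- mean(d)
  attr(out, "range") <- range(d)
  out
}
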