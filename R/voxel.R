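#' Voxelize a lofted lumen mesh for the flow solver
#'
#' Classifies voxel centers on an isotropic grid against the implicit lumen
#' field carried by a mesh produced with [loft_mesh()]: interior centers
#' become fluid, the rest solid.  The fluid region is reduced to the single
#' 26-connected component containing the inlet (smaller components are
#' discarded with a warning), inlet and outlet voxel disks are identified
#' from the cap records, and wall-adjacent fluid voxels are annotated with
#' the wall distance, outward wall normal, owning segment, centerline
#' arclength and local lumen radius used for shear extraction.
#'
#' @param mesh A `surface_mesh` from [loft_mesh()].
#' @param h Voxel spacing (mm).
#' @return A `voxel_grid` object.
#' @export
voxelize <- function(mesh, h) {
  stopifnot(inherits(mesh, "surface_mesh"), h > 0)
  tree <- attr(mesh, "tree")
  if (is.null(tree))
    abort("voxelize() needs a mesh lofted from a vessel tree (implicit lumen field unavailable)")
  pieces <- tree_pieces(tree)
  min_d <- 2 * min(pieces$ra, pieces$rb)
  if (h > min_d / 2)
    abort(sprintf(
      "insufficient resolution: spacing %.3g mm exceeds half the minimum lumen diameter (%.3g mm)",
      h, min_d))
  rmax <- max(pieces$ra, pieces$rb)
  lo <- apply(rbind(pieces$A, pieces$B), 2, min) - rmax - 2 * h
  # offset the grid by an irrational fraction of the spacing so voxel
  # centers do not fall exactly on analytically placed surfaces
  lo <- lo - h / pi
  hi <- apply(rbind(pieces$A, pieces$B), 2, max) + rmax + 2 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  caps <- tree_caps(tree)
  fld <- cpp_voxel_field(dims, lo, h, pieces$A, pieces$B, pieces$ra,
                         pieces$rb, pieces$seg,
                         as.matrix(caps[, c("cx", "cy", "cz")]),
                         as.matrix(caps[, c("nx", "ny", "nz")]),
                         caps$radius)
  cls <- as.integer(fld$f < 0)
  # keep only the inlet-connected component
  inl <- caps[caps$role == "inlet", ]
  seed_p <- c(inl$cx, inl$cy, inl$cz) + 1.5 * h * c(inl$nx, inl$ny, inl$nz) * -1
  # inlet cap normal points outward; move inward to find a fluid seed
  seed_i <- pmin(pmax(round((seed_p - lo) / h), 0), dims - 1L)
  seed_idx <- seed_i[3] * dims[1] * dims[2] + seed_i[2] * dims[1] + seed_i[1]
  if (cls[seed_idx + 1] == 0) {
    cand <- which(cls == 1)
    if (length(cand) == 0) abort("no fluid voxels at this resolution")
    xyz <- arrayInd(cand, dims)
    pc <- sweep((xyz - 1) * h, 2, -lo)
    seed_idx <- cand[which.min(rowSums(sweep(pc, 2, c(inl$cx, inl$cy, inl$cz))^2))] - 1
  }
  lab <- cpp_flood_components(cls, dims, as.integer(seed_idx))
  n_extra <- sum(lab > 1)
  if (n_extra > 0) {
    warn(sprintf("discarding %d fluid voxels in %d disconnected component(s)",
                 n_extra, max(lab) - 1))
    cls[lab > 1] <- 0L
  }
  # inlet / outlet disks: fluid voxels within one spacing of the cap plane
  outlet_map <- caps[caps$role == "outlet", ]
  outlet_map$k <- seq_len(nrow(outlet_map))
  fluid_idx <- which(cls == 1L) - 1L
  xyz <- arrayInd(fluid_idx + 1L, dims)
  P <- sweep((xyz - 1) * h, 2, lo, `+`)
  mark_cap <- function(cap, code) {
    dvec <- sweep(P, 2, c(cap$cx, cap$cy, cap$cz))
    s <- dvec %*% c(cap$nx, cap$ny, cap$nz)
    radial2 <- rowSums(dvec^2) - drop(s)^2
    sel <- s > -1.05 * h & s <= 1e-9 & radial2 < (cap$radius + h)^2
    cls[fluid_idx[sel] + 1L] <<- code
    sum(sel)
  }
  n_in <- mark_cap(inl, 2L)
  if (n_in == 0) abort("no inlet voxels identified; resolution too coarse")
  for (k in seq_len(nrow(outlet_map))) {
    n_out <- mark_cap(outlet_map[k, ], 2L + k)
    if (n_out == 0)
      abort(sprintf("no outlet voxels for segment '%s'; resolution too coarse",
                    outlet_map$segment[k]))
  }
  # wall-adjacent annotation
  widx <- cpp_wall_adjacent(cls, dims)
  wxyz <- arrayInd(widx + 1L, dims)
  WP <- sweep((wxyz - 1) * h, 2, lo, `+`)
  near <- cpp_tree_nearest(WP, pieces$A, pieces$B, pieces$ra, pieces$rb)
  nvec <- WP - near$q
  nn <- sqrt(rowSums(nvec^2))
  nvec <- nvec / pmax(nn, 1e-12)
  d_wall <- pmax(near$radius - near$d_axis, 0.05 * h)
  seg_id <- pieces$ids[pieces$seg[near$piece + 1L]]
  arcl <- pieces$s0[near$piece + 1L] + near$t * pieces$len[near$piece + 1L]
  wall <- tibble(
    idx = widx, x = WP[, 1], y = WP[, 2], z = WP[, 3],
    nx = nvec[, 1], ny = nvec[, 2], nz = nvec[, 3],
    segment = seg_id, arclength = arcl, radius = near$radius,
    d_wall = d_wall,
    corr = pmin(near$radius / pmax(near$radius - d_wall, 0.25 * near$radius), 2)
  )
  structure(list(
    cls = cls, dims = dims, origin = lo, h = h, field = fld$f,
    inlet = list(segment = inl$segment, center = c(inl$cx, inl$cy, inl$cz),
                 normal = -c(inl$nx, inl$ny, inl$nz), radius = inl$radius),
    outlets = outlet_map, wall = wall, n_fluid = sum(cls > 0)
  ), tree = tree, class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d @ %.3g mm, %d fluid voxels, %d outlets\n",
    x$dims[1], x$dims[2], x$dims[3], x$h, x$n_fluid, nrow(x$outlets)))
  invisible(x)
}

#' Count of fluid voxels in a grid
#' @param grid A `voxel_grid`.
#' @export
fluid_voxel_count <- function(grid) sum(grid$cls > 0)
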