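#' Surface meshes of vessel lumens
#'
#' A `surface_mesh` holds `vertices` (n x 3, mm), `triangles` (m x 3 vertex
#' indices, outward-oriented), optional per-face segment `labels`, and a
#' `caps` table describing the flat inlet/outlet openings.  Meshes lofted
#' from a [vessel_tree] also carry the tree itself, giving downstream steps
#' (voxelization, wall normals) access to the implicit lumen field the
#' surface was extracted from.
#'
#' @name surface_mesh
NULL

new_surface_mesh <- function(vertices, triangles, labels = NULL,
                             caps = NULL, tree = NULL, h = NULL) {
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels, caps = caps, h = h),
            tree = tree, class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %d caps\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$caps)) 0L else nrow(x$caps)))
  invisible(x)
}

# caps of a tree: root inlet plus every outlet end (outward normals)
tree_caps <- function(tree) {
  inl <- tree_inlet(tree)
  outs <- tree_outlets(tree)
  bind_rows(
    tibble(segment = inl$segment, role = "inlet",
           cx = inl$center[1], cy = inl$center[2], cz = inl$center[3],
           nx = -inl$normal[1], ny = -inl$normal[2], nz = -inl$normal[3],
           radius = inl$radius),
    tibble(segment = outs$segment, role = "outlet",
           cx = outs$x, cy = outs$y, cz = outs$z,
           nx = outs$tx, ny = outs$ty, nz = outs$tz,
           radius = outs$diameter / 2)
  )
}

# approximate pairwise clearance check between non-adjoining segments
check_self_intersection <- function(tree, stride_mm = 2) {
  ids <- names(tree$segments)
  if (length(ids) < 2) return(invisible(TRUE))
  samp <- lapply(tree$segments, function(s) {
    L <- max(arclengths(s$points))
    ss <- seq(0, L, by = max(stride_mm, L / 200))
    ip <- interp_polyline(s$points, ss, s$radii)
    list(pts = ip$points, r = ip$values)
  })
  attach_point <- function(child) {
    par <- tree$segments[[child$parent]]
    L <- max(arclengths(par$points))
    drop(interp_polyline(par$points, child$parent_frac * L))
  }
  for (a in seq_along(ids)) for (b in seq_len(a - 1)) {
    sa <- tree$segments[[ids[a]]]; sb <- tree$segments[[ids[b]]]
    J <- NULL
    if (identical(sa$parent, sb$id)) J <- attach_point(sa)
    else if (identical(sb$parent, sa$id)) J <- attach_point(sb)
    else if (!is.na(sa$parent) && identical(sa$parent, sb$parent) &&
             abs(sa$parent_frac - sb$parent_frac) < 0.05)
      J <- attach_point(sa)
    pa <- samp[[ids[a]]]; pb <- samp[[ids[b]]]
    D <- outer(seq_len(nrow(pa$pts)), seq_len(nrow(pb$pts)),
               Vectorize(function(i, j) sqrt(sum((pa$pts[i, ] - pb$pts[j, ])^2))))
    clear <- D - outer(pa$r, pb$r, `+`)
    if (!is.null(J)) {
      excl <- 3 * (max(pa$r) + max(pb$r))
      da <- sqrt(rowSums(sweep(pa$pts, 2, J)^2))
      db <- sqrt(rowSums(sweep(pb$pts, 2, J)^2))
      clear[da < excl, ] <- Inf
      clear[, db < excl] <- Inf
    }
    if (any(clear < 0))
      abort(sprintf("tree is self-intersecting: segments '%s' and '%s' overlap away from their junction",
                    ids[a], ids[b]))
  }
  invisible(TRUE)
}

#' Loft a watertight lumen surface from a vessel tree
#'
#' Each segment is swept as a circular tube of locally varying radius along
#' its centerline; the implicit union of the tube distance fields blends
#' bifurcations smoothly, distal ends and the root inlet are cut flat and
#' normal to the local tangent, and the surface is extracted by marching
#' tetrahedra, which yields a closed, consistently oriented triangulation by
#' construction.
#'
#' @param tree A `vessel_tree`.
#' @param h Surface extraction grid spacing (mm); defaults to half the
#'   minimum lumen radius, floored at 0.1 mm.
#' @return A `surface_mesh` with per-face segment labels and cap records.
#' @export
loft_mesh <- function(tree, h = NULL) {
  stopifnot(inherits(tree, "vessel_tree"))
  check_self_intersection(tree)
  pieces <- tree_pieces(tree)
  h <- h %||% max(0.1, min(pieces$ra, pieces$rb) / 2)
  rmax <- max(pieces$ra, pieces$rb)
  lo <- apply(rbind(pieces$A, pieces$B), 2, min) - rmax - 3 * h
  hi <- apply(rbind(pieces$A, pieces$B), 2, max) + rmax + 3 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  caps <- tree_caps(tree)
  fld <- cpp_voxel_field(dims, lo, h, pieces$A, pieces$B, pieces$ra,
                         pieces$rb, pieces$seg,
                         as.matrix(caps[, c("cx", "cy", "cz")]),
                         as.matrix(caps[, c("nx", "ny", "nz")]),
                         caps$radius)
  mt <- cpp_march_tets(fld$f, dims, lo, h)
  if (nrow(mt$vertices) == 0) abort("empty surface; check tree and grid spacing")
  cent <- (mt$vertices[mt$triangles[, 1], ] + mt$vertices[mt$triangles[, 2], ] +
             mt$vertices[mt$triangles[, 3], ]) / 3
  near <- cpp_tree_nearest(cent, pieces$A, pieces$B, pieces$ra, pieces$rb)
  labels <- pieces$ids[pieces$seg[near$piece + 1L]]
  new_surface_mesh(mt$vertices, mt$triangles, labels = labels, caps = caps,
                   tree = tree, h = h)
}

# per-face area and normals
face_geometry <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  normal <- cr / pmax(2 * area, 1e-300)
  centroid <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  list(area = area, normal = normal, centroid = centroid)
}

# logical index of faces lying on a flat cap
cap_faces <- function(mesh, tol = NULL) {
  if (is.null(mesh$caps)) return(rep(FALSE, nrow(mesh$triangles)))
  fg <- face_geometry(mesh)
  tol <- tol %||% (0.8 * (mesh$h %||% 0.2))
  on_cap <- rep(FALSE, nrow(mesh$triangles))
  for (i in seq_len(nrow(mesh$caps))) {
    cp <- mesh$caps[i, ]
    nvec <- c(cp$nx, cp$ny, cp$nz)
    d <- sweep(fg$centroid, 2, c(cp$cx, cp$cy, cp$cz))
    plane_dist <- abs(d %*% nvec)
    radial <- sqrt(rowSums(d^2) - drop(plane_dist)^2)
    aligned <- abs(fg$normal %*% nvec) > 0.7
    on_cap <- on_cap | (drop(plane_dist) < tol & radial < 1.8 * cp$radius &
                          drop(aligned))
  }
  on_cap
}

#' Surface area of a mesh (mm^2)
#' @param mesh A `surface_mesh`.
#' @param include_caps Include the flat cap faces (default) or only the
#'   lateral vessel wall.
#' @export
mesh_area <- function(mesh, include_caps = TRUE) {
  fg <- face_geometry(mesh)
  if (include_caps) return(sum(fg$area))
  sum(fg$area[!cap_faces(mesh)])
}

#' Enclosed volume of a watertight mesh (mm^3)
#' @param mesh A `surface_mesh` with outward orientation.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], ]; b <- V[F[, 2], ]; c0 <- V[F[, 3], ]
  sum(a[, 1] * (b[, 2] * c0[, 3] - b[, 3] * c0[, 2]) -
      a[, 2] * (b[, 1] * c0[, 3] - b[, 3] * c0[, 1]) +
      a[, 3] * (b[, 1] * c0[, 2] - b[, 2] * c0[, 1])) / 6
}

#' Check mesh watertightness and orientation consistency
#'
#' Watertight means every undirected edge is shared by exactly two
#' triangles; consistent orientation means every directed edge appears
#' exactly once.
#'
#' @param mesh A `surface_mesh`.
#' @return `TRUE`/`FALSE`; details as attribute `"problems"` when `FALSE`.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$triangles
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key_dir <- paste(ed[, 1], ed[, 2])
  key_und <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  und_counts <- table(key_und)
  dir_dup <- any(duplicated(key_dir))
  ok <- all(und_counts == 2) && !dir_dup
  if (!ok) {
    res <- FALSE
    attr(res, "problems") <- list(
      bad_edges = sum(und_counts != 2), duplicated_directed = dir_dup)
    return(res)
  }
  TRUE
}

#' Write a mesh as binary STL
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @export
write_stl <- function(mesh, path) {
  fg <- face_geometry(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "coroflow surface mesh"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(mesh$triangles)), con, size = 4, endian = "little")
  V <- mesh$vertices; F <- mesh$triangles
  for (t in seq_len(nrow(F))) {
    writeBin(as.numeric(c(fg$normal[t, ], V[F[t, 1], ], V[F[t, 2], ],
                          V[F[t, 3], ])), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are deduplicated by exact coordinates.  The result carries no
#' implicit lumen field, so it can be measured ([mesh_area()],
#' [hausdorff_distance()]) but not voxelized.
#'
#' @param path STL file path.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- matrix(0, nt, 9)
  for (t in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    dat[t, ] <- vals[4:12]
  }
  pts <- rbind(dat[, 1:3], dat[, 4:6], dat[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- !duplicated(key)
  vid <- match(key, key[uid])
  V <- pts[uid, , drop = FALSE]
  F <- cbind(vid[seq_len(nt)], vid[nt + seq_len(nt)], vid[2 * nt + seq_len(nt)])
  new_surface_mesh(V, F)
}

#' Icosphere mesh
#'
#' Geodesic sphere used as an analytic fixture for mesh-distance checks.
#'
#' @param radius Sphere radius (mm).
#' @param center Sphere center.
#' @param subdiv Subdivision level (4 gives 5120 triangles).
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  # faces = vertex triples at minimal pairwise distance, oriented outward
  D <- as.matrix(dist(V))
  edge <- min(D[D > 1e-9])
  F <- matrix(0L, 0, 3)
  for (a in 1:10) for (b in (a + 1):11) for (c0 in (b + 1):12) {
    if (abs(D[a, b] - edge) < 1e-9 && abs(D[b, c0] - edge) < 1e-9 &&
        abs(D[a, c0] - edge) < 1e-9) {
      nrm <- pracma_cross(V[b, ] - V[a, ], V[c0, ] - V[a, ])
      cen <- (V[a, ] + V[b, ] + V[c0, ]) / 3
      F <- rbind(F, if (sum(nrm * cen) > 0) c(a, b, c0) else c(a, c0, b))
    }
  }
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- unitize((V[a, ] + V[b, ]) / 2)
      V <<- rbind(V, m)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(F))) {
      a <- F[t, 1]; b <- F[t, 2]; c0 <- F[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(c0, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  V <- sweep(V * radius, 2, center, `+`)
  new_surface_mesh(V, F)
}

# area-weighted random surface samples (seeded)
sample_mesh_points <- function(mesh, n, seed = 1) {
  fg <- face_geometry(mesh)
  with_seed(seed, {
    tri <- sample.int(nrow(mesh$triangles), n, replace = TRUE,
                      prob = fg$area)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    V <- mesh$vertices; F <- mesh$triangles
    V[F[tri, 1], ] * w1 + V[F[tri, 2], ] * w2 + V[F[tri, 3], ] * w3
  })
}
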