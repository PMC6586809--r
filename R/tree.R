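#' Synthetic coronary vessel trees
#'
#' A `vessel_tree` is a rooted tree of vessel segments.  Each segment carries
#' an ordered 3D centerline polyline (mm) with a per-point lumen radius (mm),
#' and attaches to its parent at a parametric arclength fraction.  The root
#' segment models the coronary ostium (left main or proximal RCA).  Trees are
#' the geometric ground truth for projection/reconstruction experiments and
#' the input to meshing, voxelization and flow simulation.
#'
#' @name vessel_tree
NULL

new_vessel_tree <- function(segments, root, stenoses = list()) {
  structure(
    list(segments = segments, root = root, units = "mm", stenoses = stenoses),
    class = "vessel_tree"
  )
}

new_segment <- function(id, points, radii, parent = NA_character_,
                        parent_frac = NA_real_) {
  stopifnot(nrow(points) >= 2, length(radii) == nrow(points))
  list(id = id, points = points, radii = radii, parent = parent,
       parent_frac = parent_frac)
}

#' Validate a vessel tree
#'
#' Checks the structural invariants: a single root, acyclic parenthood, all
#' radii positive, polylines with at least two distinct consecutive points,
#' and (unless the tree declares a stenosis there) non-increasing radii along
#' each segment within tolerance.
#'
#' @param tree A `vessel_tree`.
#' @param tol Tolerance (mm) for the taper monotonicity check.
#' @return Invisibly `TRUE`; aborts with a message describing the violation.
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "vessel_tree"))
  ids <- names(tree$segments)
  roots <- vapply(tree$segments, function(s) is.na(s$parent), logical(1))
  if (sum(roots) != 1L) abort("tree must have exactly one root segment")
  if (!is.na(tree$segments[[tree$root]]$parent))
    abort("declared root has a parent")
  for (s in tree$segments) {
    if (!is.na(s$parent) && !s$parent %in% ids)
      abort(sprintf("segment '%s' has unknown parent '%s'", s$id, s$parent))
    if (any(s$radii <= 0))
      abort(sprintf("segment '%s' has non-positive radii", s$id))
    dseg <- sqrt(rowSums(diff(s$points)^2))
    if (any(dseg < 1e-12))
      abort(sprintf("segment '%s' has repeated consecutive points", s$id))
    sten <- Filter(function(x) x$segment == s$id, tree$stenoses)
    if (length(sten) == 0 && any(diff(s$radii) > tol))
      abort(sprintf("segment '%s' radii increase outside a stenosis", s$id))
  }
  # acyclicity
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(tree$segments[[cur]]$parent)) {
      if (cur %in% seen) abort("segment parenthood contains a cycle")
      seen <- c(seen, cur)
      cur <- tree$segments[[cur]]$parent
    }
  }
  invisible(TRUE)
}

#' Specify a focal stenosis
#'
#' @param segment Segment id carrying the lesion.
#' @param center_frac Lesion center as a fraction of segment arclength.
#' @param length Lesion length (mm).
#' @param severity Fractional diameter reduction in (0, 1); 0.5 halves the
#'   local diameter.
#' @return A `stenosis_spec` list.
#' @export
stenosis_spec <- function(segment, center_frac, length, severity) {
  if (severity >= 1 || severity < 0)
    abort("stenosis severity must lie in [0, 1)")
  if (length <= 0) abort("stenosis length must be positive")
  structure(list(segment = segment, center_frac = center_frac,
                 length = length, severity = severity),
            class = "stenosis_spec")
}

# grow a smooth polyline: gentle deterministic curvature plus seeded noise
grow_polyline <- function(start, dir, length, ds = 0.5, curve = c(0, 0, 0),
                          wiggle = 0.02) {
  n <- max(2L, ceiling(length / ds) + 1L)
  pts <- matrix(0, n, 3)
  pts[1, ] <- start
  d <- unitize(dir)
  step <- length / (n - 1)
  for (i in 2:n) {
    d <- unitize(d + step * (curve + wiggle * rnorm(3)))
    pts[i, ] <- pts[i - 1, ] + step * d
  }
  pts
}

taper_radii <- function(n, r0, r1) r0 + (r1 - r0) * seq(0, 1, length.out = n)

#' Generate a synthetic coronary tree
#'
#' Builds a left (LM bifurcating into LAD and LCx, with diagonal and obtuse
#' marginal side branches) or right (RCA trunk with acute marginal branches)
#' coronary-like tree with linear radius tapering and smoothly curved
#' centerlines.  All generated side branches have an ostial diameter above
#' 1 mm, matching the inclusion rule for identifiable side branches; smaller
#' branches must be requested explicitly with `allow_small = TRUE`.
#'
#' @param template `"left"` or `"right"`.
#' @param params Named list of morphology parameters overriding the defaults
#'   (see Details).  Lengths/radii in mm.
#' @param seed Integer seed fixing all randomness.
#' @param allow_small Permit side-branch ostial diameters of 1 mm or less.
#'
#' @details Default morphology (left): LM 10 mm (radius 2.25 to 2.0 mm), LAD
#' 110 mm (1.85 to 0.6 mm), LCx 80 mm (1.7 to 0.75 mm), `n_diag = 2`
#' diagonals and `n_om = 2` obtuse marginals of 25-45 mm with ostial radii
#' around 1 mm.  Right: RCA 120 mm (1.95 to 0.75 mm) with `n_branch = 3` side
#' branches.  Branch take-off angles are drawn uniformly inside
#' `branch_cone = c(35, 65)` degrees.  `stenoses` may carry a list of
#' [stenosis_spec()] applied after generation.  `ds` sets the centerline
#' sampling step (default 0.5 mm).
#'
#' @return A valid `vessel_tree`.
#' @examples
#' tr <- generate_tree("left", list(n_diag = 1, n_om = 1), seed = 1)
#' length(tr$segments)
#' @export
generate_tree <- function(template = c("left", "right"), params = list(),
                          seed = 1, allow_small = FALSE) {
  template <- match.arg(template)
  defaults <- if (template == "left") {
    list(
      lm = list(length = 10, r0 = 2.25, r1 = 2.0),
      lad = list(length = 110, r0 = 1.85, r1 = 0.6),
      lcx = list(length = 80, r0 = 1.7, r1 = 0.75),
      n_diag = 2, n_om = 2,
      branch_length = c(25, 45), branch_r0 = c(0.8, 1.1),
      branch_taper = 0.55, branch_cone = c(35, 65),
      diag_span = c(0.22, 0.70), om_span = c(0.25, 0.70),
      branch_max_frac = 0.9,
      ds = 0.5, wiggle = 0.02, stenoses = list()
    )
  } else {
    list(
      rca = list(length = 120, r0 = 1.95, r1 = 0.75),
      n_branch = 3,
      branch_length = c(20, 40), branch_r0 = c(0.8, 1.1),
      branch_taper = 0.55, branch_cone = c(35, 65),
      branch_span = c(0.20, 0.75),
      branch_max_frac = 0.9,
      ds = 0.5, wiggle = 0.02, stenoses = list()
    )
  }
  p <- utils::modifyList(defaults, params)
  if (any(unlist(p$branch_r0) <= 0.5) && !allow_small)
    abort(paste0(
      "requested side-branch ostial diameter is 1 mm or below; only side ",
      "branches wider than 1 mm are modelled (use allow_small = TRUE to override)"))

  tree <- with_seed(seed, {
    segs <- list()
    # clearance of a candidate polyline against the existing segments,
    # ignoring the neighbourhood of its own attachment point
    branch_clear <- function(pts, radii, attach_pt, parent_id) {
      for (other in segs) {
        keep_o <- seq(1, nrow(other$points),
                      by = max(1L, nrow(other$points) %/% 60))
        po <- other$points[keep_o, , drop = FALSE]
        ro <- other$radii[keep_o]
        keep_b <- seq(1, nrow(pts), by = max(1L, nrow(pts) %/% 40))
        pb <- pts[keep_b, , drop = FALSE]
        rb <- radii[keep_b]
        D <- matrix(0, nrow(pb), nrow(po))
        for (ii in seq_len(nrow(pb)))
          D[ii, ] <- sqrt(colSums((t(po) - pb[ii, ])^2))
        clear <- D - outer(rb, ro, `+`)
        # junction blending is legitimate: ignore the neighbourhood of the
        # attachment, but only against the parent or a segment sharing it
        shares_junction <- identical(other$id, parent_id) ||
          vnorm(other$points[1, ] - attach_pt) < 1.5 * (radii[1] + ro[1])
        if (shares_junction) {
          excl <- 3 * (max(rb) + max(ro))
          do <- sqrt(rowSums(sweep(po, 2, attach_pt)^2))
          db <- sqrt(rowSums(sweep(pb, 2, attach_pt)^2))
          clear[db < excl, ] <- Inf
          clear[, do < excl] <- Inf
        }
        if (any(clear < 0.1)) return(FALSE)  # 0.1 mm safety margin
      }
      TRUE
    }
    add_branch <- function(parent_seg, frac, id, len, r0, r1, cone, wiggle, ds) {
      s <- arclengths(parent_seg$points)
      # take-off: rotate the parent tangent by an angle inside the cone at a
      # random azimuth; redraw (and later nudge the attachment distally)
      # until the branch clears the existing tree
      frac_try <- frac
      # sibling ostia on the same parent must stay well separated
      sib_frac <- vapply(Filter(function(o)
        identical(o$parent, parent_seg$id), segs),
        function(o) o$parent_frac, 1)
      sib_sep <- function(fr) {
        length(sib_frac) == 0 ||
          min(abs(fr - sib_frac)) * max(s) > 2.5 * (r0 + max(radii_hint))
      }
      radii_hint <- r0
      for (try in 1:60) {
        if (try > 10)
          frac_try <- min(frac + (try - 10) * 0.01 + runif(1, 0, 0.01), 0.95)
        if (!sib_sep(frac_try)) next
        at <- interp_polyline(parent_seg$points, frac_try * max(s),
                              parent_seg$radii)
        i2 <- min(which(s >= frac_try * max(s))[1] + 1,
                  nrow(parent_seg$points))
        i1 <- max(i2 - 2, 1)
        tang <- unitize(parent_seg$points[i2, ] - parent_seg$points[i1, ])
        r0c <- min(r0, p$branch_max_frac * at$values)  # ostial clamp
        ang <- runif(1, cone[1], cone[2])
        az <- runif(1, 0, 360)
        perp <- unitize(pracma_cross(tang, if (abs(tang[3]) < 0.9)
          c(0, 0, 1) else c(1, 0, 0)))
        axis <- rot_about(perp, tang, az)
        d0 <- rot_about(tang, axis, ang)
        pts <- grow_polyline(drop(at$points), d0, len, ds = ds,
                             wiggle = wiggle)
        radii <- taper_radii(nrow(pts), r0c, r1 * r0c)
        if (branch_clear(pts, radii, drop(at$points), parent_seg$id)) break
        if (try == 60)
          abort(sprintf("could not place side branch '%s' without overlap", id))
      }
      new_segment(id, pts, radii, parent = parent_seg$id,
                  parent_frac = frac_try)
    }
    if (template == "left") {
      lm <- new_segment("LM",
        grow_polyline(c(0, 0, 0), c(1, -0.15, -0.1), p$lm$length,
                      ds = p$ds, wiggle = p$wiggle / 2),
        taper_radii(ceiling(p$lm$length / p$ds) + 1, p$lm$r0, p$lm$r1))
      segs[["LM"]] <- lm
      end <- lm$points[nrow(lm$points), ]
      tang <- unitize(lm$points[nrow(lm$points), ] -
                        lm$points[nrow(lm$points) - 1, ])
      lad_dir <- unitize(rot_about(tang, c(0, 0, 1), 30) + c(0, -0.45, -0.35))
      lcx_dir <- unitize(rot_about(tang, c(0, 0, 1), -45) + c(0, 0.5, -0.3))
      lad <- new_segment("LAD",
        grow_polyline(end, lad_dir, p$lad$length, ds = p$ds,
                      curve = c(-0.004, -0.003, -0.003), wiggle = p$wiggle),
        taper_radii(ceiling(p$lad$length / p$ds) + 1, p$lad$r0, p$lad$r1),
        parent = "LM", parent_frac = 1.0)
      segs[["LAD"]] <- lad
      for (try in 1:30) {
        # widen the bifurcation angle on persistent clashes
        dir_try <- if (try <= 10) lcx_dir
                   else unitize(rot_about(lcx_dir, c(0, 0, 1), -(try - 10)))
        lcx <- new_segment("LCx",
          grow_polyline(end, dir_try, p$lcx$length, ds = p$ds,
                        curve = c(-0.004, 0.004, -0.002), wiggle = p$wiggle),
          taper_radii(ceiling(p$lcx$length / p$ds) + 1, p$lcx$r0, p$lcx$r1),
          parent = "LM", parent_frac = 1.0)
        if (branch_clear(lcx$points, lcx$radii, end, "LM")) break
        if (try == 30) abort("could not separate LCx from LAD")
      }
      segs[["LCx"]] <- lcx
      if (p$n_diag > 0) {
        fr <- seq(p$diag_span[1], p$diag_span[2], length.out = max(p$n_diag, 2))
        fr <- fr[seq_len(p$n_diag)] + runif(p$n_diag, -0.02, 0.02)
        for (i in seq_len(p$n_diag)) {
          r0 <- runif(1, p$branch_r0[1], p$branch_r0[2])
          segs[[paste0("Diag", i)]] <- add_branch(
            lad, fr[i], paste0("Diag", i),
            runif(1, p$branch_length[1], p$branch_length[2]),
            r0, p$branch_taper, p$branch_cone, p$wiggle, p$ds)
        }
      }
      if (p$n_om > 0) {
        fr <- seq(p$om_span[1], p$om_span[2], length.out = max(p$n_om, 2))
        fr <- fr[seq_len(p$n_om)] + runif(p$n_om, -0.02, 0.02)
        for (i in seq_len(p$n_om)) {
          r0 <- runif(1, p$branch_r0[1], p$branch_r0[2])
          segs[[paste0("OM", i)]] <- add_branch(
            lcx, fr[i], paste0("OM", i),
            runif(1, p$branch_length[1], p$branch_length[2]),
            r0, p$branch_taper, p$branch_cone, p$wiggle, p$ds)
        }
      }
      new_vessel_tree(segs, "LM")
    } else {
      rca <- new_segment("RCA",
        grow_polyline(c(0, 0, 0), c(-1, -0.2, -0.15), p$rca$length,
                      ds = p$ds, curve = c(0.003, -0.002, -0.004),
                      wiggle = p$wiggle),
        taper_radii(ceiling(p$rca$length / p$ds) + 1, p$rca$r0, p$rca$r1))
      segs[["RCA"]] <- rca
      if (p$n_branch > 0) {
        fr <- seq(p$branch_span[1], p$branch_span[2],
                  length.out = max(p$n_branch, 2))
        fr <- fr[seq_len(p$n_branch)] + runif(p$n_branch, -0.02, 0.02)
        for (i in seq_len(p$n_branch)) {
          r0 <- runif(1, p$branch_r0[1], p$branch_r0[2])
          segs[[paste0("AM", i)]] <- add_branch(
            rca, fr[i], paste0("AM", i),
            runif(1, p$branch_length[1], p$branch_length[2]),
            r0, p$branch_taper, p$branch_cone, p$wiggle, p$ds)
        }
      }
      new_vessel_tree(segs, "RCA")
    }
  })
  # center the anatomy on the world origin (the C-arm isocenter)
  allp <- do.call(rbind, lapply(tree$segments, function(s) s$points))
  ctr <- (apply(allp, 2, min) + apply(allp, 2, max)) / 2
  for (id in names(tree$segments))
    tree$segments[[id]]$points <-
      sweep(tree$segments[[id]]$points, 2, ctr)
  for (st in p$stenoses) tree <- apply_stenosis(tree, st)
  validate_tree(tree)
  tree
}

#' Apply a focal stenosis to a tree
#'
#' Multiplies the segment radii by a smooth cosine-bell reduction profile
#' that reaches `1 - severity` at the lesion center and returns to 1 at the
#' lesion edges (C1-continuous).  The centerline is refined so that the
#' lesion center, edges and quarter points fall exactly on sample points.
#'
#' @param tree A `vessel_tree`.
#' @param spec A [stenosis_spec()].
#' @return The modified tree; the stenosis is recorded on the tree so that
#'   taper validation tolerates the recovery zone.
#' @export
apply_stenosis <- function(tree, spec) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(spec, "stenosis_spec"))
  seg <- tree$segments[[spec$segment]]
  if (is.null(seg)) abort(sprintf("no segment '%s' in tree", spec$segment))
  s <- arclengths(seg$points)
  L <- max(s)
  c0 <- spec$center_frac * L
  if (c0 - spec$length / 2 < -1e-9 || c0 + spec$length / 2 > L + 1e-9)
    abort("stenotic region extends beyond the segment")
  for (st in tree$stenoses) {
    if (st$segment == spec$segment) {
      lo1 <- st$center_frac * L - st$length / 2
      hi1 <- st$center_frac * L + st$length / 2
      if (c0 - spec$length / 2 < hi1 && c0 + spec$length / 2 > lo1)
        abort("overlapping stenoses on the same segment region")
    }
  }
  if (spec$severity == 0) {
    tree$stenoses <- c(tree$stenoses, list(spec))
    return(tree)
  }
  extra <- c0 + spec$length * c(-0.5, -0.25, 0, 0.25, 0.5)
  extra <- extra[extra > 0 & extra < L]
  s_new <- sort(c(s, extra))
  s_new <- s_new[c(TRUE, diff(s_new) > 1e-6)]  # drop near-duplicates
  res <- interp_polyline(seg$points, s_new, seg$radii)
  prof <- rep(1, length(s_new))
  inside <- abs(s_new - c0) <= spec$length / 2
  prof[inside] <- 1 - spec$severity * 0.5 *
    (1 + cos(2 * pi * (s_new[inside] - c0) / spec$length))
  seg$points <- res$points
  seg$radii <- res$values * prof
  tree$segments[[spec$segment]] <- seg
  tree$stenoses <- c(tree$stenoses, list(spec))
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, root %s, total length %.1f mm\n",
              length(x$segments), x$root, tree_total_length(x)))
  for (s in x$segments) {
    cat(sprintf("  %-6s L=%6.1f mm  d=%.2f->%.2f mm  %s\n", s$id,
                max(arclengths(s$points)), 2 * s$radii[1],
                2 * s$radii[length(s$radii)],
                if (is.na(s$parent)) "(root)"
                else sprintf("on %s @ %.2f", s$parent, s$parent_frac)))
  }
  invisible(x)
}

#' Total centerline length of a tree (mm)
#' @param tree A `vessel_tree`.
#' @export
tree_total_length <- function(tree) {
  sum(vapply(tree$segments, function(s) max(arclengths(s$points)), 1))
}

#' Outlet (leaf-end) table of a tree
#'
#' An outlet is the distal end of any segment with no child attached at its
#' very end (in the templates used here, every segment except the left main).
#'
#' @param tree A `vessel_tree`.
#' @return Tibble with segment id, outlet center, outward tangent and
#'   diameter (mm).
#' @export
tree_outlets <- function(tree) {
  has_distal_child <- vapply(tree$segments, function(s) {
    any(vapply(tree$segments, function(o)
      identical(o$parent, s$id) && o$parent_frac > 0.98, logical(1)))
  }, logical(1))
  rows <- lapply(tree$segments[!has_distal_child], function(s) {
    n <- nrow(s$points)
    tangent <- unitize(s$points[n, ] - s$points[n - 1, ])
    tibble(segment = s$id, x = s$points[n, 1], y = s$points[n, 2],
           z = s$points[n, 3], tx = tangent[1], ty = tangent[2],
           tz = tangent[3], diameter = 2 * s$radii[n])
  })
  bind_rows(rows)
}

# root inlet cap: start point, inward tangent, radius
tree_inlet <- function(tree) {
  s <- tree$segments[[tree$root]]
  tangent <- unitize(s$points[2, ] - s$points[1, ])
  list(segment = s$id, center = s$points[1, ], normal = tangent,
       radius = s$radii[1])
}

# flatten the tree into centerline pieces for the C++ field kernels:
# matrices A, B (piece endpoints), radii ra, rb, integer segment index,
# per-piece start arclength, and the segment id lookup
tree_pieces <- function(tree) {
  ids <- names(tree$segments)
  A <- NULL; B <- NULL; ra <- c(); rb <- c(); seg <- c(); s0 <- c(); len <- c()
  for (i in seq_along(ids)) {
    sg <- tree$segments[[ids[i]]]
    n <- nrow(sg$points)
    s <- arclengths(sg$points)
    A <- rbind(A, sg$points[-n, , drop = FALSE])
    B <- rbind(B, sg$points[-1, , drop = FALSE])
    ra <- c(ra, sg$radii[-n])
    rb <- c(rb, sg$radii[-1])
    seg <- c(seg, rep(i, n - 1))
    s0 <- c(s0, s[-n])
    len <- c(len, diff(s))
  }
  list(A = A, B = B, ra = ra, rb = rb, seg = seg, s0 = s0, len = len,
       ids = ids)
}

#' Serialize a vessel tree to JSON
#'
#' The schema is a list of segments, each with `id`, `points` (n x 3, mm),
#' `radii` (mm), `parent` (or null) and `parent_frac`, plus the root id and
#' any recorded stenoses.
#'
#' @param tree A `vessel_tree`.
#' @param path Output path; with `path = NULL` the JSON string is returned.
#' @export
write_tree <- function(tree, path = NULL) {
  obj <- list(
    root = tree$root, units = tree$units,
    segments = lapply(unname(tree$segments), function(s) list(
      id = s$id, points = unname(s$points), radii = s$radii,
      parent = if (is.na(s$parent)) NULL else s$parent,
      parent_frac = if (is.na(s$parent_frac)) NULL else s$parent_frac)),
    stenoses = lapply(tree$stenoses, unclass)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a vessel tree from JSON
#' @param path Path or JSON string produced by [write_tree()].
#' @export
read_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  scalar_or <- function(x, default)
    if (is.null(x) || length(x) == 0) default else x
  segs <- list()
  for (s in obj$segments) {
    pts <- s$points
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    segs[[s$id]] <- new_segment(
      s$id, pts, as.numeric(s$radii),
      parent = scalar_or(s$parent, NA_character_),
      parent_frac = scalar_or(s$parent_frac, NA_real_))
  }
  stenoses <- lapply(obj$stenoses, function(st)
    stenosis_spec(st$segment, st$center_frac, st$length, st$severity))
  tr <- new_vessel_tree(segs, obj$root, stenoses)
  validate_tree(tr)
  tr
}
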