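test_that("tree generation is deterministic and respects requested topology", {
  params <- desk_left_params(n_diag = 3, n_om = 2)
  tr1 <- generate_tree("left", params, seed = 7)
  tr2 <- generate_tree("left", params, seed = 7)
  expect_identical(tr1, tr2)
  # LM + LAD + LCx + 3 diagonals + 2 marginals
  expect_length(tr1$segments, 8)
  expect_equal(nrow(tree_outlets(tr1)), 7)
  tr3 <- generate_tree("left", params, seed = 8)
  expect_false(identical(tr1, tr3))
})

test_that("generated trees satisfy the structural invariants across seeds", {
  for (s in 1:100) {
    tr <- generate_tree(if (s %% 2) "left" else "right", seed = s)
    expect_silent(validate_tree(tr))
    outs <- tree_outlets(tr)
    # every generated side branch has an ostial diameter above 1 mm
    for (seg in tr$segments) {
      if (!is.na(seg$parent)) expect_gt(2 * seg$radii[1], 1)
    }
  }
})

test_that("sub-millimetre side branches are rejected unless overridden", {
  expect_error(
    generate_tree("left", list(branch_r0 = c(0.3, 0.45)), seed = 1),
    "1 mm")
  expect_silent(
    generate_tree("left", list(n_diag = 1, n_om = 0,
                               branch_r0 = c(0.45, 0.5)),
                  seed = 1, allow_small = TRUE))
})

test_that("stenosis follows the cosine-bell law exactly at its landmarks", {
  tr <- generate_tree("left", desk_left_params(), seed = 2)
  ref <- tr$segments$LAD
  s_ref <- coroflow:::arclengths(ref$points)
  spec <- stenosis_spec("LAD", 0.5, 8, 0.5)
  tr2 <- apply_stenosis(tr, spec)
  seg <- tr2$segments$LAD
  s <- coroflow:::arclengths(seg$points)
  L <- max(s_ref)
  # reference (unstenosed) radius from the generator's own taper law,
  # evaluated independently by interpolation of the original profile
  r_ref <- approx(s_ref, ref$radii, xout = s, rule = 2)$y
  prof <- rep(1, length(s))
  inside <- abs(s - 0.5 * L) <= 4
  prof[inside] <- 1 - 0.5 * 0.5 * (1 + cos(2 * pi * (s[inside] - 0.5 * L) / 8))
  expect_equal(seg$radii, r_ref * prof, tolerance = 1e-10)
  # center diameter exactly halved; area reduction 1 - 0.5^2 = 75%
  i0 <- which.min(abs(s - 0.5 * L))
  expect_equal(s[i0], 0.5 * L)
  expect_equal(seg$radii[i0], 0.5 * r_ref[i0])
  expect_equal(1 - (seg$radii[i0] / r_ref[i0])^2, 0.75)
  # minimum diameter over the segment is the center one
  expect_equal(min(seg$radii / r_ref), 0.5)
})

test_that("zero-severity stenosis leaves the tree unchanged and overlaps error", {
  tr <- generate_tree("left", desk_left_params(), seed = 2)
  tr0 <- apply_stenosis(tr, stenosis_spec("LAD", 0.5, 8, 0))
  expect_equal(tr0$segments, tr$segments)
  tr1 <- apply_stenosis(tr, stenosis_spec("LAD", 0.5, 8, 0.4))
  expect_error(apply_stenosis(tr1, stenosis_spec("LAD", 0.55, 8, 0.3)),
               "overlap")
  expect_error(stenosis_spec("LAD", 0.5, 8, 1.0), "severity")
})

test_that("projection matches an independent homogeneous-matrix oracle", {
  g <- gantry_geometry()
  tr <- generate_tree("left", desk_left_params(), seed = 3)
  projs <- project_tree(tr, g)
  for (k in 1:2) {
    for (id in names(tr$segments)) {
      expect_equal(projs[[k]]$segments[[id]]$uv,
                   oracle_project(tr$segments[[id]]$points, g, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("projection geometry identities hold", {
  g <- gantry_geometry(view1 = list(alpha = -30, beta = 0, sod = 750,
                                    sid = 1000, pixel = 0.2),
                       view2 = list(alpha = 40, beta = 20))
  cam <- coroflow:::gantry_camera(g, 1)
  # isocenter projects to the principal point in both views
  for (k in 1:2) {
    pr <- coroflow:::project_points(matrix(0, 1, 3),
                                    coroflow:::gantry_camera(g, k))
    expect_equal(drop(pr$uv), coroflow:::gantry_camera(g, k)$center,
                 tolerance = 1e-9)
  }
  # 10 mm offset perpendicular to the axis at the isocenter:
  # displacement = 10 * (SID/SOD) / pixel = 66.67 px
  P <- matrix(10 * cam$xv, 1, 3)
  pr <- coroflow:::project_points(P, cam)
  expect_equal(drop(pr$uv)[1] - cam$center[1], 10 * (1000 / 750) / 0.2,
               tolerance = 1e-9)
  # magnification at the isocenter is SID/SOD >= 1
  expect_equal(pr$mag, 1000 / 750)
  expect_gte(pr$mag, 1)
  # shallow separation is rejected with the constraint in the message
  expect_error(gantry_geometry(view1 = list(alpha = 0),
                               view2 = list(alpha = 30)),
               "> 45")
})

test_that("projection is scale-consistent in pixel size", {
  tr <- generate_tree("left", desk_left_params(), seed = 4)
  g1 <- gantry_geometry(view1 = list(alpha = -30, pixel = 0.2),
                        view2 = list(alpha = 40, pixel = 0.2))
  g2 <- gantry_geometry(view1 = list(alpha = -30, pixel = 0.4),
                        view2 = list(alpha = 40, pixel = 0.4))
  p1 <- project_tree(tr, g1)[[1]]
  p2 <- project_tree(tr, g2)[[1]]
  c1 <- sweep(p1$segments$LAD$uv, 2, p1$detector / 2)
  c2 <- sweep(p2$segments$LAD$uv, 2, p2$detector / 2)
  expect_equal(c1 / 2, c2, tolerance = 1e-9)
  expect_equal(p1$segments$LAD$width / 2, p2$segments$LAD$width,
               tolerance = 1e-9)
})

test_that("projection degradation is seeded and calibrated", {
  tr <- generate_tree("left", desk_left_params(), seed = 5)
  g <- gantry_geometry()
  pr <- project_tree(tr, g)[[1]]
  expect_identical(degrade_projection(pr, 0, 0, seed = 1), pr)
  d1 <- degrade_projection(pr, 1, 0.5, seed = 3)
  d2 <- degrade_projection(pr, 1, 0.5, seed = 3)
  expect_identical(d1, d2)
  # empirical displacement sd within 10% of nominal over all points
  dev <- unlist(lapply(names(pr$segments), function(id)
    d1$segments[[id]]$uv - pr$segments[[id]]$uv))
  expect_gt(length(dev), 300)
  expect_lt(abs(sd(dev) - 1), 0.1)
  expect_error(degrade_projection(pr, -1, 0), ">= 0")
})

test_that("trees and projections round-trip through JSON", {
  tr <- apply_stenosis(generate_tree("left", desk_left_params(), seed = 6),
                       stenosis_spec("LAD", 0.4, 6, 0.3))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_equal(tr2$root, tr$root)
  for (id in names(tr$segments)) {
    expect_equal(tr2$segments[[id]]$points, tr$segments[[id]]$points)
    expect_equal(tr2$segments[[id]]$radii, tr$segments[[id]]$radii)
  }
  pr <- project_tree(tr, gantry_geometry())[[1]]
  p_path <- withr::local_tempfile(fileext = ".json")
  write_projection(pr, p_path)
  pr2 <- read_projection(p_path)
  expect_equal(pr2$segments$LAD$uv, pr$segments$LAD$uv)
  expect_equal(pr2$segments$LAD$width, pr$segments$LAD$width)
})
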