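test_that("lofted tube matches cylinder area and volume and is watertight", {
  tr <- tube_tree(length = 20, radius = 1.5)
  m <- loft_mesh(tr, h = 0.1)
  expect_true(isTRUE(is_watertight(m)))
  expect_equal(mesh_area(m, include_caps = FALSE), 2 * pi * 1.5 * 20,
               tolerance = 0.02)
  expect_equal(mesh_volume(m), pi * 1.5^2 * 20, tolerance = 0.02)
})

test_that("a one-branch tree has exactly three capped openings", {
  tr <- bifurcation_tree()
  # bifurcation_tree has two branches; build a single-branch variant
  tr$segments$C <- NULL
  tr$segments$B$parent_frac <- 0.6
  # re-anchor branch start onto the parent at 60% arclength
  s <- coroflow:::arclengths(tr$segments$A$points)
  at <- coroflow:::interp_polyline(tr$segments$A$points, 0.6 * max(s))
  shift <- drop(at) - tr$segments$B$points[1, ]
  tr$segments$B$points <- sweep(tr$segments$B$points, 2, -shift)
  m <- loft_mesh(tr, h = 0.12)
  expect_true(isTRUE(is_watertight(m)))
  expect_equal(nrow(m$caps), 3)  # 1 inlet + 2 outlets
  cap_idx <- coroflow:::cap_faces(m)
  expect_gt(sum(cap_idx), 0)
})

test_that("self-intersecting trees are rejected with the offending pair", {
  tr <- tube_tree(length = 20, radius = 1.5)
  pts2 <- cbind(seq(20, 0, by = -0.5), 1.0, 0)  # runs back along the tube
  tr$segments$X <- coroflow:::new_segment("X", pts2, rep(1.5, nrow(pts2)),
                                          parent = "T", parent_frac = 1)
  expect_error(loft_mesh(tr), "self-intersecting")
})

test_that("voxelization matches the analytic cylinder volume", {
  tr <- tube_tree(length = 20, radius = 1.5)
  m <- loft_mesh(tr, h = 0.1)
  g <- voxelize(m, 0.15)
  expect_equal(fluid_voxel_count(g), pi * 1.5^2 * 20 / 0.15^3,
               tolerance = 0.05)
  # insufficient resolution is refused
  expect_error(voxelize(m, 2), "insufficient resolution")
  # the fluid forms a single connected component by construction
  lab <- coroflow:::cpp_flood_components(
    as.integer(g$cls > 0), g$dims,
    as.integer(which(g$cls > 0)[1] - 1))
  expect_equal(max(lab), 1L)
})

test_that("pruning identities: empty spec, idempotence, commutation", {
  tr <- generate_tree("left", desk_left_params(n_diag = 2, n_om = 1),
                      seed = 9)
  expect_identical(prune_tree(tr, list()), tr)
  s1 <- list(list(segment = "Diag1", action = "remove"))
  s2 <- list(list(segment = "OM1", action = "remove"))
  once <- prune_tree(tr, s1)
  expect_warning(twice <- prune_tree(once, s1), "skipped")
  expect_identical(twice, once)
  expect_identical(prune_tree(tr, c(s1, s2)),
                   prune_tree(prune_tree(tr, s2), s1))
  expect_error(prune_tree(tr, list(list(segment = "LM", action = "remove"))),
               "root")
  # remaining geometry is bitwise unchanged
  pr <- prune_tree(tr, s1)
  for (id in names(pr$segments))
    expect_identical(pr$segments[[id]]$points, tr$segments[[id]]$points)
})

test_that("pruned lumen volume equals full minus branch frusta", {
  tr <- generate_tree("left", desk_left_params(n_diag = 1, n_om = 1),
                      seed = 10)
  full <- mesh_volume(loft_mesh(tr, h = 0.1))
  pruned_tree <- prune_tree(tr, list(
    list(segment = "Diag1", action = "remove"),
    list(segment = "OM1", action = "remove")))
  pruned <- mesh_volume(loft_mesh(pruned_tree, h = 0.1))
  # frustum oracle: branch volume outside the parent lumen, with the
  # exit transition resolved by brute-force sampling
  removed <- 0
  for (id in c("Diag1", "OM1")) {
    seg <- tr$segments[[id]]
    par <- tr$segments[[seg$parent]]
    removed <- removed + branch_volume_outside_parent(seg, par)
  }
  expect_equal(full - pruned, removed, tolerance = 0.02)
})

test_that("truncation cuts at the requested arclength and recaps", {
  tr <- generate_tree("left", desk_left_params(n_diag = 1, n_om = 0),
                      seed = 11)
  cut <- prune_tree(tr, list(list(segment = "LAD", action = "truncate",
                                  at_mm = 20)))
  expect_equal(max(coroflow:::arclengths(cut$segments$LAD$points)), 20,
               tolerance = 1e-9)
  expect_error(prune_tree(tr, list(list(segment = "LAD",
                                        action = "truncate", at_mm = 500))),
               "outside")
})

test_that("centerline sectioning has the exact count and uniform spacing", {
  tr <- tube_tree(length = 30, radius = 1.5)
  secs <- section_centerline(tr, spacing = 0.3)
  expect_equal(nrow(secs), floor(30 / 0.3) + 1)  # 101 sections
  d <- sqrt(diff(secs$x)^2 + diff(secs$y)^2 + diff(secs$z)^2)
  expect_true(all(abs(d - 0.3) < 0.003))
  # a ~600 mm tree yields approximately 2000 sections
  big <- generate_tree("left", list(
    lad = list(length = 200, r0 = 1.85, r1 = 0.6),
    lcx = list(length = 150, r0 = 1.7, r1 = 0.75),
    n_diag = 3, n_om = 3, branch_length = c(55, 75)), seed = 13)
  n_sec <- nrow(section_centerline(big))
  expect_equal(n_sec, tree_total_length(big) / 0.3, tolerance = 0.01)
  expect_gt(n_sec, 1800)
})

test_that("Hausdorff distance satisfies its analytic oracles", {
  s1 <- icosphere(1, c(0, 0, 0), subdiv = 3)
  s2 <- icosphere(1, c(3, 0, 0), subdiv = 3)
  expect_lt(hausdorff_distance(s1, s1, n_samples = 2000), 1e-9)
  hd <- hausdorff_distance(s1, s2, n_samples = 5000)
  expect_equal(as.numeric(hd), 3, tolerance = 0.01)
  hd_ba <- hausdorff_distance(s2, s1, n_samples = 5000)
  expect_equal(as.numeric(hd), as.numeric(hd_ba), tolerance = 0.01)
})

test_that("N-point registration recovers an applied rigid transform", {
  set.seed(42)
  A <- matrix(rnorm(30), 10, 3)
  R <- coroflow:::rot_z(30)
  t <- c(1, 2, 3)
  B <- sweep(A %*% t(R), 2, t, `+`)
  tf <- register_npoint(A, B)
  expect_equal(tf$rotation, R, tolerance = 1e-6)
  expect_equal(tf$translation, t, tolerance = 1e-6)
  expect_lt(tf$rmsd, 1e-9)
  # identity case
  tf0 <- register_npoint(A, A)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(tf0$rmsd, 1e-12)
  # noisy correspondences: reported RMSD equals the direct residual
  Bn <- B + matrix(rnorm(30, sd = 0.1), 10, 3)
  tfn <- register_npoint(A, Bn)
  resid <- apply_transform(tfn, A) - Bn
  expect_equal(tfn$rmsd, sqrt(mean(rowSums(resid^2))), tolerance = 1e-12)
  # degenerate input
  expect_error(register_npoint(A[1:2, ], B[1:2, ]), "3 landmark")
  col <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(register_npoint(col, col + 1), "collinear")
})

test_that("landmark Cartesian distances follow Pythagoras", {
  A <- matrix(0, 4, 3)
  B <- A
  B[1, ] <- c(3, 4, 0)
  d <- landmark_cartesian_distance(A, B)
  expect_equal(d$distance, c(5, 0, 0, 0))
  expect_equal(attr(d, "mean"), 1.25)
  expect_equal(attr(d, "range"), c(0, 5))
  expect_error(landmark_cartesian_distance(A, B[1:2, ]), "counts differ")
})

test_that("meshes round-trip through binary STL", {
  s <- icosphere(2, c(1, 1, 1), subdiv = 2)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, path)
  s2 <- read_stl(path)
  expect_equal(nrow(s2$triangles), nrow(s$triangles))
  expect_equal(mesh_area(s2), mesh_area(s), tolerance = 1e-6)
  expect_true(isTRUE(is_watertight(s2)))
})
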