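make_pair <- function(seed = 3, jitter = 0) {
  tr <- generate_tree("left", desk_left_params(), seed = seed)
  g <- gantry_geometry()
  projs <- project_tree(tr, g)
  if (jitter > 0)
    projs <- lapply(1:2, function(k)
      degrade_projection(projs[[k]], jitter, 0, seed = seed + 10 * k))
  list(tree = tr, gantry = g, a = projs[[1]], b = projs[[2]])
}

test_that("noise-free correspondences have vanishing epipolar residuals", {
  p <- make_pair()
  m <- correspond_points(p$a, p$b, p$gantry)
  expect_lt(max(m$residual), 1e-6)
  # matched index pairs strictly increasing in both views per segment
  for (id in unique(m$segment)) {
    mi <- m[m$segment == id, ]
    expect_true(all(diff(mi$i) > 0))
    expect_true(all(diff(mi$j) > 0))
  }
})

test_that("segments missing from one view are excluded with a warning", {
  p <- make_pair()
  p$b$segments$OM1 <- NULL
  expect_warning(m <- correspond_points(p$a, p$b, p$gantry), "OM1")
  expect_false("OM1" %in% m$segment)
})

test_that("triangulation recovers a hand-built exact intersection", {
  g <- gantry_geometry()
  camA <- coroflow:::gantry_camera(g, 1)
  camB <- coroflow:::gantry_camera(g, 2)
  X <- c(10, 0, 5)
  uvA <- coroflow:::project_points(matrix(X, 1, 3), camA)$uv
  uvB <- coroflow:::project_points(matrix(X, 1, 3), camB)$uv
  m <- tibble::tibble(segment = "S", i = 1L, j = 1L,
                      uA = uvA[1], vA = uvA[2], uB = uvB[1], vB = uvB[2],
                      widthA = 10, widthB = 10, residual = 0)
  attr(m, "segment_meta") <- tibble::tibble(segment = "S",
                                            parent = NA_character_,
                                            parent_frac = NA_real_)
  attr(m, "views") <- c(1, 2)
  # two matched points so the polyline is valid
  m2 <- rbind(m, m)
  X2 <- c(12, 1, 6)
  uvA2 <- coroflow:::project_points(matrix(X2, 1, 3), camA)$uv
  uvB2 <- coroflow:::project_points(matrix(X2, 1, 3), camB)$uv
  m2$uA[2] <- uvA2[1]; m2$vA[2] <- uvA2[2]
  m2$uB[2] <- uvB2[1]; m2$vB[2] <- uvB2[2]
  m2$i[2] <- 2L; m2$j[2] <- 2L
  attr(m2, "segment_meta") <- attr(m, "segment_meta")
  attr(m2, "views") <- c(1, 2)
  tr <- triangulate_matches(m2, g)
  expect_equal(tr$segments$S$points[1, ], X, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(attr(tr, "matches")$gap), 1e-8)
})

test_that("triangulation gap equals the closed-form skew-line distance", {
  g <- gantry_geometry()
  camA <- coroflow:::gantry_camera(g, 1)
  camB <- coroflow:::gantry_camera(g, 2)
  # project two slightly different 3D points so the rays are skew
  Xa <- c(5, 2, -3)
  Xb <- Xa + c(0.4, -0.2, 0.3)
  uvA <- coroflow:::project_points(rbind(Xa, Xa + c(2, 0, 0)), camA)$uv
  uvB <- coroflow:::project_points(rbind(Xb, Xb + c(2, 0, 0)), camB)$uv
  m <- tibble::tibble(segment = "S", i = 1:2, j = 1:2,
                      uA = uvA[, 1], vA = uvA[, 2],
                      uB = uvB[, 1], vB = uvB[, 2],
                      widthA = 5, widthB = 5, residual = 0)
  attr(m, "segment_meta") <- tibble::tibble(segment = "S",
                                            parent = NA_character_,
                                            parent_frac = NA_real_)
  attr(m, "views") <- c(1, 2)
  tr <- triangulate_matches(m, g)
  dA <- coroflow:::pixel_ray(uvA, camA)
  dB <- coroflow:::pixel_ray(uvB, camB)
  gap_oracle <- skew_line_distance(camA$S, dA[1, ], camB$S, dB[1, ])
  expect_equal(unname(attr(tr, "matches")$gap[1]), gap_oracle,
               tolerance = 1e-9)
})

test_that("noise-free round trip recovers centerlines and radii", {
  p <- make_pair()
  rec <- reconstruct_tree(p$a, p$b, p$gantry)
  rep <- evaluate_reconstruction(rec, p$tree)
  expect_lt(max(rep$rmse), 1e-3)
  # diameters within 0.1% relative
  mean_d <- mean(unlist(lapply(p$tree$segments, function(s) 2 * s$radii)))
  expect_lt(max(rep$diameter_mae) / mean_d, 1e-3)
})

test_that("doubling projected widths doubles recovered radii", {
  p <- make_pair()
  m <- correspond_points(p$a, p$b, p$gantry)
  tr1 <- recover_diameters(triangulate_matches(m, p$gantry), p$gantry)
  m2 <- m
  m2$widthA <- 2 * m2$widthA
  m2$widthB <- 2 * m2$widthB
  attributes(m2)[c("segment_meta", "views")] <-
    attributes(m)[c("segment_meta", "views")]
  tr2 <- recover_diameters(triangulate_matches(m2, p$gantry), p$gantry)
  expect_equal(tr2$segments$LAD$radii, 2 * tr1$segments$LAD$radii,
               tolerance = 1e-12)
})

test_that("disagreeing views average and report the discrepancy", {
  p <- make_pair()
  m <- correspond_points(p$a, p$b, p$gantry)
  m$widthB <- 1.25 * m$widthB  # 25% one-sided inflation
  attributes(m)[c("segment_meta", "views")] <-
    attributes(m)[c("segment_meta", "views")]
  expect_message(
    tr <- recover_diameters(triangulate_matches(m, p$gantry), p$gantry),
    "disagree")
  base <- recover_diameters(
    triangulate_matches(correspond_points(p$a, p$b, p$gantry), p$gantry),
    p$gantry)
  expect_equal(tr$segments$LAD$radii, base$segments$LAD$radii * 1.125,
               tolerance = 1e-9)
})

test_that("reconstruction is invariant to swapping the two views", {
  p <- make_pair()
  r1 <- reconstruct_tree(p$a, p$b, p$gantry)
  r2 <- reconstruct_tree(p$b, p$a, p$gantry)
  expect_equal(r1$segments$LAD$points, r2$segments$LAD$points,
               tolerance = 1e-8)
})

test_that("jittered projections stay accurate and degrade gracefully", {
  p <- make_pair(seed = 11, jitter = 1)
  m <- correspond_points(p$a, p$b, p$gantry)
  expect_lt(mean(m$residual), 1.5)
  # correspondence indices within +/-2 of the identity pairing for >= 95%
  expect_gt(mean(abs(m$i - m$j) <= 2), 0.95)
  # RMSE grows monotonically in expectation with jitter amplitude
  # (the full 20-seed sweep runs with the acceptance checks)
  sds <- c(0, 1, 2)
  mean_rmse <- vapply(sds, function(sdv) {
    mean(vapply(1:8, function(s) {
      p <- make_pair(seed = 100 + s, jitter = sdv)
      rec <- reconstruct_tree(p$a, p$b, p$gantry)
      mean(evaluate_reconstruction(rec, p$tree)$rmse)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_rmse) > 0))
})

test_that("evaluation identities: self, translation, label mismatch", {
  tr <- generate_tree("left", desk_left_params(), seed = 12)
  rep <- evaluate_reconstruction(tr, tr)
  expect_equal(max(rep$rmse), 0)
  shifted <- tr
  for (id in names(shifted$segments))
    shifted$segments[[id]]$points <-
      sweep(shifted$segments[[id]]$points, 2, c(-3, -4, 0))
  rep2 <- evaluate_reconstruction(shifted, tr)
  expect_equal(rep2$rmse, rep(5, nrow(rep2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  bad <- tr
  names(bad$segments)[4] <- bad$segments[[4]]$id <- "Mystery"
  expect_error(evaluate_reconstruction(bad, tr), "Mystery")
})
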