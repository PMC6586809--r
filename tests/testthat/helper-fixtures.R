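# shared fixtures built in code

# straight single-segment tube tree along +x
tube_tree <- function(length = 20, radius = 1.5, ds = 0.5) {
  pts <- cbind(seq(0, length, by = ds), 0, 0)
  seg <- coroflow:::new_segment("T", pts, rep(radius, nrow(pts)))
  coroflow:::new_vessel_tree(list(T = seg), "T")
}

# symmetric (or asymmetric) planar Y bifurcation
bifurcation_tree <- function(rB = c(1.0, 0.85), rC = c(1.0, 0.85),
                             trunk_len = 10, branch_len = 15,
                             half_angle = 35) {
  pA <- cbind(seq(0, trunk_len, 0.5), 0, 0)
  a <- half_angle * pi / 180
  dirB <- c(cos(a), sin(a), 0)
  dirC <- c(cos(a), -sin(a), 0)
  end <- c(trunk_len, 0, 0)
  sB <- seq(0, branch_len, 0.5)
  pB <- t(vapply(sB, function(s) end + s * dirB, numeric(3)))
  pC <- t(vapply(sB, function(s) end + s * dirC, numeric(3)))
  segs <- list(
    A = coroflow:::new_segment("A", pA, rep(1.5, nrow(pA))),
    B = coroflow:::new_segment("B", pB,
          seq(rB[1], rB[2], length.out = nrow(pB)), parent = "A",
          parent_frac = 1),
    C = coroflow:::new_segment("C", pC,
          seq(rC[1], rC[2], length.out = nrow(pC)), parent = "A",
          parent_frac = 1))
  coroflow:::new_vessel_tree(segs, "A")
}

# small desk-scale left tree parameters used across tests
desk_left_params <- function(n_diag = 1, n_om = 1) {
  list(n_diag = n_diag, n_om = n_om,
       lm = list(length = 8, r0 = 2.0, r1 = 1.85),
       lad = list(length = 40, r0 = 1.6, r1 = 0.8),
       lcx = list(length = 30, r0 = 1.5, r1 = 0.8),
       branch_length = c(12, 18), diag_span = c(0.25, 0.68))
}

# independent pinhole-projection oracle using a homogeneous camera matrix
oracle_project <- function(P, gantry, k) {
  cam <- coroflow:::gantry_camera(gantry, k)
  R <- rbind(cam$xv, cam$yv, cam$zv)
  t <- -drop(R %*% cam$S)
  f <- cam$sid / cam$pixel
  K <- matrix(c(f, 0, 0, 0, f, 0, cam$center[1], cam$center[2], 1), 3, 3)
  M <- K %*% cbind(R, t)
  X <- cbind(P, 1) %*% t(M)
  X[, 1:2] / X[, 3]
}

# closed-form distance between two skew lines
skew_line_distance <- function(S1, d1, S2, d2) {
  n <- coroflow:::pracma_cross(d1, d2)
  abs(sum((S2 - S1) * n)) / sqrt(sum(n^2))
}

# volume of a branch tube outside its parent's lumen: per-piece conical
# frusta, with the fraction outside the parent capsule estimated by
# brute-force point sampling inside each slab
branch_volume_outside_parent <- function(seg, parent, n_per_piece = 400,
                                         seed = 1) {
  pc <- coroflow:::tree_pieces(coroflow:::new_vessel_tree(
    setNames(list(parent), parent$id), parent$id))
  v <- 0
  coroflow:::with_seed(seed, {
    for (i in seq_len(nrow(seg$points) - 1)) {
      a <- seg$points[i, ]; b <- seg$points[i + 1, ]
      r1 <- seg$radii[i]; r2 <- seg$radii[i + 1]
      h <- sqrt(sum((b - a)^2))
      vol <- pi / 3 * h * (r1^2 + r1 * r2 + r2^2)
      # uniform samples in the slab (rejection from bounding cylinder)
      tpar <- runif(n_per_piece)
      rr <- sqrt(runif(n_per_piece)) * (r1 + (r2 - r1) * tpar)
      th <- runif(n_per_piece, 0, 2 * pi)
      axis <- (b - a) / h
      e1 <- coroflow:::unitize(coroflow:::pracma_cross(
        axis, if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
      e2 <- coroflow:::pracma_cross(axis, e1)
      P <- outer(tpar, b - a) + matrix(a, n_per_piece, 3, byrow = TRUE) +
        outer(rr * cos(th), e1) + outer(rr * sin(th), e2)
      near <- coroflow:::cpp_tree_nearest(P, pc$A, pc$B, pc$ra, pc$rb)
      outside <- mean(near$d_axis > near$radius)
      v <- v + vol * outside
    }
  })
  v
}
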