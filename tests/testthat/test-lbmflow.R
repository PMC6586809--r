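test_that("fluid constants default to whole-blood values", {
  fl <- fluid_config()
  expect_equal(fl$mu, 0.004)   # 4 cP
  expect_equal(fl$rho, 1060)   # kg/m^3
  expect_error(fluid_config(mu = -1), "positive")
})

test_that("inlet specification enforces a unit-mean waveform", {
  inl <- inlet_spec("pulsatile")
  expect_equal(inl$v_mean, 0.28)
  expect_equal(coroflow:::waveform_mean(inl$waveform), 1, tolerance = 1e-6)
  expect_equal(inlet_spec("steady")$v_mean, 0.25)
  bad <- tibble::tibble(t_frac = seq(0, 0.9, 0.1), w = rep(2, 10))
  expect_error(inlet_spec("pulsatile", waveform = bad, normalize = FALSE),
               "mean")
  norm <- inlet_spec("pulsatile", waveform = bad)
  expect_equal(coroflow:::waveform_mean(norm$waveform), 1, tolerance = 1e-9)
})

test_that("unit mapping reproduces nu = mu/rho and guards the tau window", {
  tr <- tube_tree(length = 10, radius = 1.5)
  g <- voxelize(loft_mesh(tr, h = 0.12), 0.15)
  inl <- inlet_spec("steady", v_mean = 0.28)
  st <- build_lattice(g, fluid_config(), inl, mach = 0.08)
  expect_equal(st$nu, 0.004 / 1060)   # 3.77e-6 m^2/s
  expect_gt(st$tau, 0.5)
  expect_lte(st$tau, 2)
  # lattice viscosity consistency: nu = cs^2 (tau - 1/2) dx^2/dt
  expect_equal((st$tau - 0.5) / 3 * st$Cx^2 / st$Ct, st$nu,
               tolerance = 1e-12)
  expect_error(build_lattice(g, fluid_config(), inl, mach = 0.2),
               "Mach")
  # a hugely viscous fluid pushes tau over the ceiling
  expect_error(build_lattice(g, fluid_config(mu = 10), inl, mach = 0.08),
               "relaxation time")
})

test_that("a quiescent initialized lattice has zero velocity and zero WSS", {
  tr <- tube_tree(length = 8, radius = 1.2)
  g <- voxelize(loft_mesh(tr, h = 0.12), 0.2)
  inl <- inlet_spec("steady", v_mean = 0.25)
  st <- build_lattice(g, fluid_config(), inl, mach = 0.08)
  st <- initialize_equilibrium(st, function(P) matrix(0, nrow(P), 3))
  w <- extract_wss(st)
  expect_equal(max(abs(w$tau_pa)), 0)
})

test_that("Murray resistance assignment satisfies its identities", {
  tr <- tube_tree(length = 10, radius = 1.5)
  outs1 <- assign_resistances(tr, total_mean_flow = 2e-6)
  expect_equal(nrow(outs1), 1)
  expect_equal(outs1$resistance, attr(outs1, "R_tot"))  # single outlet
  bi <- bifurcation_tree(rB = c(1.0, 1.0), rC = c(0.5, 0.5))
  outs2 <- assign_resistances(bi, total_mean_flow = 2e-6)
  # d = 2 mm vs 1 mm: resistance ratio 1:8
  rB <- outs2$resistance[outs2$segment == "B"]
  rC <- outs2$resistance[outs2$segment == "C"]
  expect_equal(rC / rB, 8)
  # parallel combination returns R_tot to 1e-9 relative
  expect_equal(1 / sum(1 / outs2$resistance), attr(outs2, "R_tot"),
               tolerance = 1e-9)
  # at a common pressure the flow split is 8:1
  q <- (1 / outs2$resistance) / sum(1 / outs2$resistance)
  expect_equal(unname(q[outs2$segment == "B"] / q[outs2$segment == "C"]), 8)
})

test_that("the 0D network solve matches a hand-built two-resistor circuit", {
  bi <- bifurcation_tree(rB = c(1.0, 1.0), rC = c(0.5, 0.5))
  outs <- assign_resistances(bi, total_mean_flow = 2e-6)
  net <- solve_network0d(bi, outs, inflow = 2e-6)
  expect_equal(sum(net$q), 2e-6, tolerance = 1e-12)
  # independent oracle: series tube resistance + outlet resistance per arm
  mu <- 0.004
  tube_R <- function(L, r) 8 * mu * (L * 1e-3) / (pi * (r * 1e-3)^4)
  RB <- tube_R(15, 1.0) + outs$resistance[outs$segment == "B"]
  RC <- tube_R(15, 0.5) + outs$resistance[outs$segment == "C"]
  split_oracle <- (1 / RB) / (1 / RB + 1 / RC)
  expect_equal(net$q[net$segment == "B"] / sum(net$q), split_oracle,
               tolerance = 1e-3)
})

test_that("steady tube flow reproduces Poiseuille at reduced scale", {
  # compact configuration (12 voxels/diameter) for the routine suite; the
  # full 20-voxel validation runs with the acceptance checks
  tr <- tube_tree(length = 18, radius = 1.2)
  g <- voxelize(loft_mesh(tr, h = 0.12), 0.2)
  inl <- inlet_spec("steady", v_mean = 0.2)
  outs <- assign_resistances(tr, total_mean_flow = 0.2 * pi * 1.2e-3^2)
  st <- build_lattice(g, fluid_config(), inl, mach = 0.08)
  st <- initialize_equilibrium(st, function(P) {
    r2 <- (P[, 2]^2 + P[, 3]^2) / 1.2^2
    cbind(2 * 0.2 * pmax(1 - r2, 0), 0, 0)
  })
  res <- suppressWarnings(run_steady(st, inl, outs, max_steps = 9000,
                                     tol = 1e-5))
  # mass conservation at the boundaries
  qin <- tail(attr(res$flows, "inflow")$q, 1)
  qout <- tail(res$flows$q, 1)
  expect_equal(qin, 0.2 * pi * 1.2e-3^2 * 1e6, tolerance = 1e-3)
  expect_lt(abs(qin - qout) / qin, 0.01)
  # wall shear within 10% of 4 mu v / R at this coarse resolution
  w <- res$wss
  w2 <- w[w$x > 10 & w$x < 16, ]
  expect_equal(mean(w2$taess), 4 * 0.004 * 0.2 / 1.2e-3, tolerance = 0.1)
  # doubling the mean velocity doubles WSS in the laminar regime
  inl2 <- inlet_spec("steady", v_mean = 0.4)
  st2 <- build_lattice(g, fluid_config(), inl2, mach = 0.08)
  st2 <- initialize_equilibrium(st2, function(P) {
    r2 <- (P[, 2]^2 + P[, 3]^2) / 1.2^2
    cbind(2 * 0.4 * pmax(1 - r2, 0), 0, 0)
  })
  res2 <- suppressWarnings(run_steady(st2, inl2,
    assign_resistances(tr, total_mean_flow = 0.4 * pi * 1.2e-3^2),
    max_steps = 9000, tol = 1e-5))
  w3 <- res2$wss[res2$wss$x > 10 & res2$wss$x < 16, ]
  expect_equal(mean(w3$taess) / mean(w2$taess), 2, tolerance = 0.02)
})

test_that("pulsatile tube tracks the quasi-steady Poiseuille oracle", {
  # low Womersley number via a viscous test fluid (alpha ~ 0.5)
  mu <- 0.04
  tr <- tube_tree(length = 10, radius = 1.0)
  g <- voxelize(loft_mesh(tr, h = 0.1), 0.15)
  inl <- inlet_spec("pulsatile", v_mean = 0.1, period = 0.8)
  outs <- assign_resistances(tr, total_mean_flow = 0.1 * pi * 1e-6)
  st <- build_lattice(g, fluid_config(mu = mu), inl, mach = 0.08)
  res <- run_transient(st, inl, outs, n_cycles = 2, periodicity_tol = 0.1)
  w <- res$wss
  times <- attr(w, "times")
  sel <- w$x > 4 & w$x < 8
  inst <- colMeans(as.matrix(w[sel, grep("^t[0-9]+$", names(w))]))
  # quasi-steady oracle: 4 mu vbar w(t) / R at each snapshot
  tf <- times / attr(w, "period")
  oracle <- 4 * mu * 0.1 *
    coroflow:::waveform_at(inl$waveform, tf) / 1e-3
  expect_lt(max(abs(inst - oracle) / max(oracle)), 0.1)
  # TAESS of the tracked signal close to the steady mean value
  ta <- taess(w)
  expect_equal(mean(ta$taess[sel]), 4 * mu * 0.1 / 1e-3, tolerance = 0.1)
  # global mass conservation over the final cycle
  fl <- res$flows
  last <- fl$t > max(fl$t) - attr(w, "period")
  qin <- mean(attr(fl, "inflow")$q[last])
  qout <- mean(fl$q[last])
  expect_lt(abs(qin - qout) / qin, 0.01)
})

test_that("transient through the steady interface has vanishing WSS variance", {
  tr <- tube_tree(length = 8, radius = 1.0)
  g <- voxelize(loft_mesh(tr, h = 0.1), 0.18)
  inl <- inlet_spec("steady", v_mean = 0.15, period = 0.1)
  outs <- assign_resistances(tr, total_mean_flow = 0.15 * pi * 1e-6)
  st <- build_lattice(g, fluid_config(mu = 0.02), inl, mach = 0.08)
  res <- suppressWarnings(run_transient(st, inl, outs, n_cycles = 4,
                                        n_wss = 10))
  M <- as.matrix(res$wss[, grep("^t[0-9]+$", names(res$wss))])
  # time variance across the final cycle is negligible vs the mean
  rel_var <- apply(M, 1, sd) / pmax(rowMeans(M), 1e-12)
  expect_lt(stats::median(rel_var), 0.02)
})

test_that("the resolution convergence driver reports decreasing change", {
  tr <- tube_tree(length = 10, radius = 1.2)
  inl <- inlet_spec("steady", v_mean = 0.15)
  outs <- assign_resistances(tr, total_mean_flow = 0.15 * pi * 1.2e-3^2)
  rep <- suppressWarnings(suppressMessages(mesh_independence(
    tr, resolutions = c(0.3, 0.24, 0.2), inlet = inl, outlets = outs,
    fluid = fluid_config(mu = 0.02), max_steps = 5000, tol = 1e-4)))
  expect_equal(nrow(rep), 3)
  expect_true(is.na(rep$rel_change[1]))
  expect_true(all(is.finite(rep$rel_change[-1])))
  # identical resolution twice: zero change
  rep2 <- suppressWarnings(suppressMessages(mesh_independence(
    tr, resolutions = c(0.3, 0.3), inlet = inl, outlets = outs,
    fluid = fluid_config(mu = 0.02), max_steps = 3000, tol = 1e-4)))
  expect_equal(rep2$rel_change[2], 0, tolerance = 1e-12)
})
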