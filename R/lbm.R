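#' Blood rheology configuration
#'
#' Defaults model blood as an incompressible Newtonian fluid with dynamic
#' viscosity 4 cP and density 1060 kg/m^3; both are overridable.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param rho Density (kg/m^3).
#' @export
fluid_config <- function(mu = 0.004, rho = 1060) {
  if (mu <= 0 || rho <= 0) abort("viscosity and density must be positive")
  structure(list(mu = mu, rho = rho), class = "fluid_config")
}

#' Packaged coronary inflow waveform
#'
#' A two-phase, diastolic-dominant periodic velocity waveform (systolic dip,
#' diastolic peak) with unit mean, shipped as a plain CSV
#' (`t_frac` in cycle fractions, multiplier `w`) and fully user-replaceable.
#'
#' @param path Optional CSV path overriding the packaged waveform.
#' @return Tibble with `t_frac` and `w`.
#' @export
default_waveform <- function(path = NULL) {
  path <- path %||% system.file("extdata", "coronary_waveform.csv",
                                package = "coroflow")
  wf <- as_tibble(read.csv(path))
  stopifnot(all(c("t_frac", "w") %in% names(wf)))
  wf
}

# periodic mean of a waveform over one cycle (trapezoid with wrap-around)
waveform_mean <- function(wf) {
  t <- c(wf$t_frac, 1)
  w <- c(wf$w, wf$w[1])
  trapz(t, w)
}

#' Inlet boundary specification
#'
#' A Poiseuille (parabolic) velocity profile is imposed over the inlet disk,
#' scaled in time by `v_mean * w(t)`.  Defaults: 0.25 m/s steady (average
#' diastolic velocity) and 0.28 m/s cycle-mean for pulsatile flow with the
#' packaged waveform, period 0.8 s.
#'
#' @param mode `"steady"` or `"pulsatile"`.
#' @param v_mean Cycle-mean inlet velocity (m/s); defaults 0.25 (steady) /
#'   0.28 (pulsatile).
#' @param waveform Tibble `t_frac`, `w` with unit mean (steady mode uses a
#'   constant 1).
#' @param period Cardiac period (s).
#' @param normalize Rescale the waveform to unit mean (otherwise a non-unit
#'   mean is an error).
#' @export
inlet_spec <- function(mode = c("pulsatile", "steady"), v_mean = NULL,
                       waveform = NULL, period = 0.8, normalize = TRUE) {
  mode <- match.arg(mode)
  v_mean <- v_mean %||% if (mode == "steady") 0.25 else 0.28
  if (v_mean <= 0) abort("mean inlet velocity must be positive")
  if (mode == "steady") {
    waveform <- tibble(t_frac = c(0, 0.5), w = c(1, 1))
  } else {
    waveform <- waveform %||% default_waveform()
    m <- waveform_mean(waveform)
    if (abs(m - 1) > 1e-6) {
      if (!normalize)
        abort(sprintf("waveform mean is %.6f; must be 1", m))
      waveform$w <- waveform$w / m
    }
  }
  structure(list(mode = mode, v_mean = v_mean, waveform = waveform,
                 period = period), class = "inlet_spec")
}

# waveform multiplier at cycle fraction(s) tf (periodic linear interpolation)
waveform_at <- function(wf, tf) {
  tf <- tf %% 1
  t <- c(wf$t_frac, 1)
  w <- c(wf$w, wf$w[1])
  approx(t, w, xout = tf, rule = 2)$y
}

#' Distribute outlet resistances over a tree
#'
#' The total coronary microcirculation resistance is set from the mean
#' aortic pressure and total mean flow, `R_tot = P / Q`, and apportioned
#' over the outlets in parallel with conductances proportional to the cubed
#' outlet diameter (Murray's-law exponent, configurable):
#' `R_i = R_tot * sum(d_j^m) / d_i^m`, so the parallel combination equals
#' `R_tot` exactly.
#'
#' @param tree A `vessel_tree`.
#' @param mean_aortic_pressure Mean aortic pressure (Pa; default 90 mmHg).
#' @param total_mean_flow Total mean coronary flow (m^3/s).  Defaults to the
#'   inlet area times a 0.28 m/s mean velocity.
#' @param murray_exponent Diameter exponent (default 3).
#' @return Tibble with `segment`, `diameter` (mm), `resistance` (Pa s/m^3);
#'   `R_tot` attached as an attribute.
#' @export
assign_resistances <- function(tree, mean_aortic_pressure = 90 * 133.322,
                               total_mean_flow = NULL, murray_exponent = 3) {
  outs <- tree_outlets(tree)
  if (nrow(outs) == 0) abort("tree has no outlets")
  if (mean_aortic_pressure <= 0) abort("pressure must be positive")
  inl <- tree_inlet(tree)
  total_mean_flow <- total_mean_flow %||% (pi * (inl$radius * 1e-3)^2 * 0.28)
  if (total_mean_flow <= 0) abort("flow must be positive")
  R_tot <- mean_aortic_pressure / total_mean_flow
  dm <- outs$diameter^murray_exponent
  out <- tibble(segment = outs$segment, diameter = outs$diameter,
                resistance = R_tot * sum(dm) / dm)
  attr(out, "R_tot") <- R_tot
  out
}

#' Build a lattice for the flow solver
#'
#' Fixes the lattice-to-physical unit map: the spatial step is the voxel
#' spacing, the time step is chosen so the estimated peak velocity maps to
#' the target lattice Mach number, and the relaxation time follows from the
#' kinematic viscosity through the BGK relation `nu = cs^2 (tau - 1/2) dt`.
#' The estimated peak accounts for the parabolic profile (2x mean), the
#' waveform peak, and flow acceleration through the tightest declared
#' stenosis.
#'
#' @param grid A `voxel_grid`.
#' @param fluid A [fluid_config()].
#' @param inlet An [inlet_spec()].
#' @param mach Target lattice Mach number (< 0.1).
#' @param u_peak_est Override for the peak physical velocity estimate (m/s).
#' @return A `lattice_state` carrying the unit scales and relaxation time;
#'   distributions are initialized at rest on first use.
#' @export
build_lattice <- function(grid, fluid, inlet, mach = 0.05,
                          u_peak_est = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(fluid, "fluid_config"))
  if (mach >= 0.1) abort("target lattice Mach number must be below 0.1")
  tree <- attr(grid, "tree")
  jet <- 1
  if (!is.null(tree) && length(tree$stenoses) > 0) {
    sev <- max(vapply(tree$stenoses, function(s) s$severity, 1))
    jet <- 1 / (1 - sev)^2
  }
  wmax <- max(inlet$waveform$w)
  u_peak <- u_peak_est %||% (2 * inlet$v_mean * wmax * jet)
  Cx <- grid$h * 1e-3
  u_lat <- mach / sqrt(3)
  Cu <- u_peak / u_lat
  Ct <- Cx / Cu
  nu <- fluid$mu / fluid$rho
  nu_lat <- nu * Ct / Cx^2
  tau <- 3 * nu_lat + 0.5
  if (tau <= 0.5 || tau > 2)
    abort(sprintf(
      "relaxation time %.4f outside (0.5, 2]; change the voxel resolution or Mach target",
      tau))
  structure(list(grid = grid, fluid = fluid, tau = tau, mach = mach,
                 Cx = Cx, Ct = Ct, Cu = Cu, Cp = fluid$rho * Cu^2,
                 nu = nu, f = NULL),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(
    "<lattice_state> %d fluid nodes, tau=%.4f, dx=%.3g mm, dt=%.3g s, Mach %.3g\n",
    x$grid$n_fluid, x$tau, x$Cx * 1e3, x$Ct, x$mach))
  invisible(x)
}

# interpolated (Bouzidi) walls need some odd-mode relaxation margin; very
# close to tau = 1/2 the interpolation feeds a near-wall mode, so the solver
# falls back to plain halfway bounce-back there
bouzidi_field <- function(state, setup) {
  if (state$tau >= 0.503) setup$fgrid else NULL
}

# assemble solver arguments shared by steady and transient drivers
lbm_setup <- function(state, outlets) {
  grid <- state$grid
  cls <- grid$cls
  dims <- grid$dims
  fl <- which(cls == 2L) - 1L
  xyz <- arrayInd(fl + 1L, dims)
  P <- sweep((xyz - 1) * grid$h, 2, grid$origin, `+`)
  inl <- grid$inlet
  dv <- sweep(P, 2, inl$center)
  s <- drop(dv %*% inl$normal)
  r2 <- pmax(rowSums(dv^2) - s^2, 0)
  w <- pmax(2 * (1 - r2 / inl$radius^2), 0.02)
  # normalize so the discrete piston flux equals v_mean * pi R^2 exactly
  w <- w * (pi * inl$radius^2 / grid$h^2) / sum(w)
  om <- grid$outlets
  stopifnot(nrow(om) > 0)
  ord <- match(om$segment, outlets$segment)
  if (any(is.na(ord)))
    abort(paste0("outlet resistances missing for: ",
                 paste(om$segment[is.na(ord)], collapse = ", ")))
  R_phys <- outlets$resistance[ord]
  R_lat <- R_phys * state$Cx^2 / (state$fluid$rho * state$Cu)
  oidx <- integer(0); okk <- integer(0)
  for (k in seq_len(nrow(om))) {
    sel <- which(cls == 2L + k) - 1L
    oidx <- c(oidx, sel)
    okk <- c(okk, rep(k, length(sel)))
  }
  # the explicit 3D-0D outlet coupling is a fixed-point iteration whose
  # differential gain scales with R_outlet over the internal (Poiseuille)
  # path resistance; under-relax each outlet accordingly or the lumped
  # loop oscillates when branches are short and wide
  tree <- attr(grid, "tree")
  relax <- rep(0.05, nrow(om))
  if (!is.null(tree)) {
    net <- tryCatch(solve_network0d(tree, outlets, inflow = 1e-6,
                                    fluid = state$fluid),
                    error = function(e) NULL)
    if (!is.null(net)) {
      ordn <- match(om$segment, net$segment)
      z_path <- (net$p_inlet[1] - net$q[ordn] * R_phys) / net$q[ordn]
      relax <- pmin(0.05, pmax(0.25 * z_path / R_phys, 5e-4))
    }
  }
  list(cls = cls, dims = dims, inlet_idx = fl, inlet_w = w,
       inlet_n = inl$normal, outlet_idx = oidx, outlet_k = okk,
       outlet_n = as.matrix(om[, c("nx", "ny", "nz")]), R_lat = R_lat,
       relax = relax,
       outlet_segments = om$segment, fgrid = grid$field,
       inlet_area_lat = pi * (inl$radius / grid$h)^2)
}

# wrap a raw solver return into physical-unit tibbles
lbm_postprocess <- function(state, setup, raw, times_wss) {
  grid <- state$grid
  xyz <- arrayInd(raw$node_idx + 1L, grid$dims)
  P <- sweep((xyz - 1) * grid$h, 2, grid$origin, `+`)
  fields <- tibble(
    x = P[, 1], y = P[, 2], z = P[, 3],
    ux = raw$ux * state$Cu, uy = raw$uy * state$Cu, uz = raw$uz * state$Cu,
    p = (raw$rho - 1) / 3 * state$Cp)
  nwrec <- raw$wss_recorded
  wss <- NULL
  if (nwrec > 0) {
    m <- raw$wss[, seq_len(nwrec), drop = FALSE] * state$Cp
    wss <- as_tibble(cbind(grid$wall,
                           setNames(as.data.frame(m),
                                    paste0("t", seq_len(nwrec)))))
    attr(wss, "times") <- times_wss[seq_len(nwrec)]
  }
  qconv <- state$Cu * state$Cx^2 * 1e6  # lattice flow -> ml/s
  flows <- NULL
  if (length(raw$flow_steps) > 0) {
    tt <- (raw$flow_steps + 1) * state$Ct
    flows <- bind_rows(lapply(seq_along(setup$R_lat), function(k) {
      tibble(segment = setup$outlet_segments[k], t = tt,
             q = raw$flows[k, ] * qconv)
    }))
    attr(flows, "inflow") <- tibble(t = tt, q = raw$inflow * qconv)
  }
  state$f <- raw$f
  list(state = state, fields = fields, wss = wss, flows = flows,
       steps_done = raw$steps_done, converged = raw$converged,
       residual = raw$residual)
}

#' Initialize lattice distributions at equilibrium with a velocity field
#'
#' Sets the distributions to the local equilibrium of unit density and a
#' prescribed physical velocity, useful to start a steady run close to the
#' expected solution (e.g. a Poiseuille profile) and cut the transient.
#'
#' @param state A `lattice_state`.
#' @param velocity Function of an n x 3 position matrix (mm) returning an
#'   n x 3 velocity matrix (m/s).
#' @return The state with initialized distributions.
#' @export
initialize_equilibrium <- function(state, velocity) {
  grid <- state$grid
  packed <- which(grid$cls == 1L)
  xyz <- arrayInd(packed, grid$dims)
  P <- sweep((xyz - 1) * grid$h, 2, grid$origin, `+`)
  u <- velocity(P) / state$Cu
  n <- nrow(u)
  cx <- c(0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0)
  cy <- c(0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1)
  cz <- c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1)
  wq <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  f <- matrix(0, n, 19)
  u2 <- rowSums(u^2)
  for (q in 1:19) {
    cu <- u[, 1] * cx[q] + u[, 2] * cy[q] + u[, 3] * cz[q]
    f[, q] <- wq[q] * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * u2)
  }
  state$f <- as.numeric(f)
  state
}

#' Run the solver to a steady state
#'
#' Constant inflow at `inlet$v_mean` (ramped over `ramp_steps` to avoid a
#' start-up water hammer), iterated until the domain-mean speed changes by
#' less than `tol` between successive checks or `max_steps` is reached.
#'
#' @param state A `lattice_state` from [build_lattice()].
#' @param inlet An [inlet_spec()] (its waveform is ignored; steady mode).
#' @param outlets Outlet resistance table from [assign_resistances()].
#' @param max_steps,tol,check_every Convergence controls.
#' @param mass_tol Additional convergence requirement: relative
#'   inflow/outflow imbalance below this value.
#' @param ramp_steps Inlet ramp length (steps).
#' @param collision Collision operator: `"trt"` (two-relaxation-time,
#'   default), `"regularized"` (Hermite-regularized BGK), or plain `"bgk"`.
#' @param trt_lambda TRT odd-rate parameter Lambda; the default 0.03 trades
#'   wall-closure accuracy against advective stability at relaxation times
#'   close to 1/2 (the wall-exact value 3/16 is unstable there).
#' @return A `flow_result` list: updated state, macroscopic `fields` (m/s,
#'   Pa), wall `wss` table (Pa), outlet `flows` (ml/s), convergence info.
#' @export
run_steady <- function(state, inlet, outlets, max_steps = 60000L,
                       tol = 2e-4, check_every = 250L, ramp_steps = 1000L,
                       collision = c("regularized", "trt", "bgk"),
                       mass_tol = 0.005, trt_lambda = 0.03) {
  collision <- match.arg(collision)
  setup <- lbm_setup(state, outlets)
  U0 <- inlet$v_mean / state$Cu
  if (is.null(state$f)) {
    ramp <- sin(pmin(seq_len(max_steps) / max(ramp_steps, 1), 1) * pi / 2)^2
  } else {
    ramp <- rep(1, max_steps)  # continuing from an initialized state
    ramp_steps <- 0L
  }
  U <- U0 * ramp
  flow_every <- 50L
  raw <- cpp_lbm_run(setup$cls, setup$dims, setup$inlet_idx, setup$inlet_w,
                     setup$inlet_n, setup$outlet_idx, setup$outlet_k,
                     setup$outlet_n, setup$R_lat, relax = setup$relax,
                     flow_every = flow_every, U = U, tau = state$tau,
                     regularized = switch(collision, bgk = 0L, regularized = 1L, trt = 2L),
                     wss_idx = state$grid$wall$idx,
                     wss_normal = as.matrix(state$grid$wall[, c("nx", "ny", "nz")]),
                     wss_corr = state$grid$wall$corr,
                     wss_steps = as.integer(max_steps - 1),
                     f_init = state$f, check_every = as.integer(check_every),
                     conv_tol = tol,
                     min_steps = as.integer(max(2 * ramp_steps, 2000)),
                     fgrid = bouzidi_field(state, setup),
                     trt_lambda = trt_lambda,
                     inlet_area_lat = setup$inlet_area_lat,
                     mass_tol = mass_tol)
  res <- lbm_postprocess(state, setup, raw, times_wss = 0)
  if (!res$converged)
    warn(sprintf("steady run hit max_steps with residual %.3g", res$residual))
  res$wss$taess <- res$wss$t1
  class(res) <- "flow_result"
  res
}

#' Run a pulsatile (transient) simulation
#'
#' Simulates `n_cycles` cardiac cycles of the inlet waveform; the first
#' cycles serve as warm-up and wall shear stress is recorded over the final
#' cycle at `n_wss + 1` evenly spaced instants (both cycle endpoints
#' included).  Cycle-to-cycle periodicity is monitored on the outlet mean
#' flows; if the relative change between the last two cycles exceeds
#' `periodicity_tol` a warning reports the achieved residual.
#'
#' @inheritParams run_steady
#' @param n_cycles Number of cardiac cycles (>= 2).
#' @param n_wss WSS snapshots over the final cycle.
#' @param periodicity_tol Relative cycle-to-cycle tolerance on outlet flows.
#' @return A `flow_result`; `$wss` holds one column per snapshot and the
#'   snapshot times as an attribute.
#' @export
run_transient <- function(state, inlet, outlets, n_cycles = 2L, n_wss = 24L,
                          periodicity_tol = 0.05,
                          collision = c("regularized", "trt", "bgk"),
                          trt_lambda = 0.03) {
  collision <- match.arg(collision)
  if (n_cycles < 2) abort("transient runs need at least 2 cycles")
  setup <- lbm_setup(state, outlets)
  spc <- max(100L, as.integer(round(inlet$period / state$Ct)))
  nsteps <- spc * n_cycles
  tf <- (seq_len(nsteps) - 1) / spc
  ramp <- pmin(seq_len(nsteps) / (0.15 * spc), 1)
  U <- inlet$v_mean * waveform_at(inlet$waveform, tf) * ramp / state$Cu
  wss_steps <- as.integer(round(seq(spc * (n_cycles - 1), nsteps - 1,
                                    length.out = n_wss + 1)))
  flow_every <- max(1L, spc %/% 200L)
  raw <- cpp_lbm_run(setup$cls, setup$dims, setup$inlet_idx, setup$inlet_w,
                     setup$inlet_n, setup$outlet_idx, setup$outlet_k,
                     setup$outlet_n, setup$R_lat, relax = setup$relax,
                     flow_every = flow_every, U = U, tau = state$tau,
                     regularized = switch(collision, bgk = 0L, regularized = 1L, trt = 2L),
                     wss_idx = state$grid$wall$idx,
                     wss_normal = as.matrix(state$grid$wall[, c("nx", "ny", "nz")]),
                     wss_corr = state$grid$wall$corr,
                     wss_steps = wss_steps, f_init = state$f,
                     check_every = 500L, conv_tol = -1, min_steps = 0L,
                     fgrid = bouzidi_field(state, setup),
                     trt_lambda = trt_lambda,
                     inlet_area_lat = setup$inlet_area_lat)
  res <- lbm_postprocess(
    state, setup, raw,
    times_wss = (wss_steps - spc * (n_cycles - 1)) * state$Ct)
  if (!is.null(res$wss)) attr(res$wss, "period") <- spc * state$Ct
  # periodicity: outlet cycle means of the last two cycles
  fl <- res$flows
  cyc <- floor((fl$t - 1e-12) / inlet$period)
  means <- stats::aggregate(q ~ segment + cyc, data = fl, FUN = mean)
  last2 <- means[means$cyc >= n_cycles - 2, ]
  if (length(unique(last2$cyc)) == 2) {
    wide <- stats::reshape(last2, idvar = "segment", timevar = "cyc",
                           direction = "wide")
    qcols <- grep("^q\\.", names(wide))
    rel <- abs(wide[[qcols[2]]] - wide[[qcols[1]]]) /
      pmax(abs(wide[[qcols[2]]]), 1e-9)
    res$periodicity <- max(rel)
    if (res$periodicity > periodicity_tol)
      warn(sprintf(
        "cycle-to-cycle periodicity not reached: max relative outlet-flow change %.1f%%",
        100 * res$periodicity))
  }
  res$period <- inlet$period
  class(res) <- "flow_result"
  res
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> %d steps, %s\n", x$steps_done,
              if (isTRUE(x$converged)) "converged"
              else sprintf("residual %.3g", x$residual %||% NA)))
  invisible(x)
}

#' Extract the wall shear stress field from a solver state
#'
#' Computes the deviatoric stress from the non-equilibrium distribution
#' moments at every wall-adjacent fluid voxel, forms the traction against
#' the local wall normal, removes the normal component and reports the
#' tangential magnitude in Pa, linearly extrapolated from the voxel center
#' to the wall using the known wall distance and local lumen radius.
#'
#' @param state A `lattice_state` whose distributions have been advanced
#'   (e.g. the `$state` of a [run_steady()] result).
#' @return Tibble of wall samples with `tau_pa`.
#' @export
extract_wss <- function(state) {
  if (is.null(state$f)) abort("lattice state has no distributions yet")
  grid <- state$grid
  cls <- grid$cls
  packed <- which(cls == 1L)  # same scan order as the solver
  n <- length(packed)
  f <- matrix(state$f, nrow = n)
  cx <- c(0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0)
  cy <- c(0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1)
  cz <- c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1)
  wq <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  sel <- match(grid$wall$idx + 1L, packed)
  fs <- f[sel, , drop = FALSE]
  rho <- rowSums(fs)
  ux <- (fs %*% cx) / rho; uy <- (fs %*% cy) / rho; uz <- (fs %*% cz) / rho
  u2 <- ux^2 + uy^2 + uz^2
  pxx <- pyy <- pzz <- pxy <- pxz <- pyz <- numeric(length(sel))
  for (q in 1:19) {
    cu <- cx[q] * ux + cy[q] * uy + cz[q] * uz
    feq <- wq[q] * rho * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * u2)
    fn <- fs[, q] - feq
    pxx <- pxx + fn * cx[q]^2; pyy <- pyy + fn * cy[q]^2
    pzz <- pzz + fn * cz[q]^2; pxy <- pxy + fn * cx[q] * cy[q]
    pxz <- pxz + fn * cx[q] * cz[q]; pyz <- pyz + fn * cy[q] * cz[q]
  }
  # stored populations are post-collision; their non-equilibrium part is
  # (1 - 1/tau) times the pre-collision one
  fac <- -(1 - 1 / (2 * state$tau)) / (1 - 1 / state$tau)
  tr <- (pxx + pyy + pzz) / 3
  sxx <- fac * (pxx - tr); syy <- fac * (pyy - tr); szz <- fac * (pzz - tr)
  sxy <- fac * pxy; sxz <- fac * pxz; syz <- fac * pyz
  w <- grid$wall
  tx <- sxx * w$nx + sxy * w$ny + sxz * w$nz
  ty <- sxy * w$nx + syy * w$ny + syz * w$nz
  tz <- sxz * w$nx + syz * w$ny + szz * w$nz
  tn <- tx * w$nx + ty * w$ny + tz * w$nz
  tx <- tx - tn * w$nx; ty <- ty - tn * w$ny; tz <- tz - tn * w$nz
  out <- w
  out$tau_pa <- drop(sqrt(tx^2 + ty^2 + tz^2)) * w$corr * state$Cp
  out
}

#' Poiseuille resistor-network solution of a tree (0D oracle)
#'
#' Independent lumped check for the 3D solver: every segment is a chain of
#' Hagen-Poiseuille resistances `8 mu L / (pi r^4)` split at branch
#' attachment points, outlets terminate in their assigned lumped resistances
#' to a common venous reference, and the linear network is solved for a
#' prescribed total inflow.
#'
#' @param tree A `vessel_tree`.
#' @param outlets Table from [assign_resistances()].
#' @param inflow Total inflow (m^3/s).
#' @param fluid A [fluid_config()].
#' @return Tibble of per-outlet flows (m^3/s and ml/s) plus inlet pressure.
#' @export
solve_network0d <- function(tree, outlets, inflow, fluid = fluid_config()) {
  nodes <- character(0)
  node_id <- function(nm) {
    i <- match(nm, nodes)
    if (is.na(i)) { nodes <<- c(nodes, nm); i <- length(nodes) }
    i
  }
  edges <- list()  # list of c(i, j, R)
  seg_node_at <- function(segid, s_mm) sprintf("%s@%.6f", segid, s_mm)
  # resistance of a segment between arclengths (trapezoid on 1/r^4)
  seg_R <- function(seg, s0, s1) {
    s <- arclengths(seg$points)
    ss <- sort(unique(c(s0, s1, s[s > s0 & s < s1])))
    rr <- approx(s, seg$radii, xout = ss, rule = 2)$y * 1e-3
    integ <- trapz(ss * 1e-3, 1 / rr^4)
    8 * fluid$mu / pi * integ
  }
  for (id in names(tree$segments)) {
    seg <- tree$segments[[id]]
    L <- max(arclengths(seg$points))
    kids <- Filter(function(o) identical(o$parent, id), tree$segments)
    cuts <- sort(unique(c(0, vapply(kids, function(k) k$parent_frac * L, 1), L)))
    for (i in seq_len(length(cuts) - 1)) {
      a <- node_id(seg_node_at(id, cuts[i]))
      b <- node_id(seg_node_at(id, cuts[i + 1]))
      edges[[length(edges) + 1]] <- c(a, b, seg_R(seg, cuts[i], cuts[i + 1]))
    }
  }
  # tie each child's proximal node to its parent's attachment node
  alias <- seq_along(nodes)
  for (id in names(tree$segments)) {
    seg <- tree$segments[[id]]
    if (is.na(seg$parent)) next
    par <- tree$segments[[seg$parent]]
    Lp <- max(arclengths(par$points))
    a <- node_id(seg_node_at(id, 0))
    b <- node_id(seg_node_at(seg$parent, seg$parent_frac * Lp))
    alias[a] <- b
  }
  resolve <- function(i) { while (alias[i] != i) i <- alias[i]; i }
  # outlet resistors to ground (node 0)
  outs <- tree_outlets(tree)
  onode <- integer(nrow(outs))
  for (k in seq_len(nrow(outs))) {
    seg <- tree$segments[[outs$segment[k]]]
    L <- max(arclengths(seg$points))
    onode[k] <- node_id(seg_node_at(outs$segment[k], L))
  }
  Rout <- outlets$resistance[match(outs$segment, outlets$segment)]
  n <- length(nodes)
  G <- matrix(0, n, n)
  addG <- function(i, j, R) {
    i <- resolve(i); j <- resolve(j)
    g <- 1 / R
    G[i, i] <<- G[i, i] + g
    G[j, j] <<- G[j, j] + g
    G[i, j] <<- G[i, j] - g
    G[j, i] <<- G[j, i] - g
  }
  for (e in edges) addG(e[1], e[2], e[3])
  for (k in seq_len(nrow(outs))) {
    i <- resolve(onode[k])
    G[i, i] <- G[i, i] + 1 / Rout[k]  # to ground
  }
  b <- numeric(n)
  root <- tree$segments[[tree$root]]
  b[resolve(node_id(seg_node_at(tree$root, 0)))] <- inflow
  live <- vapply(seq_len(n), function(i) resolve(i) == i, logical(1)) &
    (rowSums(abs(G)) > 0 | abs(b) > 0)
  p <- numeric(n)
  p[live] <- solve(G[live, live, drop = FALSE], b[live])
  q_out <- p[vapply(onode, resolve, 1L)] / Rout
  tibble(segment = outs$segment, q = q_out, q_mls = q_out * 1e6,
         p_inlet = p[resolve(node_id(seg_node_at(tree$root, 0)))])
}

#' Estimate the peak velocity in a tree from the lumped network
#'
#' Solves the Poiseuille resistor network ([solve_network0d()]) at the
#' prescribed mean inflow and returns a conservative estimate of the peak
#' velocity anywhere in the tree over the cardiac cycle: per segment, twice
#' the mean velocity at the narrowest cross-section carrying that segment's
#' flow, scaled by the waveform peak and a safety headroom.  Used to fix the
#' lattice time step tightly instead of a worst-case bound.
#'
#' @param tree A `vessel_tree`.
#' @param outlets Resistances from [assign_resistances()].
#' @param inlet An [inlet_spec()].
#' @param fluid A [fluid_config()].
#' @param headroom Multiplicative safety factor.
#' @return Peak velocity estimate (m/s).
#' @export
estimate_peak_velocity <- function(tree, outlets, inlet,
                                   fluid = fluid_config(),
                                   headroom = 1.25) {
  inl <- tree_inlet(tree)
  q_in <- inlet$v_mean * pi * (inl$radius * 1e-3)^2
  net <- solve_network0d(tree, outlets, q_in, fluid)
  # per-segment flow = sum of subtree outlet flows
  seg_flow <- function(id) {
    keep <- id
    repeat {
      more <- names(Filter(function(s) s$parent %in% keep, tree$segments))
      more <- setdiff(more, keep)
      if (length(more) == 0) break
      keep <- c(keep, more)
    }
    sum(net$q[net$segment %in% keep])
  }
  v <- vapply(names(tree$segments), function(id) {
    rmin <- min(tree$segments[[id]]$radii) * 1e-3
    seg_flow(id) / (pi * rmin^2)
  }, 1)
  2 * max(inlet$waveform$w) * headroom * max(v, inlet$v_mean)
}

#' Mesh-independence (resolution convergence) study
#'
#' Runs the same steady case at a decreasing sequence of voxel resolutions
#' and reports the relative change of the section-averaged wall shear
#' profile between successive resolutions, flagging convergence when the
#' change drops below `tol`.
#'
#' @param tree A `vessel_tree`.
#' @param resolutions Decreasing voxel spacings (mm).
#' @param inlet,outlets,fluid Simulation setup.
#' @param tol Convergence tolerance on the mean relative profile change.
#' @param ... Passed to [run_steady()].
#' @return A `convergence_report` tibble (one row per resolution).
#' @export
mesh_independence <- function(tree, resolutions, inlet, outlets,
                              fluid = fluid_config(), tol = 0.05, ...) {
  if (length(resolutions) < 2) abort("need at least 2 resolutions")
  mesh <- loft_mesh(tree)
  secs <- section_centerline(tree)
  profs <- list()
  rows <- list()
  prev <- NULL
  for (i in seq_along(resolutions)) {
    h <- resolutions[i]
    grid <- voxelize(mesh, h)
    st <- build_lattice(grid, fluid, inlet)
    res <- run_steady(st, inlet, outlets, ...)
    pr <- circumferential_average(res$wss, secs)
    key <- paste(pr$segment, pr$section)
    change <- NA_real_
    if (!is.null(prev)) {
      common <- intersect(key, prev$key)
      a <- pr$taess[match(common, key)]
      b <- prev$taess[match(common, prev$key)]
      ok <- is.finite(a) & is.finite(b)
      change <- mean(abs(a[ok] - b[ok])) / mean(abs(b[ok]))
    }
    rows[[i]] <- tibble(h = h, n_fluid = grid$n_fluid,
                        mean_taess = mean(pr$taess, na.rm = TRUE),
                        rel_change = change,
                        converged = is.finite(change) && change < tol)
    prev <- list(key = key, taess = pr$taess)
  }
  out <- bind_rows(rows)
  class(out) <- c("convergence_report", class(out))
  out
}
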