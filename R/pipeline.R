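#' Study run configuration
#'
#' Assembles the full configuration of a synthetic side-branch study:
#' tree morphology (desk-scale left-coronary defaults), stenosis, gantry,
#' projection noise, meshing/voxel resolutions, solver settings, outlet
#' resistance model, pruning specification for the matched model, and the
#' analysis thresholds.  A single `seed` governs every stochastic stage.
#' Configurations round-trip losslessly through YAML ([write_run_config()],
#' [read_run_config()]).
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    template = "left",
    tree = list(
      lm = list(length = 6, r0 = 1.15, r1 = 1.12),
      lad = list(length = 32, r0 = 1.0, r1 = 0.9),
      lcx = list(length = 22, r0 = 0.95, r1 = 0.8),
      n_diag = 2, n_om = 1,
      branch_length = c(9, 14), branch_r0 = c(0.95, 1.05),
      branch_taper = 0.92, branch_max_frac = 0.95,
      diag_span = c(0.2, 0.6), wiggle = 0.01
    ),
    stenosis = list(segment = "LAD", center_frac = 0.45, length = 5,
                    severity = 0.25),
    gantry = list(view1 = list(alpha = -30, beta = 0),
                  view2 = list(alpha = 40, beta = 20)),
    jitter = list(centerline_sd = 0, width_sd = 0),
    mesh_h = 0.12,
    voxel_h = 0.3,
    solver = list(mode = "steady", mach = 0.095, max_steps = 12000,
                  tol = 1e-4, n_cycles = 2, collision = "regularized"),
    resistances = list(mean_aortic_pressure = 90 * 133.322,
                       murray_exponent = 3),
    inlet = list(v_mean_steady = 0.25, v_mean_pulsatile = 0.28,
                 period = 0.8),
    prune = list(list(segment = "Diag2", action = "remove"),
                 list(segment = "OM1", action = "remove")),
    analysis = list(threshold = 0.5, bands = c(1, 2, 3), spacing = 0.3)
  )
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A `run_config`.
#' @param path Output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed),
                        cfg[setdiff(names(cfg), "seed")]))
}

# canonical JSON for deterministic checksums
canonical_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

#' Checksum of a study report file
#' @param path File path.
#' @return MD5 string.
#' @export
report_checksum <- function(path) unname(tools::md5sum(path))

# build the study tree from a config
config_tree <- function(config) {
  params <- config$tree
  params$stenoses <- list(do.call(stenosis_spec, config$stenosis))
  generate_tree(config$template, params, seed = config$seed)
}

config_inlet <- function(config) {
  if (config$solver$mode == "steady")
    inlet_spec("steady", v_mean = config$inlet$v_mean_steady,
               period = config$inlet$period)
  else
    inlet_spec("pulsatile", v_mean = config$inlet$v_mean_pulsatile,
               period = config$inlet$period)
}

# simulate one model (tree -> mesh -> grid -> flow -> section profile)
simulate_model <- function(tree, config, inlet, outlets = NULL) {
  mesh <- loft_mesh(tree, h = config$mesh_h)
  grid <- voxelize(mesh, config$voxel_h)
  outs <- outlets %||% assign_resistances(
    tree,
    mean_aortic_pressure = config$resistances$mean_aortic_pressure,
    total_mean_flow = pi * (tree_inlet(tree)$radius * 1e-3)^2 *
      inlet$v_mean,
    murray_exponent = config$resistances$murray_exponent)
  u_peak <- estimate_peak_velocity(tree, outs, inlet)
  state <- build_lattice(grid, fluid_config(), inlet,
                         mach = config$solver$mach, u_peak_est = u_peak)
  if (config$solver$mode == "steady") {
    res <- run_steady(state, inlet, outs,
                      max_steps = config$solver$max_steps,
                      tol = config$solver$tol, ramp_steps = 2500,
                      collision = config$solver$collision)
    wss_tab <- res$wss
    wss_tab$taess <- wss_tab$t1
  } else {
    res <- run_transient(state, inlet, outs,
                         n_cycles = config$solver$n_cycles,
                         collision = config$solver$collision)
    wss_tab <- taess(res$wss)
  }
  sections <- section_centerline(tree, spacing = config$analysis$spacing)
  profile <- suppressMessages(circumferential_average(wss_tab, sections))
  list(mesh = mesh, grid = grid, outlets = outs, result = res,
       wss = wss_tab, sections = sections, profile = profile)
}

#' Run the full synthetic side-branch study
#'
#' End-to-end pipeline: generate a synthetic stenosed coronary tree,
#' project it onto the biplane gantry, reconstruct the 3D tree from the
#' two views, loft and voxelize the reconstructed (complete) model, prune
#' it to the matched model, simulate both with identical inflow, and
#' reduce the two runs to section profiles, the point-to-point comparison,
#' shear-band strata, per-vessel outflow and the statistical tests.  All
#' intermediate artifacts are persisted under `out_dir` and the
#' consolidated report is written as canonical JSON whose checksum is
#' returned; the whole pipeline is deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return A `study_report` list (invisible components: paths, checksum).
#' @export
run_full_study <- function(config, out_dir = tempfile("coroflow_study")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(sprintf("stage '%s' failed: %s (artifacts in %s)", name,
                    conditionMessage(e), out_dir)))
  }
  truth <- stage("synth", config_tree(config))
  write_tree(truth, file.path(out_dir, "tree_truth.json"))
  gantry <- stage("gantry", do.call(gantry_geometry, config$gantry))
  projs <- stage("project", project_tree(truth, gantry))
  if (config$jitter$centerline_sd > 0 || config$jitter$width_sd > 0) {
    projs <- lapply(seq_along(projs), function(k)
      degrade_projection(projs[[k]], config$jitter$centerline_sd,
                         config$jitter$width_sd,
                         seed = config$seed + k))
  }
  write_projection(projs[[1]], file.path(out_dir, "view1.json"))
  write_projection(projs[[2]], file.path(out_dir, "view2.json"))
  ccm_tree <- stage("reconstruct",
                    reconstruct_tree(projs[[1]], projs[[2]], gantry))
  recon_rep <- evaluate_reconstruction(ccm_tree, truth)
  write_tree(ccm_tree, file.path(out_dir, "tree_ccm.json"))
  mcm_tree <- stage("prune", prune_tree(ccm_tree, config$prune))
  write_tree(mcm_tree, file.path(out_dir, "tree_mcm.json"))
  inlet <- config_inlet(config)
  ccm <- stage("simulate_ccm", simulate_model(ccm_tree, config, inlet))
  mcm <- stage("simulate_mcm", simulate_model(mcm_tree, config, inlet))
  write_stl(ccm$mesh, file.path(out_dir, "ccm.stl"))
  write_stl(mcm$mesh, file.path(out_dir, "mcm.stl"))
  hd <- hausdorff_distance(ccm$mesh, mcm$mesh, n_samples = 4000,
                           seed = config$seed)
  cmp <- stage("analyze", compare_point_to_point(
    ccm$profile, mcm$profile, threshold = config$analysis$threshold))
  strata <- stratify(cmp, breaks = config$analysis$bands)
  out_ccm <- outflow_report(ccm$result$flows, ccm_tree,
                            period = config$inlet$period)
  out_mcm <- outflow_report(mcm$result$flows, mcm_tree,
                            period = config$inlet$period)
  st <- stats_suite(
    bind_rows(tibble(model = "CCM", taess = cmp$pairs$ccm),
              tibble(model = "MCM", taess = cmp$pairs$mcm)),
    value = "taess", group = "model")
  write.csv(cmp$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  write.csv(as.data.frame(strata), file.path(out_dir, "strata.csv"),
            row.names = FALSE)
  report <- list(
    config_seed = config$seed,
    reconstruction = list(mean_rmse_mm = mean(recon_rep$rmse),
                          mean_diameter_mae_mm = mean(recon_rep$diameter_mae)),
    hausdorff_ccm_mcm_mm = as.numeric(hd),
    n_sections_compared = nrow(cmp$pairs),
    n_sections_excluded = nrow(cmp$excluded),
    frac_above_threshold = cmp$frac_above,
    strata = as.data.frame(strata),
    outflow = list(
      ccm_total_mls = attr(out_ccm, "total_mls"),
      mcm_total_mls = attr(out_mcm, "total_mls"),
      ccm_per_vessel = as.data.frame(attr(out_ccm, "per_vessel")),
      mcm_per_vessel = as.data.frame(attr(out_mcm, "per_vessel"))),
    stats = as.data.frame(st$test)
  )
  report_path <- file.path(out_dir, "report.json")
  canonical_json(report, report_path)
  structure(list(
    truth = truth, ccm_tree = ccm_tree, mcm_tree = mcm_tree,
    reconstruction = recon_rep, comparison = cmp, strata = strata,
    outflow_ccm = out_ccm, outflow_mcm = out_mcm, stats = st,
    hausdorff = hd, report = report, out_dir = out_dir,
    checksum = report_checksum(report_path)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d matched sections, %.1f%% above %.2g Pa; outflow CCM %.2f / MCM %.2f ml/s\n",
    x$report$n_sections_compared, 100 * x$report$frac_above_threshold,
    x$comparison$threshold, x$report$outflow$ccm_total_mls,
    x$report$outflow$mcm_total_mls))
  invisible(x)
}

#' Extract a subtree rooted at a segment
#'
#' The segment becomes the new root (its parent link is dropped); all its
#' descendants are retained with geometry unchanged.
#'
#' @param tree A `vessel_tree`.
#' @param root_segment Segment id of the new root.
#' @export
extract_subtree <- function(tree, root_segment) {
  if (is.null(tree$segments[[root_segment]]))
    abort(sprintf("no segment '%s'", root_segment))
  keep <- root_segment
  repeat {
    more <- names(Filter(function(s) s$parent %in% keep, tree$segments))
    more <- setdiff(more, keep)
    if (length(more) == 0) break
    keep <- c(keep, more)
  }
  segs <- tree$segments[keep]
  segs[[root_segment]]$parent <- NA_character_
  segs[[root_segment]]$parent_frac <- NA_real_
  stens <- Filter(function(st) st$segment %in% keep, tree$stenoses)
  new_vessel_tree(segs, root_segment, stens)
}

#' Canonical configuration of the side-branch ablation experiment
#'
#' The study conditions of the desk-scale branch-removal experiment: a
#' left-coronary tree whose three diagonals are wide enough to carry the
#' dominant share of LAD flow (tip diameters comparable to the strongly
#' tapered distal LAD), a moderate (35% diameter) mid-LAD stenosis, 0.3 mm
#' voxels, and two pulsatile cycles per submodel.  Kept in one place so the
#' test-suite and analysis scripts run the identical experiment.
#'
#' @param seed Master seed.
#' @export
ablation_config <- function(seed = 1) {
  run_config(
    seed = seed,
    tree = list(
      lm = list(length = 6, r0 = 1.15, r1 = 1.12),
      lad = list(length = 36, r0 = 1.0, r1 = 0.97),
      lcx = list(length = 20, r0 = 0.95, r1 = 0.8),
      n_diag = 3, n_om = 1,
      branch_length = c(8, 12), branch_r0 = c(1.05, 1.15),
      branch_taper = 0.95, branch_max_frac = 1.0,
      diag_span = c(0.14, 0.32), om_span = c(0.3, 0.6),
      wiggle = 0.01
    ),
    stenosis = list(segment = "LAD", center_frac = 0.5, length = 5,
                    severity = 0.15),
    voxel_h = 0.28,
    solver = list(mode = "steady", mach = 0.095, max_steps = 15000,
                  tol = 2e-4, n_cycles = 2, collision = "regularized")
  )
}

#' Side-branch ablation experiment on the LAD
#'
#' Reproduces the branch-removal study design at desk scale: the full
#' left-coronary tree is simulated once (steady, cycle-mean inflow) to
#' measure the flow entering the LAD; the LAD subtree is then extracted
#' and simulated as a standalone model with `k = n, .., 0` diagonal
#' branches, the inlet flow of every submodel matched to the LAD inflow of
#' the full model.  As branches are removed, the matched inflow is forced
#' through the trunk, raising trunk shear.
#'
#' @param config A [run_config()]; its tree must carry at least
#'   `k_values` diagonals.
#' @param k_values Numbers of diagonals to retain (descending).
#' @param transient Use pulsatile submodel runs (default) or steady.
#' @return An `ablation_report` tibble: one row per `k` with the
#'   trunk-averaged TAESS (Pa) and the LAD terminal outflow (ml/s); the
#'   parent-model LAD inflow is attached as an attribute.
#' @export
run_lad_ablation <- function(config, k_values = NULL, transient = TRUE) {
  stopifnot(inherits(config, "run_config"))
  n_diag <- config$tree$n_diag
  k_values <- k_values %||% rev(seq(0, n_diag))
  truth <- config_tree(config)
  inlet_full <- inlet_spec("steady", v_mean = config$inlet$v_mean_steady,
                           period = config$inlet$period)
  full <- simulate_model(truth, config, inlet_full)
  # LAD inflow of the full model = outflow of the LAD subtree outlets
  lad_ids <- names(extract_subtree(truth, "LAD")$segments)
  fl <- full$result$flows
  q_lad <- sum(vapply(split(fl$q, fl$segment)[
    intersect(unique(fl$segment), lad_ids)],
    function(x) mean(tail(x, 5)), 1))
  lad_full <- extract_subtree(truth, "LAD")
  r_ost <- lad_full$segments[["LAD"]]$radii[1]
  v_match <- q_lad * 1e-6 / (pi * (r_ost * 1e-3)^2)
  # outlet resistances are assigned once on the full submodel and inherited
  # by every pruned variant: pruning removes branches, not the
  # microcirculation downstream of the branches that remain -- and with
  # fixed per-outlet resistances the trunk flow is pointwise non-decreasing
  # under branch removal
  outs_full <- assign_resistances(
    lad_full,
    mean_aortic_pressure = config$resistances$mean_aortic_pressure,
    total_mean_flow = pi * (r_ost * 1e-3)^2 * v_match,
    murray_exponent = config$resistances$murray_exponent)
  rows <- list()
  for (k in k_values) {
    # remove proximal diagonals first (keep the k most distal ones)
    drop <- if (k < n_diag)
      lapply(seq_len(n_diag - k), function(i)
        list(segment = paste0("Diag", i), action = "remove"))
    else list()
    sub <- prune_tree(lad_full, drop)
    sub_cfg <- config
    sub_cfg$solver$mode <- if (transient) "pulsatile" else "steady"
    inlet_k <- inlet_spec(if (transient) "pulsatile" else "steady",
                          v_mean = v_match, period = config$inlet$period)
    outs_k <- outs_full[outs_full$segment %in% names(sub$segments), ]
    sim <- simulate_model(sub, sub_cfg, inlet_k, outlets = outs_k)
    trunk <- sim$profile[sim$profile$segment == "LAD" & !sim$profile$empty, ]
    orep <- outflow_report(sim$result$flows, sub,
                           period = config$inlet$period)
    out_lad <- orep$q_mls[orep$segment == "LAD"]
    rows[[as.character(k)]] <- tibble(
      k = k, trunk_taess = mean(trunk$taess),
      trunk_sections = nrow(trunk), lad_outflow_mls = out_lad,
      periodicity = sim$result$periodicity %||% NA_real_)
  }
  out <- bind_rows(rows)
  attr(out, "lad_inflow_mls") <- q_lad
  attr(out, "v_match") <- v_match
  class(out) <- c("ablation_report", class(out))
  out
}

#' Matched-vs-unmatched Hausdorff discrimination matrix
#'
#' Generates `n` synthetic trees, produces a perturbed, pruned copy of
#' each (the stand-in for a second-modality reconstruction of the same
#' anatomy), and computes the full symmetric Hausdorff distance matrix
#' between all originals and all copies.  Correct identification shows up
#' as the matrix minimum of each row lying on the diagonal.
#'
#' @param n Number of trees (>= 3).
#' @param seed Master seed.
#' @param perturb_sd Smooth centerline perturbation amplitude (mm).
#' @param params Tree parameter overrides passed to [generate_tree()].
#' @param mesh_h Lofting resolution (mm).
#' @param n_samples Hausdorff sample count.
#' @return An `hd_matrix` object: the distance matrix and the fraction of
#'   rows whose minimum is on the diagonal.
#' @export
run_hd_matrix <- function(n = 5, seed = 1, perturb_sd = 0.3,
                          params = list(), mesh_h = 0.15,
                          n_samples = 3000) {
  if (n < 3) abort("need at least 3 trees")
  trees <- lapply(seq_len(n), function(i)
    generate_tree("left", params, seed = seed + i))
  copies <- lapply(seq_len(n), function(i) {
    # redraw the perturbation if it makes segments collide
    for (attempt in 0:25) {
      cand <- perturb_tree(trees[[i]], sd = perturb_sd,
                           seed = seed + 100 + i + 1000 * attempt)
      ok <- tryCatch({
        coroflow:::check_self_intersection(cand)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(cand)
    }
    abort("could not perturb tree without self-intersection")
  })
  meshes_a <- lapply(trees, loft_mesh, h = mesh_h)
  meshes_b <- lapply(copies, loft_mesh, h = mesh_h)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- hausdorff_distance(meshes_a[[i]], meshes_b[[j]],
                                  n_samples = n_samples,
                                  seed = seed + 17 * i + j)
  }
  diag_frac <- mean(apply(D, 1, which.min) == seq_len(n))
  structure(list(matrix = D, diagonal_fraction = diag_frac,
                 perturb_sd = perturb_sd),
            class = "hd_matrix")
}

#' @export
print.hd_matrix <- function(x, ...) {
  cat(sprintf(
    "<hd_matrix> %d x %d; diagonal-minimum fraction %.2f\n",
    nrow(x$matrix), ncol(x$matrix), x$diagonal_fraction))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Smoothly perturb a tree's centerlines
#'
#' Adds a low-frequency random displacement to every segment centerline
#' (preserving topology and radii), emulating the geometric differences
#' between reconstructions of the same anatomy from different modalities.
#'
#' @param tree A `vessel_tree`.
#' @param sd Displacement amplitude (mm).
#' @param seed Seed.
#' @export
perturb_tree <- function(tree, sd = 0.3, seed = 1) {
  with_seed(seed, {
    for (id in names(tree$segments)) {
      seg <- tree$segments[[id]]
      n <- nrow(seg$points)
      s <- arclengths(seg$points)
      L <- max(s)
      for (d in 1:3) {
        amp <- rnorm(2, sd = sd)
        ph <- runif(2, 0, 2 * pi)
        seg$points[, d] <- seg$points[, d] +
          amp[1] * sin(pi * s / L + ph[1]) / 2 +
          amp[2] * sin(2 * pi * s / L + ph[2]) / 2
      }
      tree$segments[[id]] <- seg
    }
    tree
  })
}
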