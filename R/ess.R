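#' Time-averaged endothelial shear stress
#'
#' Reduces a transient wall shear stress recording to TAESS: at each wall
#' sample, the time average of the tangential traction magnitude over one
#' cardiac cycle (trapezoidal in time, treating the recording as periodic).
#'
#' @param wss Wide WSS table from [run_transient()] (snapshot columns
#'   `t1..tk`, snapshot times and period as attributes) or a steady result's
#'   `wss` table.
#' @param period Cardiac period (s); defaults to the table's attribute.
#' @return The wall-sample table with a `taess` column (Pa).
#' @export
taess <- function(wss, period = NULL) {
  tcols <- grep("^t[0-9]+$", names(wss), value = TRUE)
  if (length(tcols) == 0) abort("no snapshot columns in WSS table")
  M <- as.matrix(wss[, tcols])
  times <- attr(wss, "times")
  period <- period %||% attr(wss, "period")
  out <- wss[, setdiff(names(wss), tcols)]
  if (length(tcols) == 1) {
    out$taess <- unname(M[, 1])
    return(out)
  }
  if (is.null(times) || is.null(period))
    abort("snapshot times and period are required for time averaging")
  span <- max(times) - min(times)
  dt <- span / (length(times) - 1)
  if (abs(span - period) > 2.5 * dt)
    abort(sprintf(
      "WSS samples span %.4g s, not one full cycle of %.4g s", span, period))
  tw <- c(times, min(times) + period)
  Mw <- cbind(M, M[, 1])
  dvec <- diff(tw)
  wts <- c(dvec / 2, 0) + c(0, dvec / 2)
  out$taess <- unname(drop(Mw %*% wts)) / period
  out
}

#' Circumferentially averaged shear profile
#'
#' Assigns every wall sample to its nearest 0.3 mm centerline section (by
#' the sample's arclength on its owning segment) and averages within each
#' section, producing the per-section profile on which all model-to-model
#' comparisons operate.  Sections that receive no samples are flagged empty
#' rather than dropped.
#'
#' @param samples Wall-sample table carrying `segment`, `arclength` and a
#'   `taess` (or `tau_pa`) column.
#' @param sections Output of [section_centerline()].
#' @param value Name of the value column to average.
#' @return A `section_profile` tibble: `segment`, `section`, `arclength`,
#'   `taess`, `n_samples`, `empty`.
#' @export
circumferential_average <- function(samples, sections, value = NULL) {
  value <- value %||% if ("taess" %in% names(samples)) "taess" else "tau_pa"
  spacing <- attr(sections, "spacing") %||% 0.3
  smax <- stats::aggregate(section ~ segment, data = sections, FUN = max)
  s <- samples
  s$section <- round(s$arclength / spacing)
  s$section <- pmin(s$section, smax$section[match(s$segment, smax$segment)])
  s <- s[!is.na(s$section), ]
  agg <- s |>
    group_by(.data$segment, .data$section) |>
    summarise(taess = mean(.data[[value]]), n_samples = n(),
              .groups = "drop")
  out <- sections |>
    select("segment", "section", "arclength") |>
    left_join(agg, by = c("segment", "section")) |>
    mutate(n_samples = ifelse(is.na(.data$n_samples), 0L, .data$n_samples),
           empty = .data$n_samples == 0L)
  n_empty <- sum(out$empty)
  if (n_empty > 0)
    inform(sprintf("%d of %d sections received no wall samples", n_empty,
                   nrow(out)))
  attr(out, "spacing") <- spacing
  class(out) <- c("section_profile", class(out))
  out
}

# parallel-transported frames along a resampled centerline
transport_frames <- function(pts) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[pmin(3:(n + 1), n), , drop = FALSE] -
                   pts[pmax(1:(n - 1), 1), , drop = FALSE]))
  tang <- tang / sqrt(rowSums(tang^2))
  e <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e[1, ] <- unitize(pracma_cross(tang[1, ], ref))
  for (i in 2:n) {
    v <- e[i - 1, ] - sum(e[i - 1, ] * tang[i, ]) * tang[i, ]
    e[i, ] <- unitize(v)
  }
  b <- cbind(tang[, 2] * e[, 3] - tang[, 3] * e[, 2],
             tang[, 3] * e[, 1] - tang[, 1] * e[, 3],
             tang[, 1] * e[, 2] - tang[, 2] * e[, 1])
  list(tangent = tang, e = e, b = b)
}

#' 2D cylindrical shear map of a single vessel
#'
#' Unrolls the wall of one (tubular) segment into an arclength-by-angle
#' image: each wall sample is binned by its centerline arclength and by its
#' circumferential angle about the local tangent, with the angular reference
#' parallel-transported continuously along the centerline.  Empty bins are
#' filled by circular interpolation along the angle and flagged.
#'
#' @param samples Wall-sample table with `segment`, `arclength`, positions
#'   `x,y,z` and a `taess`/`tau_pa` column.
#' @param tree The `vessel_tree` owning the samples.
#' @param segment Segment id to map.
#' @param spacing Arclength bin size (mm).
#' @param n_theta Angular bins.
#' @param value Value column name.
#' @return A `cylindrical_map` with `values` (rows = arclength), `empty`
#'   mask, bin centers.
#' @export
cylindrical_map <- function(samples, tree, segment, spacing = 0.3,
                            n_theta = 24, value = NULL) {
  value <- value %||% if ("taess" %in% names(samples)) "taess" else "tau_pa"
  seg <- tree$segments[[segment]]
  if (is.null(seg)) abort(sprintf("no segment '%s'", segment))
  L <- max(arclengths(seg$points))
  sgrid <- seq(0, floor(L / spacing) * spacing, by = spacing)
  cl <- interp_polyline(seg$points, sgrid)
  fr <- transport_frames(cl)
  sm <- samples[samples$segment == segment, ]
  if (nrow(sm) == 0) abort("no samples on this segment")
  si <- pmin(pmax(round(sm$arclength / spacing), 0), length(sgrid) - 1) + 1
  d <- cbind(sm$x, sm$y, sm$z) - cl[si, , drop = FALSE]
  theta <- atan2(rowSums(d * fr$b[si, , drop = FALSE]),
                 rowSums(d * fr$e[si, , drop = FALSE]))
  ti <- floor((theta + pi) / (2 * pi) * n_theta) + 1
  ti[ti > n_theta] <- n_theta
  vals <- matrix(NA_real_, length(sgrid), n_theta)
  cnt <- matrix(0L, length(sgrid), n_theta)
  for (i in seq_len(nrow(sm))) {
    r <- si[i]; c0 <- ti[i]
    if (is.na(vals[r, c0])) vals[r, c0] <- 0
    vals[r, c0] <- vals[r, c0] + sm[[value]][i]
    cnt[r, c0] <- cnt[r, c0] + 1L
  }
  vals <- vals / ifelse(cnt > 0, cnt, NA)
  empty <- cnt == 0L
  for (r in seq_len(nrow(vals))) {
    row <- vals[r, ]
    if (all(is.na(row)) || !anyNA(row)) next
    idx <- which(!is.na(row))
    xi <- c(idx - n_theta, idx, idx + n_theta)
    yi <- rep(row[idx], 3)
    nai <- which(is.na(row))
    vals[r, nai] <- approx(xi, yi, xout = nai, rule = 2)$y
  }
  structure(list(values = vals, empty = empty,
                 arclength = sgrid,
                 theta = seq(-pi + pi / n_theta, pi - pi / n_theta,
                             length.out = n_theta),
                 segment = segment),
            class = "cylindrical_map")
}

#' @export
print.cylindrical_map <- function(x, ...) {
  cat(sprintf("<cylindrical_map> %s: %d x %d bins, %.0f%% filled directly\n",
              x$segment, nrow(x$values), ncol(x$values),
              100 * mean(!x$empty)))
  invisible(x)
}

#' Point-to-point comparison of complete vs matched model profiles
#'
#' Matches sections between a complete coronary model (CCM) and a matched
#' (pruned) coronary model (MCM) by segment label and section index -- the
#' two models share centerlines exactly after pruning, which is what makes
#' a direct per-section comparison meaningful.  Sections on branches absent
#' from the MCM are excluded and listed, and the fraction of matched pairs
#' whose absolute TAESS difference exceeds `threshold` is reported.
#'
#' @param ccm,mcm `section_profile` tables for the two models.
#' @param threshold Difference threshold (Pa), default 0.5.
#' @return A `pair_comparison`: `$pairs` (matched sections with `delta`),
#'   `$excluded` (with reasons), `$frac_above`.
#' @export
compare_point_to_point <- function(ccm, mcm, threshold = 0.5) {
  key <- c("segment", "section")
  cc <- ccm |> select(all_of(key), "arclength", ccm = "taess",
                      ccm_empty = "empty")
  mm <- mcm |> select(all_of(key), mcm = "taess", mcm_empty = "empty")
  pairs <- inner_join(cc, mm, by = key)
  excl_branch <- anti_join(cc, mm, by = key) |>
    mutate(reason = "absent in MCM") |> select(all_of(key), "reason")
  excl_empty <- pairs |>
    filter(.data$ccm_empty | .data$mcm_empty) |>
    mutate(reason = "empty section") |> select(all_of(key), "reason")
  pairs <- pairs |>
    filter(!.data$ccm_empty & !.data$mcm_empty) |>
    mutate(delta = .data$ccm - .data$mcm) |>
    select(all_of(key), "arclength", "ccm", "mcm", "delta")
  if (nrow(pairs) == 0) abort("no common non-empty sections to compare")
  res <- structure(list(
    pairs = pairs,
    excluded = bind_rows(excl_branch, excl_empty),
    threshold = threshold,
    frac_above = mean(abs(pairs$delta) > threshold)
  ), class = "pair_comparison")
  res
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf(
    "<pair_comparison> %d matched sections (%d excluded); %.1f%% differ by > %.2g Pa\n",
    nrow(x$pairs), nrow(x$excluded), 100 * x$frac_above, x$threshold))
  invisible(x)
}

#' Stratify sections into shear bands
#'
#' Classifies per-section TAESS into the four atherosclerosis-relevant
#' bands: low (< 1 Pa), intermediate (1 to < 2 Pa), high (2 to < 3 Pa) and
#' very high (>= 3 Pa).  Values falling exactly on a boundary go to the
#' higher band (configurable via `breaks`).  For a pair comparison, both
#' models are stratified and the mean CCM-minus-MCM difference is reported
#' per CCM band.
#'
#' @param x A `pair_comparison` or `section_profile`.
#' @param breaks Interior band boundaries (Pa).
#' @return A `strata_report` tibble (`model`, `band`, `n`, `fraction`);
#'   for pairs, per-band mean differences as attribute `"band_delta"`.
#' @export
stratify <- function(x, breaks = c(1, 2, 3)) {
  labs <- c("low", "intermediate", "high", "very_high")
  band_of <- function(v) cut(v, c(-Inf, breaks, Inf), labels = labs,
                             right = FALSE)
  if (inherits(x, "pair_comparison")) {
    p <- x$pairs
    res <- bind_rows(
      tibble(model = "CCM", band = band_of(p$ccm)),
      tibble(model = "MCM", band = band_of(p$mcm))
    ) |>
      group_by(.data$model, .data$band, .drop = FALSE) |>
      summarise(n = n(), .groups = "drop_last") |>
      mutate(fraction = .data$n / sum(.data$n)) |> ungroup()
    bd <- tibble(band = band_of(p$ccm), delta = p$delta) |>
      group_by(.data$band, .drop = FALSE) |>
      summarise(mean_delta = mean(.data$delta), n = n(), .groups = "drop")
    attr(res, "band_delta") <- bd
  } else {
    v <- x$taess[!x$empty]
    res <- tibble(model = "model", band = band_of(v)) |>
      group_by(.data$model, .data$band, .drop = FALSE) |>
      summarise(n = n(), .groups = "drop") |>
      mutate(fraction = .data$n / sum(.data$n))
  }
  class(res) <- c("strata_report", class(res))
  res
}

#' Per-vessel volumetric outflow report
#'
#' Time-mean volumetric flow (ml/s) at the end of each terminal vessel over
#' an averaging window (by default the final cardiac cycle of the series),
#' grouped into the major vessels (LAD, LCx, RCA) by walking each outlet's
#' ancestry.
#'
#' @param flows Outlet flow series from a `flow_result` (`segment`, `t`,
#'   `q` in ml/s; inflow series attached).
#' @param tree The simulated `vessel_tree`.
#' @param window Optional `c(tmin, tmax)` averaging window (s).
#' @param period If given and `window` is NULL, average over the final
#'   period of the series.
#' @return An `outflow_report` tibble per outlet; per-vessel and total
#'   summaries plus the conservation error as attributes.
#' @export
outflow_report <- function(flows, tree, window = NULL, period = NULL) {
  if (!all(flows$segment %in% names(tree$segments)))
    abort("flow series contains outlets not labelled in the tree")
  main <- c("LAD", "LCx", "RCA")
  vessel_of <- function(id) {
    cur <- id
    while (!cur %in% main) {
      p <- tree$segments[[cur]]$parent
      if (is.na(p)) return(id)
      cur <- p
    }
    cur
  }
  if (is.null(window)) {
    tmax <- max(flows$t)
    window <- c(if (!is.null(period)) tmax - period else min(flows$t), tmax)
  }
  fl <- flows |> filter(.data$t >= window[1] - 1e-12,
                        .data$t <= window[2] + 1e-12)
  out <- fl |>
    group_by(.data$segment) |>
    summarise(q_mls = mean(.data$q), .groups = "drop") |>
    mutate(vessel = vapply(.data$segment, vessel_of, ""))
  per_vessel <- out |>
    group_by(.data$vessel) |>
    summarise(q_mls = sum(.data$q_mls), .groups = "drop")
  total <- sum(out$q_mls)
  inflow <- attr(flows, "inflow")
  cons <- NA_real_
  if (!is.null(inflow)) {
    qin <- mean(inflow$q[inflow$t >= window[1] - 1e-12 &
                           inflow$t <= window[2] + 1e-12])
    cons <- abs(total - qin) / abs(qin)
    attr(out, "inflow_mls") <- qin
  }
  attr(out, "per_vessel") <- per_vessel
  attr(out, "total_mls") <- total
  attr(out, "conservation_error") <- cons
  class(out) <- c("outflow_report", class(out))
  out
}

#' Statistical test suite for grouped section values
#'
#' Runs the reporting pipeline used for grouped shear comparisons: a
#' Kolmogorov-Smirnov normality check per group, mean and standard error
#' summaries, then a two-tailed Student t test for two groups, a
#' Kruskal-Wallis test for three or more unpaired groups, or a Friedman
#' test for three or more paired groups (requires complete blocks).
#' Significance is declared at p < 0.05.
#'
#' @param data Long data frame of observations.
#' @param value,group Column names (strings) of the value and grouping
#'   variables.
#' @param block Optional column name of the pairing/block variable
#'   (switches >= 3 groups from Kruskal-Wallis to Friedman).
#' @param alpha Significance level.
#' @return A `stats_report` list: `$summary`, `$normality`, `$test`.
#' @export
stats_suite <- function(data, value, group, block = NULL, alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("each group needs at least two observations")
  summ <- tibble(group = levels(g),
                 n = as.integer(table(g)),
                 mean = as.numeric(tapply(v, g, mean)),
                 sem = as.numeric(tapply(v, g, function(x)
                   sd(x) / sqrt(length(x)))))
  norm <- bind_rows(lapply(levels(g), function(lv) {
    x <- v[g == lv]
    suppressWarnings(
      ks <- stats::ks.test(x, "pnorm", mean = mean(x), sd = sd(x)))
    tibble(group = lv, statistic = unname(ks$statistic),
           p_value = ks$p.value, normal = ks$p.value >= alpha)
  }))
  if (nlevels(g) == 2) {
    tt <- stats::t.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
                        alternative = "two.sided", var.equal = FALSE)
    test <- tibble(test = "Student t (two-tailed, Welch)",
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  } else if (is.null(block)) {
    kw <- stats::kruskal.test(v, g)
    test <- tibble(test = "Kruskal-Wallis",
                   statistic = unname(kw$statistic), p_value = kw$p.value)
  } else {
    b <- factor(data[[block]])
    if (any(table(g, b) != 1))
      abort("Friedman test requires exactly one observation per group in every block")
    fr <- stats::friedman.test(v, g, b)
    test <- tibble(test = "Friedman", statistic = unname(fr$statistic),
                   p_value = fr$p.value)
  }
  test$significant <- test$p_value < alpha
  structure(list(summary = summ, normality = norm, test = test,
                 alpha = alpha), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s: statistic %.4g, p = %.3g (%ssignificant at %.2g)\n",
              x$test$test, x$test$statistic, x$test$p_value,
              if (x$test$significant) "" else "not ", x$alpha))
  invisible(x)
}
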