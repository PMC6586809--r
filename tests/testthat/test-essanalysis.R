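# build a synthetic WSS recording: wide table with snapshot columns
fake_wss <- function(tau_fun, times, period, n_samples = 5,
                     segment = "T", arclength = NULL) {
  M <- t(vapply(seq_len(n_samples), function(i) tau_fun(times, i),
                numeric(length(times))))
  tab <- tibble::tibble(
    segment = segment,
    arclength = arclength %||% seq(0, 1, length.out = n_samples),
    x = 0, y = 0, z = 0)
  tab <- cbind(tab, setNames(as.data.frame(M),
                             paste0("t", seq_along(times))))
  attr(tab, "times") <- times
  attr(tab, "period") <- period
  tibble::as_tibble(tab)
}

test_that("TAESS time averaging matches closed forms", {
  times <- seq(0, 0.8, length.out = 201)[-201]
  # constant 2 Pa -> TAESS 2
  w1 <- fake_wss(function(t, i) rep(2, length(t)), times, 0.8)
  expect_equal(taess(w1)$taess, rep(2, 5))
  # A|sin(2 pi t/T)| -> 2A/pi (trapezoid on 200 points, wrap-around)
  A <- 3.7
  w2 <- fake_wss(function(t, i) A * abs(sin(2 * pi * t / 0.8)), times, 0.8)
  expect_equal(taess(w2)$taess, rep(2 * A / pi, 5), tolerance = 1e-3)
  # invariant to a time-origin shift of the periodic signal
  w3 <- fake_wss(function(t, i) A * abs(sin(2 * pi * (t + 0.17) / 0.8)),
                 times, 0.8)
  expect_equal(taess(w3)$taess, taess(w2)$taess, tolerance = 1e-3)
  # incomplete cycle rejected
  w4 <- fake_wss(function(t, i) rep(1, length(t)), times[1:80], 0.8)
  attr(w4, "times") <- times[1:80]
  expect_error(taess(w4), "full cycle")
})

test_that("circumferential averaging partitions samples exactly", {
  tr <- tube_tree(length = 9, radius = 1)
  secs <- section_centerline(tr, spacing = 0.3)
  set.seed(1)
  n <- 500
  samples <- tibble::tibble(
    segment = "T", arclength = runif(n, 0, 9),
    x = 0, y = 0, z = 0, taess = 1.5)
  pr <- suppressMessages(circumferential_average(samples, secs))
  expect_equal(sum(pr$n_samples), n)          # samples partition
  expect_true(all(pr$taess[!pr$empty] == 1.5))  # constants preserved
  expect_s3_class(pr, "section_profile")
})

test_that("cylindrical map places a hot spot in the hand-computed bin", {
  tr <- tube_tree(length = 9, radius = 1)
  # samples on the tube surface at known angles about the +x axis
  set.seed(2)
  n <- 400
  s <- runif(n, 0, 9)
  th <- runif(n, -pi, pi)
  # transported frame of a straight +x tube: e = (0,-1,0), b = (0,0,-1)
  # => a point (s, cos a, sin a) has map angle atan2(-sin a, -cos a)
  samples <- tibble::tibble(
    segment = "T", arclength = s,
    x = s, y = cos(th), z = sin(th),
    taess = 1)
  hot_s <- 4.65; hot_a <- 1.0
  samples$x[1] <- hot_s; samples$y[1] <- cos(hot_a); samples$z[1] <- sin(hot_a)
  samples$arclength[1] <- hot_s
  samples$taess[1] <- 50
  cm <- cylindrical_map(samples, tr, "T", spacing = 0.3, n_theta = 12)
  # expected bin, computed by hand from the frame definition
  row <- round(hot_s / 0.3) + 1
  ang <- atan2(-sin(hot_a), -cos(hot_a))
  col <- min(floor((ang + pi) / (2 * pi) * 12) + 1, 12)
  expect_equal(unname(which(cm$values == max(cm$values), arr.ind = TRUE)[1, ]),
               c(row, col))
  # map mean of directly filled bins equals the sample mean within binning
  expect_equal(mean(cm$values[!cm$empty]), mean(samples$taess),
               tolerance = 0.15)
  # axisymmetric field gives near-constant rows
  samples$taess <- 2
  cm2 <- cylindrical_map(samples, tr, "T", spacing = 0.3, n_theta = 12)
  expect_true(all(abs(cm2$values[!apply(cm2$empty, 1, all), ] - 2) < 1e-9,
                  na.rm = TRUE))
})

test_that("point-to-point comparison equals brute-force enumeration", {
  mk_profile <- function(vals, segment = "T") {
    n <- length(vals)
    structure(tibble::tibble(
      segment = segment, section = seq_len(n) - 1L,
      arclength = (seq_len(n) - 1) * 0.3,
      taess = vals, n_samples = 10L, empty = FALSE),
      class = c("section_profile", class(tibble::tibble())),
      spacing = 0.3)
  }
  # identity: nothing above any positive threshold
  p <- mk_profile(runif(50, 0, 4))
  same <- compare_point_to_point(p, p, threshold = 0.5)
  expect_equal(same$frac_above, 0)
  # uniform +1 Pa offset: all pairs above 0.5 Pa
  q <- mk_profile(p$taess + 1)
  shifted <- compare_point_to_point(q, p, threshold = 0.5)
  expect_equal(shifted$frac_above, 1)
  expect_equal(shifted$pairs$delta, rep(1, 50))
  # randomized profiles match direct enumeration exactly, many seeds
  for (s in 1:25) {
    set.seed(s)
    a <- mk_profile(runif(200, 0, 5))
    b <- mk_profile(pmax(a$taess + rnorm(200, 0, 0.6), 0))
    cmp <- compare_point_to_point(a, b, threshold = 0.5)
    brute <- sum(abs(a$taess - b$taess) > 0.5) / 200
    expect_identical(cmp$frac_above, brute)
  }
  # CCM-only sections are excluded and listed
  a2 <- mk_profile(runif(60, 0, 4))
  b2 <- mk_profile(runif(40, 0, 4))
  cmp2 <- compare_point_to_point(a2, b2)
  expect_equal(nrow(cmp2$pairs), 40)
  expect_equal(nrow(cmp2$excluded), 20)
  expect_true(all(cmp2$excluded$reason == "absent in MCM"))
})

test_that("strata fractions follow the band definitions", {
  mk_pair <- function(ccm, mcm) {
    structure(list(
      pairs = tibble::tibble(segment = "T",
                             section = seq_along(ccm) - 1L,
                             arclength = 0, ccm = ccm, mcm = mcm,
                             delta = ccm - mcm),
      excluded = tibble::tibble(), threshold = 0.5,
      frac_above = mean(abs(ccm - mcm) > 0.5)), class = "pair_comparison")
  }
  # all at 0.5 Pa -> 100% low band
  st <- stratify(mk_pair(rep(0.5, 20), rep(0.5, 20)))
  low <- st[st$model == "CCM" & st$band == "low", ]
  expect_equal(low$fraction, 1)
  # band boundaries go to the higher band
  st2 <- stratify(mk_pair(c(1, 2, 3), c(0.5, 0.5, 0.5)))
  cc <- st2[st2$model == "CCM", ]
  expect_equal(cc$n[cc$band == "intermediate"], 1L)  # 1.0 Pa
  expect_equal(cc$n[cc$band == "high"], 1L)          # 2.0 Pa
  expect_equal(cc$n[cc$band == "very_high"], 1L)     # 3.0 Pa
  # uniform on [0, 4]: 25% per band within sampling error
  set.seed(3)
  v <- runif(20000, 0, 4)
  st3 <- stratify(mk_pair(v, v))
  expect_equal(st3$fraction[st3$model == "CCM"], rep(0.25, 4),
               tolerance = 0.05)
  # fractions sum to one per model
  expect_equal(sum(st3$fraction[st3$model == "CCM"]), 1, tolerance = 1e-9)
  # invariant to section order and uniform relabeling
  set.seed(4)
  perm <- sample(length(v))
  st4 <- stratify(mk_pair(v[perm], v[perm]))
  expect_equal(st3$fraction, st4$fraction, tolerance = 1e-12)
})

test_that("outflow report groups outlets into major vessels and conserves mass", {
  tr <- generate_tree("left", desk_left_params(n_diag = 1, n_om = 1),
                      seed = 14)
  flows <- dplyr::bind_rows(lapply(
    c(LAD = 1.2, Diag1 = 0.4, LCx = 0.8, OM1 = 0.3),
    function(q) tibble::tibble(t = seq(0, 0.8, 0.1), q = q)) |>
      (\(l) Map(\(d, s) dplyr::mutate(d, segment = s), l, names(l)))())
  attr(flows, "inflow") <- tibble::tibble(t = seq(0, 0.8, 0.1), q = 2.7)
  rep <- outflow_report(flows, tr)
  pv <- attr(rep, "per_vessel")
  expect_equal(pv$q_mls[pv$vessel == "LAD"], 1.6)  # LAD + its diagonal
  expect_equal(pv$q_mls[pv$vessel == "LCx"], 1.1)
  expect_equal(attr(rep, "total_mls"), 2.7)
  expect_equal(attr(rep, "conservation_error"), 0, tolerance = 1e-12)
  # constant series: mean equals the constant
  expect_equal(rep$q_mls[rep$segment == "LAD"], 1.2)
  bad <- dplyr::mutate(flows, segment = ifelse(segment == "OM1", "ZZ",
                                               segment))
  attr(bad, "inflow") <- attr(flows, "inflow")
  expect_error(outflow_report(bad, tr), "not labelled")
})

test_that("statistical suite picks the right test and matches hand results", {
  # identical groups: t statistic 0, p = 1
  d0 <- data.frame(v = rep(c(1, 2, 3, 4), 2),
                   g = rep(c("a", "b"), each = 4))
  r0 <- stats_suite(d0, "v", "g")
  expect_equal(r0$test$statistic, 0)
  expect_equal(r0$test$p_value, 1)
  expect_false(r0$test$significant)
  # strongly separated normals are significant
  set.seed(5)
  d1 <- data.frame(v = c(rnorm(50), rnorm(50, 5)),
                   g = rep(c("a", "b"), each = 50))
  r1 <- stats_suite(d1, "v", "g")
  expect_true(r1$test$significant)
  expect_match(r1$test$test, "t ")
  # Kruskal-Wallis H matches the rank-sum formula on a 3x3 example
  d2 <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                   g = rep(c("a", "b", "c"), each = 3))
  r2 <- stats_suite(d2, "v", "g")
  H <- 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10
  expect_equal(unname(r2$test$statistic), H)
  expect_match(r2$test$test, "Kruskal")
  # paired design dispatches to Friedman; incomplete blocks error
  d3 <- data.frame(v = rnorm(12), g = rep(c("a", "b", "c"), 4),
                   b = rep(1:4, each = 3))
  r3 <- stats_suite(d3, "v", "g", block = "b")
  expect_match(r3$test$test, "Friedman")
  d4 <- d3[-1, ]
  expect_error(stats_suite(d4, "v", "g", block = "b"), "block")
  # summaries report mean and SEM
  expect_equal(r1$summary$sem[1], sd(d1$v[d1$g == "a"]) / sqrt(50))
})
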