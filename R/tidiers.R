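#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reconstruction report
#' @param x A `reconstruction_report`.
#' @param ... Unused.
#' @return The per-segment tibble.
#' @export
tidy.reconstruction_report <- function(x, ...) as_tibble(x)

#' One-row reconstruction summary
#' @param x A `reconstruction_report`.
#' @param ... Unused.
#' @export
glance.reconstruction_report <- function(x, ...) {
  tibble(n_segments = nrow(x), mean_rmse = mean(x$rmse),
         max_rmse = max(x$rmse),
         mean_diameter_mae = mean(x$diameter_mae))
}

#' Tidy a point-to-point model comparison
#' @param x A `pair_comparison`.
#' @param ... Unused.
#' @return The matched-section tibble with `delta` (Pa).
#' @export
tidy.pair_comparison <- function(x, ...) x$pairs

#' One-row comparison summary
#' @param x A `pair_comparison`.
#' @param ... Unused.
#' @export
glance.pair_comparison <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n_excluded = nrow(x$excluded),
         threshold = x$threshold, frac_above = x$frac_above,
         mean_delta = mean(x$pairs$delta))
}

#' Tidy a strata report
#' @param x A `strata_report`.
#' @param ... Unused.
#' @export
tidy.strata_report <- function(x, ...) as_tibble(x)

#' Tidy a cylindrical map into long format
#' @param x A `cylindrical_map`.
#' @param ... Unused.
#' @export
tidy.cylindrical_map <- function(x, ...) {
  df <- expand.grid(arclength = x$arclength, theta = x$theta)
  tibble(segment = x$segment, arclength = df$arclength,
         theta = df$theta, taess = as.vector(x$values),
         interpolated = as.vector(x$empty))
}

#' Tidy a statistical test report
#' @param x A `stats_report`.
#' @param ... Unused.
#' @return The test tibble (statistic, p-value, significance).
#' @export
tidy.stats_report <- function(x, ...) x$test

#' Group summaries of a statistical test report
#' @param x A `stats_report`.
#' @param ... Unused.
#' @export
glance.stats_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "group",
                     values_from = c("n", "mean", "sem"))
}

#' Tidy a flow result's outlet series
#' @param x A `flow_result`.
#' @param ... Unused.
#' @export
tidy.flow_result <- function(x, ...) x$flows

#' One-row flow-run summary
#' @param x A `flow_result`.
#' @param ... Unused.
#' @export
glance.flow_result <- function(x, ...) {
  tibble(steps = x$steps_done, converged = isTRUE(x$converged),
         residual = x$residual %||% NA_real_,
         periodicity = x$periodicity %||% NA_real_)
}
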