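#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_col geom_point
#'   scale_fill_viridis_c labs facet_wrap theme_minimal autoplot
NULL

#' Plot a circumferentially averaged shear profile
#'
#' TAESS along the centerline arclength, one panel per segment.
#'
#' @param object A `section_profile` from [circumferential_average()].
#' @param ... Unused.
#' @export
autoplot.section_profile <- function(object, ...) {
  ggplot(object[!object$empty, ],
         aes(x = .data$arclength, y = .data$taess)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~segment, scales = "free_x") +
    labs(x = "centerline arclength (mm)", y = "TAESS (Pa)") +
    theme_minimal()
}

#' Plot a 2D cylindrical shear map
#'
#' The unrolled vessel wall: arclength along the vessel versus
#' circumferential angle, colored by TAESS.
#'
#' @param object A `cylindrical_map`.
#' @param ... Unused.
#' @export
autoplot.cylindrical_map <- function(object, ...) {
  df <- expand.grid(s = object$arclength, theta = object$theta)
  df$taess <- as.vector(object$values)
  ggplot(df, aes(x = .data$s, y = .data$theta, fill = .data$taess)) +
    geom_tile() +
    scale_fill_viridis_c(name = "TAESS (Pa)") +
    labs(x = "centerline arclength (mm)",
         y = "circumferential angle (rad)",
         title = object$segment) +
    theme_minimal()
}

#' Plot shear-band strata fractions
#'
#' Fraction of sections per shear band, side by side for the compared
#' models.
#'
#' @param object A `strata_report` from [stratify()].
#' @param ... Unused.
#' @export
autoplot.strata_report <- function(object, ...) {
  ggplot(object, aes(x = .data$band, y = .data$fraction,
                     fill = .data$model)) +
    geom_col(position = "dodge") +
    labs(x = "TAESS band", y = "fraction of sections", fill = NULL) +
    theme_minimal()
}

#' Plot a Hausdorff-distance discrimination matrix
#'
#' Heat map of the symmetric Hausdorff distance between every original
#' tree and every perturbed copy; correct identification appears as a dark
#' diagonal.
#'
#' @param object An `hd_matrix` from [run_hd_matrix()].
#' @param ... Unused.
#' @export
autoplot.hd_matrix <- function(object, ...) {
  D <- object$matrix
  df <- expand.grid(original = seq_len(nrow(D)), copy = seq_len(ncol(D)))
  df$hd <- as.vector(D)
  ggplot(df, aes(x = .data$copy, y = .data$original, fill = .data$hd)) +
    geom_tile() +
    scale_fill_viridis_c(name = "HD (mm)", direction = -1) +
    labs(x = "perturbed copy", y = "original tree") +
    theme_minimal()
}

#' Plot an inflow waveform
#' @param object An `inlet_spec`.
#' @param ... Unused.
#' @export
autoplot.inlet_spec <- function(object, ...) {
  wf <- object$waveform
  ggplot(wf, aes(x = .data$t_frac * object$period,
                 y = .data$w * object$v_mean)) +
    geom_line() +
    labs(x = "time (s)", y = "inlet mean velocity (m/s)") +
    theme_minimal()
}

#' Plot the branch-ablation dose-response
#'
#' Trunk-averaged TAESS against the number of retained side branches.
#'
#' @param object An `ablation_report` from [run_lad_ablation()].
#' @param ... Unused.
#' @export
autoplot.ablation_report <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$trunk_taess)) +
    geom_line() + geom_point() +
    labs(x = "retained diagonal branches",
         y = "trunk-averaged TAESS (Pa)") +
    theme_minimal()
}
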