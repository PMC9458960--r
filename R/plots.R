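#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap labs
#'   theme_minimal position_dodge geom_point
#' @export
ggplot2::autoplot

#' Plot a reference motion
#'
#' Joint flexion angles (degrees) over the gait cycle.
#'
#' @param object A `reference_motion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_motion <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("phase", paste0("ang_", .joint_names))],
    -"phase", names_to = "joint", values_to = "angle") %>%
    mutate(joint = sub("^ang_", "", .data$joint),
           angle = .data$angle * 180 / pi)
  ggplot(long, aes(x = 100 * .data$phase, y = .data$angle,
                   colour = .data$joint)) +
    geom_line() +
    labs(x = "% gait cycle", y = "angle (deg)",
         title = sprintf("Reference gait, %.2f m/s", attr(object, "speed"))) +
    theme_minimal()
}

#' Plot mean cycle curves of a trial
#'
#' @param object A `trial_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$pct, y = .data$angle_deg)) +
    geom_line() +
    facet_wrap(~joint, scales = "free_y") +
    labs(x = "% gait cycle", y = "flexion angle (deg)") +
    theme_minimal()
}

#' Plot per-joint kinematic differences
#'
#' @param object A `gait_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"joint",
                              names_to = "measure", values_to = "deg")
  ggplot(long, aes(x = .data$joint, y = .data$deg, fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "difference (deg)") +
    theme_minimal()
}

#' Plot sweep results
#'
#' RMS differences against the swept belt parameter, one line per joint.
#'
#' @param results A tibble from [run_sweep()].
#' @param x One of `"fmax_N"`, `"fctrl_Hz"`, `"mass_kg"`, `"speed_mps"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(results, x = "fmax_N") {
  stopifnot(x %in% names(results))
  ggplot(results, aes(x = .data[[x]], y = .data$rms_diff_deg,
                      colour = .data$joint)) +
    geom_line() + geom_point() +
    labs(y = "RMS difference (deg)") +
    theme_minimal()
}

#' Plot cycle-normalized ground reaction forces
#'
#' Horizontal (braking negative) and vertical GRF of one foot over the
#' gait cycle, as used to explain how belt-speed fluctuation reshapes the
#' braking force.
#'
#' @param trial A `trial_result`.
#' @param foot `"right"` or `"left"`.
#' @return A ggplot object.
#' @export
plot_grf <- function(trial, foot = "right") {
  g <- extract_grf(trial, foot)
  long <- tidyr::pivot_longer(g$mean, -"pct", names_to = "component",
                              values_to = "force")
  ggplot(long, aes(x = .data$pct, y = .data$force)) +
    geom_line() +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "% gait cycle", y = "force (N)") +
    theme_minimal()
}
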