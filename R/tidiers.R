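#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trial result into long mean cycle curves
#'
#' @param x A `trial_result`.
#' @param ... Unused.
#' @return A tibble `joint`, `pct`, `angle_deg` (mean cycle curve, right
#'   hip/knee/ankle); empty if no cycles were retained.
#' @export
tidy.trial_result <- function(x, ...) {
  if (is.null(x$mean_curves))
    return(tibble(joint = character(), pct = numeric(),
                  angle_deg = numeric()))
  tidyr::pivot_longer(x$mean_curves, -"pct", names_to = "joint",
                      values_to = "angle_deg") %>%
    select("joint", "pct", "angle_deg") %>% arrange(.data$joint, .data$pct)
}

#' One-row summary of a trial
#'
#' @inheritParams tidy.trial_result
#' @return A tibble with environment, speed, mass, retained cycles, fall
#'   outcome and mean imitation reward (total and per term).
#' @export
glance.trial_result <- function(x, ...) {
  env <- if (inherits(x$config$environment, "treadmill_spec")) {
    if (x$config$environment$ideal) "ideal_treadmill" else "treadmill"
  } else "overground"
  tibble(environment = env, speed_mps = x$config$speed,
         mass_kg = x$config$mass, retained_cycles = x$retained_cycles,
         fell = x$fell, fell_time = x$fell_time,
         mean_reward = x$mean_reward,
         rp = x$reward_components[["rp"]], rv = x$reward_components[["rv"]],
         re = x$reward_components[["re"]], rc = x$reward_components[["rc"]],
         status = x$status)
}

#' @export
tidy.gait_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.gait_comparison <- function(x, ...) {
  tibble(max_diff_deg = max(x$max_diff_deg),
         rms_diff_deg = max(x$rms_diff_deg),
         fell_treadmill = attr(x, "fell_treadmill"),
         fell_overground = attr(x, "fell_overground"))
}
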