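#' Detect heel-strike events from vertical GRF
#'
#' Heel strikes are rising crossings of a force threshold on a foot's
#' vertical ground reaction force, with a debounce window suppressing
#' chatter: a crossing within `debounce` seconds of the previous accepted
#' event is ignored.
#'
#' @param grf A data frame with columns `time` (s) and `fz` (N), uniformly
#'   sampled; optionally a `foot` column, in which case events are detected
#'   per foot.
#' @param threshold Force threshold (N), > 0.  Default 20 N.
#' @param debounce Minimum spacing between events (s).  Default 0.1 s.
#' @param min_stance Stance-confirmation window (s): a crossing counts as
#'   a heel strike only if the force stays at or above the threshold for
#'   at least 90 percent of the samples in the following window (initial
#'   contact of a sustained stance).  0 (the default) accepts any
#'   crossing; trial segmentation uses a quarter gait cycle to reject brief
#'   swing-phase grazes.
#' @return A tibble with columns `foot` (or `"all"`) and `time`; empty if
#'   there is no crossing.
#' @export
detect_gait_events <- function(grf, threshold = 20, debounce = 0.1,
                               min_stance = 0) {
  if (threshold <= 0)
    abort("`threshold` must be positive.", class = "treadgait_invalid_argument")
  if (!all(c("time", "fz") %in% names(grf)))
    abort("`grf` needs `time` and `fz` columns.", class = "treadgait_schema_error")
  one_foot <- function(df) {
    fz <- df$fz
    n <- length(fz)
    up <- which(fz[-1] >= threshold & fz[-n] < threshold) + 1
    if (min_stance > 0 && length(up) > 0) {
      dt <- df$time[2] - df$time[1]
      need <- ceiling(min_stance / dt)
      loaded <- fz >= threshold
      ok <- vapply(up, function(i) {
        j <- min(i + need, n)
        mean(loaded[i:j]) >= 0.9
      }, logical(1))
      up <- up[ok]
    }
    times <- df$time[up]
    keep <- numeric(0)
    last <- -Inf
    for (t in times) {
      if (t - last >= debounce) { keep <- c(keep, t); last <- t }
    }
    tibble(time = keep)
  }
  if ("foot" %in% names(grf)) {
    grf %>% group_by(.data$foot) %>%
      dplyr::group_modify(~ one_foot(.x)) %>% dplyr::ungroup()
  } else {
    mutate(one_foot(grf), foot = "all", .before = 1)
  }
}

#' Normalize time series to percent gait cycle
#'
#' Resamples each inter-strike interval of every numeric column to `n`
#' evenly spaced points (0-100% of the gait cycle) by linear
#' interpolation, and averages the retained cycles pointwise.
#'
#' @param series A data frame with a `time` column and one or more numeric
#'   value columns.
#' @param events Heel-strike times (numeric vector, sorted; at least 2).
#' @param n Number of resample points per cycle (default 101).
#' @return A list with `cycles` (tibble: `cycle`, `pct`, one column per
#'   variable) and `mean` (tibble: `pct`, pointwise mean per variable).
#' @export
cycle_normalize <- function(series, events, n = 101) {
  if (length(events) < 2)
    abort("need at least 2 heel-strike events to form a cycle.",
          class = "treadgait_insufficient_cycles")
  if (n < 2) abort("`n` must be >= 2.", class = "treadgait_invalid_argument")
  if (!"time" %in% names(series))
    abort("`series` needs a `time` column.", class = "treadgait_schema_error")
  vars <- setdiff(names(series)[vapply(series, is.numeric, logical(1))], "time")
  pct <- seq(0, 100, length.out = n)
  cyc <- purrr::map_dfr(seq_len(length(events) - 1), function(k) {
    tq <- seq(events[k], events[k + 1], length.out = n)
    vals <- lapply(series[vars], function(v)
      approx(series$time, v, xout = tq, rule = 2)$y)
    dplyr::bind_cols(tibble(cycle = k, pct = pct), as_tibble(vals))
  })
  mean_curve <- cyc %>% group_by(.data$pct) %>%
    summarise(across(dplyr::all_of(vars), mean), .groups = "drop")
  list(cycles = cyc, mean = mean_curve)
}

#' Compare treadmill and overground kinematics
#'
#' Differences the mean treadmill cycle curve against the mean overground
#' cycle curve for the hip, knee and ankle flexion angles and reports the
#' maximum absolute and root-mean-square difference per joint (degrees over
#' the normalized gait cycle).  If either trial fell before accumulating
#' two retained cycles, the fell outcome is propagated instead of numbers.
#'
#' @param treadmill,overground `trial_result` objects from [run_trial()],
#'   run with the same reference and model.
#' @return A tibble of class `gait_comparison` with columns `joint`,
#'   `max_diff_deg`, `rms_diff_deg` and attributes `fell_treadmill`,
#'   `fell_overground`.
#' @export
compare_kinematics <- function(treadmill, overground) {
  stopifnot(inherits(treadmill, "trial_result"),
            inherits(overground, "trial_result"))
  short_t <- treadmill$retained_cycles < 2 || is.null(treadmill$mean_curves)
  short_o <- overground$retained_cycles < 2 || is.null(overground$mean_curves)
  joints <- c("hip", "knee", "ankle")
  if (short_t || short_o) {
    out <- tibble(joint = joints, max_diff_deg = NA_real_,
                  rms_diff_deg = NA_real_)
  } else {
    mt <- treadmill$mean_curves
    mo <- overground$mean_curves
    if (!identical(names(mt), names(mo)))
      abort("trials have mismatched joint sets.",
            class = "treadgait_schema_error")
    out <- purrr::map_dfr(joints, function(j) {
      d <- mt[[j]] - mo[[j]]
      tibble(joint = j, max_diff_deg = max(abs(d)),
             rms_diff_deg = sqrt(mean(d^2)))
    })
  }
  structure(out,
            fell_treadmill = isTRUE(treadmill$fell),
            fell_overground = isTRUE(overground$fell),
            class = c("gait_comparison", class(tibble())))
}

#' Detect a fall in a trial trajectory
#'
#' The model has fallen at the first instant where the root height drops
#' below half the standing hip height or the trunk pitches beyond 60
#' degrees.
#'
#' @param trajectory A data frame with columns `time`, `root_z`, `pitch`.
#' @param model A `biped_model`.
#' @return A list `fell` (logical) and `time` (s, `NA` if no fall).
#' @export
detect_fall <- function(trajectory, model) {
  stopifnot(inherits(model, "biped_model"))
  bad <- trajectory$root_z < 0.5 * model$standing_hip_height |
    abs(trajectory$pitch) > 60 * pi / 180
  if (any(bad)) list(fell = TRUE, time = trajectory$time[which(bad)[1]])
  else list(fell = FALSE, time = NA_real_)
}

#' Extract cycle-normalized ground reaction forces
#'
#' Per-foot horizontal and vertical GRF against percent gait cycle for the
#' retained cycles of a trial; horizontal braking forces are negative.
#'
#' @param trial A `trial_result`.
#' @param foot `"right"` or `"left"`.
#' @return A list with `cycles` and `mean` tibbles (`pct`, `fx`, `fz`).
#' @export
extract_grf <- function(trial, foot = c("right", "left")) {
  stopifnot(inherits(trial, "trial_result"))
  foot <- match.arg(foot)
  if (trial$retained_cycles < 1)
    abort("trial has no retained cycles.",
          class = "treadgait_insufficient_cycles")
  suff <- if (foot == "right") "_r" else "_l"
  ser <- tibble(time = trial$trajectory$time,
                fx = trial$grf[[paste0("fx", suff)]],
                fz = trial$grf[[paste0("fz", suff)]])
  cycle_normalize(ser, trial$retained_events, n = 101)
}
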