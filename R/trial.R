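#' Configure a simulation trial
#'
#' @param environment `"overground"` or a [treadmill_spec()].
#' @param mass Total body mass (kg).
#' @param height Standing height (m).
#' @param speed Nominal gait speed (m/s); for treadmill trials this should
#'   equal the belt target speed.
#' @param template A `gait_template`, or `NULL` to pick walk/run by speed.
#' @param model A pre-built [build_biped()] model, or `NULL` to build one
#'   from `mass` and `height` (a supplied model takes precedence).
#' @param reference A pre-generated `reference_motion`, or `NULL` to
#'   generate one from the template.
#' @param duration Trial length (s); `NULL` chooses `(transient + 5 + 0.6)`
#'   gait cycles so at least five steady cycles are retained.
#' @param dt Physics time step (s).
#' @param seed Integer seed (forwarded to the reference generator).
#' @param gains A [pd_gains()].
#' @param stabilizer Logical; enable the root stabilizer (default TRUE).
#' @param mu Foot-ground friction coefficient for overground trials.
#' @param n_transient Gait cycles discarded as transient (default 3).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(environment = "overground", mass = 63, height = 1.73,
                         speed = 1.05, template = NULL, model = NULL,
                         reference = NULL,
                         duration = NULL, dt = 5e-4, seed = 1L,
                         gains = pd_gains(), stabilizer = TRUE, mu = 0.9,
                         n_transient = 3) {
  if (!(identical(environment, "overground") ||
        inherits(environment, "treadmill_spec")))
    abort("`environment` must be \"overground\" or a treadmill_spec.",
          class = "treadgait_invalid_argument")
  if (dt <= 0 || dt > 2e-3)
    abort("`dt` must lie in (0, 2e-3].", class = "treadgait_invalid_argument")
  if (!is.null(model)) mass <- model$total_mass
  structure(list(environment = environment, mass = mass, height = height,
                 speed = speed, template = template, model = model,
                 reference = reference,
                 duration = duration, dt = dt, seed = as.integer(seed),
                 gains = gains, stabilizer = stabilizer, mu = mu,
                 n_transient = n_transient),
            class = "trial_config")
}

#' Run a forward-dynamics gait trial
#'
#' Initializes the biped on the surface in the reference pose at phase 0
#' with root velocity matched to the environment (overground: walking
#' forward at the reference speed; treadmill: stationary over a belt
#' already running at its target speed), then advances the physics with
#' the tracking controller at every step.  Heel strikes are detected on
#' the right foot's vertical GRF, the first `n_transient` cycles are
#' discarded, joint-angle curves are normalized to percent gait cycle, and
#' the motion-imitation reward is scored over the steady portion.
#'
#' @param config A [trial_config()].
#' @return An object of class `trial_result`: trajectory/GRF/belt tibbles,
#'   heel-strike times, per-cycle and mean cycle curves (degrees, right
#'   hip/knee/ankle), fall flag and time, mean imitation reward, and the
#'   model/reference used.
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  model <- config$model %||% build_biped(config$mass, config$height)
  reference <- config$reference %||%
    generate_reference(model, config$speed, config$template,
                       seed = config$seed)
  T <- attr(reference, "cycle_duration")
  duration <- config$duration %||% ((config$n_transient + 6.6) * T)
  if (duration < 5 * T)
    abort(sprintf("duration %.2f s is under 5 gait cycles (T = %.2f s).",
                  duration, T),
          class = "treadgait_invalid_argument")

  tm <- config$environment
  on_treadmill <- inherits(tm, "treadmill_spec")
  mode <- if (!on_treadmill) 0L else if (tm$ideal) 1L else 2L
  v_target <- if (on_treadmill) tm$target_speed else 0
  mu <- if (on_treadmill) tm$mu else config$mu

  q0 <- c(0, reference$root_z[1], reference$root_pitch[1],
          as.numeric(reference[1, paste0("ang_", .joint_names)]))
  xd0 <- reference$root_xd[1] - if (on_treadmill) v_target else 0
  qd0 <- c(xd0, reference$root_zd[1], reference$root_pitchd[1],
           as.numeric(reference[1, paste0("vel_", .joint_names)]))

  g <- config$gains
  # controller strength follows body mass (one controller per subject mass)
  ms <- if (is.na(g$mass_ref %||% NA)) 1 else config$mass / g$mass_ref
  belt_kp <- 0; belt_kd <- 0
  if (mode == 2L) { belt_kp <- tm$kp; belt_kd <- tm$kd }
  n_steps <- round(duration / config$dt)
  ref_ang <- as.matrix(reference[paste0("ang_", .joint_names)])
  ref_vel <- as.matrix(reference[paste0("vel_", .joint_names)])

  sim <- cpp_simulate(model, q0, qd0, ref_ang, ref_vel,
                      reference$root_z, reference$root_zd,
                      reference$root_pitch, reference$root_pitchd,
                      T, 0,
                      ms * g$kp6, ms * g$kd6, ms * g$tau_max,
                      g$phase_lead %||% 0,
                      config$stabilizer, ms * g$pitch[1], ms * g$pitch[2],
                      ms * g$height[1], ms * g$height[2],
                      mode, v_target,
                      if (mode == 2L) tm$max_force else 0,
                      if (mode == 2L) tm$control_freq else 0,
                      belt_kp, belt_kd,
                      if (on_treadmill) tm$m_belt else 1,
                      if (on_treadmill && !tm$ideal) tm$mu_deck else 0,
                      v_target,
                      mu, model$contact_kn, model$contact_cn,
                      model$contact_veps,
                      config$dt, n_steps)

  log <- sim$log
  trajectory <- as_tibble(as.data.frame(log[, 1:19, drop = FALSE]))
  names(trajectory) <- c("time", .coord_names, paste0(.coord_names, "_d"))
  grf <- tibble(time = log[, 1],
                fx_l = log[, 20] + log[, 22], fz_l = log[, 21] + log[, 23],
                fx_r = log[, 24] + log[, 26], fz_r = log[, 25] + log[, 27])
  contact_pts <- as_tibble(as.data.frame(log[, 20:27, drop = FALSE]))
  names(contact_pts) <- c("fx_heel_l", "fz_heel_l", "fx_toe_l", "fz_toe_l",
                          "fx_heel_r", "fz_heel_r", "fx_toe_r", "fz_toe_r")
  belt <- tibble(time = log[, 1], position = log[, 28], speed = log[, 29],
                 force = log[, 30])

  fall <- detect_fall(trajectory, model)
  events <- detect_gait_events(tibble(time = grf$time, fz = grf$fz_r),
                               debounce = 0.5 * T, min_stance = 0.25 * T)$time

  # retained cycles: after the transient, fully before any fall
  retained <- numeric(0)
  if (length(events) >= 2) {
    idx <- seq_along(events)
    start <- config$n_transient + 1
    if (length(events) >= start) retained <- events[start:length(events)]
    if (fall$fell) retained <- retained[retained <= fall$time]
  }
  retained_cycles <- max(length(retained) - 1, 0)

  cycles <- NULL; mean_curves <- NULL
  if (retained_cycles >= 1) {
    ang_deg <- tibble(time = trajectory$time,
                      hip = trajectory$hip_r * 180 / pi,
                      knee = trajectory$knee_r * 180 / pi,
                      ankle = trajectory$ankle_r * 180 / pi)
    cn <- cycle_normalize(ang_deg, retained, n = 101)
    cycles <- cn$cycles
    mean_curves <- cn$mean
  }

  rew <- .batch_rewards(model, reference, trajectory, T,
                        window_start = config$n_transient * T,
                        window_end = if (fall$fell) fall$time else Inf)

  structure(list(config = config, model = model, reference = reference,
                 trajectory = trajectory, grf = grf,
                 contact_points = contact_pts, belt = belt,
                 events = events, retained_events = retained,
                 retained_cycles = retained_cycles,
                 cycles = cycles, mean_curves = mean_curves,
                 fell = fall$fell, fell_time = fall$time,
                 mean_reward = rew$mean_r,
                 reward_components = rew$components,
                 rewards = rew$series,
                 status = if (sim$status == 0) "ok" else "numeric_failure"),
            class = "trial_result")
}

# vectorized imitation rewards over a logged trajectory
.batch_rewards <- function(model, reference, trajectory, T,
                           window_start = 0, window_end = Inf,
                           weights = reward_weights()) {
  ph <- (trajectory$time / T) %% 1
  ref <- .interp_reference(reference, ph,
                           c(paste0("ang_", .joint_names),
                             paste0("vel_", .joint_names),
                             "foot_l_x", "foot_l_z", "foot_r_x", "foot_r_z",
                             "com_x", "com_z"))
  qm <- as.matrix(trajectory[.coord_names])
  qdm <- as.matrix(trajectory[paste0(.coord_names, "_d")])
  rp <- exp(-2 * rowSums((ref[, 1:6, drop = FALSE] - qm[, 4:9])^2))
  rv <- exp(-0.04 * rowSums((ref[, 7:12, drop = FALSE] - qdm[, 4:9])^2))
  pts <- .fk_batch_rel_root(model, qm)
  re <- exp(-40 * ((ref[, "foot_l_x"] - pts$foot_l[, 1])^2 +
                   (ref[, "foot_l_z"] - pts$foot_l[, 2])^2 +
                   (ref[, "foot_r_x"] - pts$foot_r[, 1])^2 +
                   (ref[, "foot_r_z"] - pts$foot_r[, 2])^2))
  rc <- exp(-30 * ((ref[, "com_x"] - pts$com[, 1])^2 +
                   (ref[, "com_z"] - pts$com[, 2])^2))
  r <- weights$wp * rp + weights$wv * rv + weights$we * re + weights$wc * rc
  sel <- trajectory$time >= window_start & trajectory$time <= window_end
  if (!any(sel)) sel <- rep(TRUE, length(r))
  list(series = tibble(time = trajectory$time, rp = rp, rv = rv,
                       re = re, rc = rc, r = r),
       mean_r = mean(r[sel]),
       components = c(rp = mean(rp[sel]), rv = mean(rv[sel]),
                      re = mean(re[sel]), rc = mean(rc[sel])))
}

# foot centres and CoM relative to the root for a matrix of configurations
.fk_batch_rel_root <- function(model, qm) {
  pitch <- qm[, 3]
  leg <- function(hip, knee, ankle) {
    a_th <- pitch + hip; a_sh <- a_th - knee; a_ft <- a_sh + ankle
    knee_p <- cbind(model$l_thigh * sin(a_th), -model$l_thigh * cos(a_th))
    ankle_p <- knee_p + cbind(model$l_shank * sin(a_sh),
                              -model$l_shank * cos(a_sh))
    cl <- model$contact_local
    mid <- colMeans(cl)
    cbind(ankle_p[, 1] + mid[1] * cos(a_ft) - mid[2] * sin(a_ft),
          ankle_p[, 2] + mid[1] * sin(a_ft) + mid[2] * cos(a_ft))
  }
  fl <- leg(qm[, 4], qm[, 5], qm[, 6])
  fr <- leg(qm[, 7], qm[, 8], qm[, 9])
  # CoM relative to root, mass-weighted over the seven segments
  m <- model$seg_mass
  seg_com <- function(hip, knee, ankle) {
    a_th <- pitch + hip; a_sh <- a_th - knee; a_ft <- a_sh + ankle
    knee_p <- cbind(model$l_thigh * sin(a_th), -model$l_thigh * cos(a_th))
    ankle_p <- knee_p + cbind(model$l_shank * sin(a_sh),
                              -model$l_shank * cos(a_sh))
    cl <- model$com_local
    th <- cbind(cl[2, 1] * cos(a_th) - cl[2, 2] * sin(a_th),
                cl[2, 1] * sin(a_th) + cl[2, 2] * cos(a_th))
    sh <- knee_p + cbind(cl[3, 1] * cos(a_sh) - cl[3, 2] * sin(a_sh),
                         cl[3, 1] * sin(a_sh) + cl[3, 2] * cos(a_sh))
    ft <- ankle_p + cbind(cl[4, 1] * cos(a_ft) - cl[4, 2] * sin(a_ft),
                          cl[4, 1] * sin(a_ft) + cl[4, 2] * cos(a_ft))
    m[2] * th + m[3] * sh + m[4] * ft
  }
  hat <- cbind(model$com_local[1, 1] * cos(pitch) -
                 model$com_local[1, 2] * sin(pitch),
               model$com_local[1, 1] * sin(pitch) +
                 model$com_local[1, 2] * cos(pitch))
  com <- (m[1] * hat + seg_com(qm[, 4], qm[, 5], qm[, 6]) +
            seg_com(qm[, 7], qm[, 8], qm[, 9])) / sum(m)
  list(foot_l = fl, foot_r = fr, com = com)
}

#' @export
print.trial_result <- function(x, ...) {
  env <- if (inherits(x$config$environment, "treadmill_spec")) {
    if (x$config$environment$ideal) "ideal treadmill" else "treadmill"
  } else "overground"
  cat(sprintf("<trial_result> %s, %.2f m/s, %.0f kg: %d retained cycles, mean reward %.3f%s\n",
              env, x$config$speed, x$config$mass, x$retained_cycles,
              x$mean_reward,
              if (x$fell) sprintf(", FELL at %.2f s", x$fell_time) else ""))
  invisible(x)
}

#' Sweep treadmill conditions against overground baselines
#'
#' Runs the full factorial of maximum belt force, belt control frequency,
#' body mass and speed, comparing each treadmill trial against the
#' overground baseline for its (mass, speed) pair (computed once per pair
#' with the same controller and reference).
#'
#' @param base_config A [trial_config()] providing all settings not swept.
#' @param fmax Maximum belt forces (N); `Inf` denotes the ideal kinematic
#'   belt.
#' @param fctrl Belt control frequencies (Hz).
#' @param mass Body masses (kg).
#' @param speed Walking speeds (m/s).
#' @return A tibble with one row per condition and joint: `mass_kg`,
#'   `speed_mps`, `fmax_N`, `fctrl_Hz`, `joint`, `max_diff_deg`,
#'   `rms_diff_deg`, `fell`; falls propagate as `fell = TRUE` with `NA`
#'   differences.
#' @export
run_sweep <- function(base_config = trial_config(),
                      fmax = c(100, 200, 300, 400, 500),
                      fctrl = c(10, 13, 17, 25, 50),
                      mass = 63, speed = 1.05) {
  if (length(fmax) == 0 || length(fctrl) == 0 || length(mass) == 0 ||
      length(speed) == 0)
    abort("sweep grid must be non-empty in every factor.",
          class = "treadgait_invalid_argument")
  out <- list()
  for (m in mass) for (v in speed) {
    model <- build_biped(m, base_config$height)
    ref <- generate_reference(model, v, base_config$template,
                              seed = base_config$seed)
    cfg_o <- base_config
    cfg_o$environment <- "overground"
    cfg_o$mass <- m; cfg_o$speed <- v; cfg_o$reference <- ref
    over <- run_trial(cfg_o)
    for (f in fmax) for (h in fctrl) {
      cfg_t <- cfg_o
      cfg_t$environment <- treadmill_spec(v, max_force = f, control_freq = h,
                                          mu = base_config$mu,
                                          ideal = is.infinite(f))
      tr <- run_trial(cfg_t)
      cmp <- compare_kinematics(tr, over)
      out[[length(out) + 1]] <- mutate(as_tibble(cmp),
                                       mass_kg = m, speed_mps = v,
                                       fmax_N = f, fctrl_Hz = h,
                                       fell = tr$fell, .before = 1)
    }
  }
  bind_rows(out) %>%
    select("mass_kg", "speed_mps", "fmax_N", "fctrl_Hz", "joint",
           "max_diff_deg", "rms_diff_deg", "fell")
}
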