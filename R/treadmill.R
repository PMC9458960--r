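#' Treadmill specification
#'
#' Parameters of the belt and its speed controller.  A non-ideal belt is a
#' one-degree-of-freedom translating body (mass `m_belt`, prismatic joint
#' to the frame) driven by a PD speed controller whose force is recomputed
#' at `control_freq` Hz, held constant between updates (zero-order hold)
#' and saturated at `max_force`.  An ideal belt is a kinematic body: it
#' holds the target speed exactly regardless of load.
#'
#' Belt speed is measured along the belt's running direction, so a walker
#' facing +x stands on surface material moving at `-belt speed` in world
#' coordinates.
#'
#' @param target_speed Target belt speed v* (m/s, >= 0).
#' @param max_force Saturation limit Fmax of the control force (N).
#' @param control_freq Controller update rate (Hz).
#' @param kp,kd PD gains (N s/m, N s^2/m); `NULL` means auto-tuned via
#'   [auto_tune_gains()].
#' @param m_belt Belt equivalent mass (kg).
#' @param mu_deck Belt-deck Coulomb friction coefficient.
#' @param mu Belt-foot friction coefficient.
#' @param ideal If TRUE the belt is kinematic and force/frequency limits do
#'   not apply.
#' @return An object of class `treadmill_spec`.
#' @examples
#' treadmill_spec(1.05, max_force = 300, control_freq = 17)
#' treadmill_spec(1.05, ideal = TRUE)
#' @export
treadmill_spec <- function(target_speed, max_force = 300, control_freq = 17,
                           kp = NULL, kd = NULL, m_belt = 10, mu_deck = 0.05,
                           mu = 0.9, ideal = FALSE) {
  if (target_speed < 0)
    abort("`target_speed` must be >= 0.", class = "treadgait_invalid_argument")
  if (!ideal) {
    if (max_force <= 0) abort("`max_force` must be positive.",
                              class = "treadgait_invalid_argument")
    if (control_freq <= 0) abort("`control_freq` must be positive.",
                                 class = "treadgait_invalid_argument")
  }
  if (m_belt <= 0) abort("`m_belt` must be positive.",
                         class = "treadgait_invalid_argument")
  spec <- structure(list(target_speed = target_speed, max_force = max_force,
                         control_freq = control_freq, kp = kp, kd = kd,
                         m_belt = m_belt, mu_deck = mu_deck, mu = mu,
                         ideal = ideal),
                    class = "treadmill_spec")
  if (!ideal && (is.null(kp) || is.null(kd))) {
    g <- auto_tune_gains(spec)
    spec$kp <- spec$kp %||% g[["kp"]]
    spec$kd <- spec$kd %||% g[["kd"]]
  }
  spec
}

#' @export
print.treadmill_spec <- function(x, ...) {
  if (x$ideal) {
    cat(sprintf("<treadmill_spec> ideal belt, v* = %.2f m/s\n", x$target_speed))
  } else {
    cat(sprintf(
      "<treadmill_spec> v* = %.2f m/s, Fmax = %g N, fctrl = %g Hz, Kp = %g, Kd = %g\n",
      x$target_speed, x$max_force, x$control_freq, x$kp, x$kd))
  }
  invisible(x)
}

#' Auto-tune belt PD gains
#'
#' For zero-order-hold proportional control of a pure inertia, the discrete
#' closed loop is stable for `Kp < 2 * m_belt * fctrl`; the tuning rule
#' takes half that bound, `Kp = m_belt * fctrl`, and a light derivative
#' term `Kd = 0.1 * Kp / fctrl`.
#'
#' @param spec A non-ideal `treadmill_spec` with `control_freq` and
#'   `m_belt` set.
#' @return Named numeric vector `c(kp = , kd = )`.
#' @examples
#' auto_tune_gains(treadmill_spec(1.05, control_freq = 25, m_belt = 10))
#' @export
auto_tune_gains <- function(spec) {
  stopifnot(inherits(spec, "treadmill_spec"))
  if (spec$ideal)
    abort("an ideal belt needs no gains.", class = "treadgait_invalid_argument")
  kp <- spec$m_belt * spec$control_freq
  c(kp = kp, kd = 0.1 * kp / spec$control_freq)
}

#' Belt state
#'
#' @param position Belt position along its running direction (m).
#' @param velocity Belt speed (m/s).
#' @param held_force Control force currently held by the zero-order hold (N).
#' @param last_update Time of the last controller update (s), `-Inf` if none.
#' @param prev_velocity Belt speed at the previous controller update (for
#'   the derivative term), `NA` if none.
#' @return An object of class `belt_state`.
#' @export
belt_state <- function(position = 0, velocity = 0, held_force = 0,
                       last_update = -Inf, prev_velocity = NA_real_) {
  structure(list(position = position, velocity = velocity,
                 held_force = held_force, last_update = last_update,
                 prev_velocity = prev_velocity),
            class = "belt_state")
}

#' Zero-order-hold PD belt control force
#'
#' If `t` has reached the next update instant (period `1/control_freq`
#' after the last update), the force is recomputed as
#' `clip(Kp * (v* - v_belt) - Kd * a_belt, -Fmax, +Fmax)` where `a_belt` is
#' the belt acceleration estimated from the last two controller-update
#' velocity samples; otherwise the held force is returned unchanged.
#'
#' @param spec A non-ideal `treadmill_spec`.
#' @param belt A `belt_state`.
#' @param t Current time (s).
#' @return A list with `force` (N) and the updated `belt` state.
#' @export
belt_control_force <- function(spec, belt, t) {
  stopifnot(inherits(spec, "treadmill_spec"), inherits(belt, "belt_state"))
  if (spec$ideal)
    abort("an ideal belt has no control force.",
          class = "treadgait_invalid_argument")
  period <- 1 / spec$control_freq
  if (t >= belt$last_update + period - 1e-12 || !is.finite(belt$last_update)) {
    a_belt <- if (is.na(belt$prev_velocity)) 0
              else (belt$velocity - belt$prev_velocity) / period
    f <- spec$kp * (spec$target_speed - belt$velocity) - spec$kd * a_belt
    f <- min(max(f, -spec$max_force), spec$max_force)
    belt$prev_velocity <- belt$velocity
    belt$held_force <- f
    belt$last_update <- if (is.finite(belt$last_update))
      belt$last_update + period else t
  }
  list(force = belt$held_force, belt = belt)
}

#' Advance the belt by one time step
#'
#' Ideal mode: the belt is kinematic, holding exactly the target speed and
#' ignoring loads.  Non-ideal: semi-implicit Euler step of
#' `m_belt * dv = (F_ctrl + foot load - deck friction) * dt`, with deck
#' friction `mu_deck * (m_belt * g + vertical foot load) * tanh(v / v_eps)`.
#'
#' @inheritParams belt_control_force
#' @param foot_tangential_load Tangential foot load on the belt along its
#'   running direction (N); braking loads are negative.
#' @param foot_normal_load Vertical foot load on the deck (N, >= 0).
#' @param dt Time step (s).
#' @param g Gravitational acceleration (m/s^2).
#' @param v_eps Friction regularization velocity (m/s).
#' @return The updated `belt_state`.
#' @export
step_belt <- function(spec, belt, foot_tangential_load = 0,
                      foot_normal_load = 0, dt = 5e-4, g = 9.81,
                      v_eps = 0.05) {
  stopifnot(inherits(spec, "treadmill_spec"), inherits(belt, "belt_state"))
  if (dt <= 0) abort("`dt` must be positive.",
                     class = "treadgait_invalid_argument")
  if (spec$ideal) {
    belt$velocity <- spec$target_speed
    belt$position <- belt$position + spec$target_speed * dt
    return(belt)
  }
  deck <- spec$mu_deck * (spec$m_belt * g + max(foot_normal_load, 0)) *
    tanh(belt$velocity / v_eps)
  belt$velocity <- belt$velocity +
    dt * (belt$held_force + foot_tangential_load - deck) / spec$m_belt
  belt$position <- belt$position + belt$velocity * dt
  belt
}

#' Closed-form response of the ZOH-controlled belt
#'
#' Exact discrete recursion of the linear zero-order-hold PD loop on a pure
#' inertia under a piecewise-constant disturbance force, independent of the
#' physics engine: between force breakpoints (controller updates and
#' disturbance switch times) the total force is constant, so the velocity
#' advances linearly.  Deck friction is not modelled (the linear loop).
#'
#' @param spec A non-ideal `treadmill_spec`.
#' @param disturbance A data frame with columns `time` and `force`: each
#'   force holds from its time until the next row (piecewise constant).
#'   Must start at or before time 0.
#' @param horizon Simulation horizon (s).
#' @param v0 Initial belt speed (m/s); defaults to the target speed.
#' @param saturate If FALSE, the force clip at `max_force` is disabled
#'   (pure linear loop).
#' @return A tibble with columns `time`, `speed`, `force` sampled at every
#'   breakpoint (left limit semantics: each row holds from `time` to the
#'   next row).
#' @export
belt_response_oracle <- function(spec, disturbance, horizon,
                                 v0 = NULL, saturate = TRUE) {
  stopifnot(inherits(spec, "treadmill_spec"))
  if (spec$ideal)
    abort("the oracle applies to the non-ideal belt.",
          class = "treadgait_invalid_argument")
  if (!all(c("time", "force") %in% names(disturbance)))
    abort("`disturbance` needs `time` and `force` columns.",
          class = "treadgait_invalid_argument")
  if (min(disturbance$time) > 0 || max(disturbance$time) > horizon)
    abort("disturbance profile must start at t <= 0 and lie within the horizon.",
          class = "treadgait_invalid_argument")
  period <- 1 / spec$control_freq
  updates <- seq(0, horizon, by = period)
  times <- sort(unique(c(updates, disturbance$time[disturbance$time >= 0],
                         horizon)))
  dist_at <- stats::approxfun(disturbance$time, disturbance$force,
                              method = "constant", rule = 2)
  v <- v0 %||% spec$target_speed
  f_hold <- 0
  v_prev <- NA_real_
  out_t <- numeric(length(times)); out_v <- out_t; out_f <- out_t
  for (i in seq_along(times)) {
    t <- times[i]
    if (any(abs(t - updates) < 1e-12)) {
      a <- if (is.na(v_prev)) 0 else (v - v_prev) / period
      f <- spec$kp * (spec$target_speed - v) - spec$kd * a
      if (saturate) f <- min(max(f, -spec$max_force), spec$max_force)
      v_prev <- v
      f_hold <- f
    }
    out_t[i] <- t; out_v[i] <- v; out_f[i] <- f_hold
    if (i < length(times)) {
      dt <- times[i + 1] - t
      v <- v + dt * (f_hold + dist_at(t)) / spec$m_belt
    }
  }
  tibble(time = out_t, speed = out_v, force = out_f)
}

#' Simulate the belt loop at fixed step size
#'
#' Drives [belt_control_force()] and [step_belt()] at time step `dt` under
#' a piecewise-constant disturbance; used to verify the belt integrator
#' against [belt_response_oracle()].
#'
#' @inheritParams belt_response_oracle
#' @param dt Integration step (s).
#' @param mu_deck_zero If TRUE (default), deck friction is disabled to
#'   match the linear oracle.
#' @return A tibble `time`, `speed`, `force` at every step.
#' @export
run_belt_sim <- function(spec, disturbance, horizon, dt = 1e-5, v0 = NULL,
                         mu_deck_zero = TRUE) {
  stopifnot(inherits(spec, "treadmill_spec"))
  sp <- spec
  if (mu_deck_zero) sp$mu_deck <- 0
  dist_at <- stats::approxfun(disturbance$time, disturbance$force,
                              method = "constant", rule = 2)
  n <- round(horizon / dt)
  v <- v0 %||% sp$target_speed
  period <- 1 / sp$control_freq
  next_up <- 0
  f_hold <- 0
  v_prev <- NA_real_
  tvec <- (0:(n - 1)) * dt
  dvec <- dist_at(tvec)
  vout <- numeric(n); fout <- numeric(n)
  kp <- sp$kp; kd <- sp$kd; vstar <- sp$target_speed
  fmax <- sp$max_force; mb <- sp$m_belt
  for (i in seq_len(n)) {
    t <- tvec[i]
    if (t >= next_up - 1e-12) {
      a <- if (is.na(v_prev)) 0 else (v - v_prev) / period
      f_hold <- min(max(kp * (vstar - v) - kd * a, -fmax), fmax)
      v_prev <- v
      next_up <- next_up + period
    }
    v <- v + dt * (f_hold + dvec[i]) / mb
    vout[i] <- v; fout[i] <- f_hold
  }
  tibble(time = tvec + dt, speed = vout, force = fout)
}
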