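#' Create a simulation state
#'
#' @param q Generalized coordinates (9): root x, root z, trunk pitch, and
#'   six joint angles (rad).
#' @param qd Generalized velocities (9).
#' @param t Simulation time (s).
#' @param contact_forces 4 x 2 matrix of per-contact-point forces (N), rows
#'   heel_l, toe_l, heel_r, toe_r, columns fx, fz.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(q, qd = rep(0, 9), t = 0,
                      contact_forces = matrix(0, 4, 2)) {
  if (length(q) != 9 || length(qd) != 9)
    abort("`q` and `qd` must have length 9.", class = "treadgait_invalid_argument")
  if (!all(is.finite(q)) || !all(is.finite(qd)))
    abort("state entries must be finite.", class = "treadgait_invalid_argument")
  q <- stats::setNames(as.numeric(q), .coord_names)
  qd <- stats::setNames(as.numeric(qd), .coord_names)
  dimnames(contact_forces) <- list(c("heel_l", "toe_l", "heel_r", "toe_r"),
                                   c("fx", "fz"))
  structure(list(q = q, qd = qd, t = t, contact_forces = contact_forces),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %.4f s, root (%.3f, %.3f) m, pitch %.3f rad\n",
              x$t, x$q[1], x$q[2], x$q[3]))
  invisible(x)
}

# default flat ground; `speed` is the x-velocity of the surface material
# (a treadmill belt running backwards has negative speed)
ground_surface <- function(height = 0, speed = 0, mu = 0.9) {
  list(height = height, speed = speed, mu = mu)
}

#' Penalty contact forces at the foot contact points
#'
#' For each heel/toe point with penetration depth `delta` below the surface,
#' the normal force is a Hunt-Crossley-style penalty
#' `fN = kn * delta * (1 + cn * delta_dot)` clipped at zero, and the
#' tangential force is regularized Coulomb friction
#' `fT = -mu * fN * tanh(v_rel / v_eps)` where `v_rel` is the point's
#' horizontal velocity relative to the surface material.  Points above the
#' surface carry no force.
#'
#' @param model A `biped_model` (carries kn, cn, v_eps defaults).
#' @param state A `sim_state`.
#' @param surface A list with `height` (m), `speed` (surface material
#'   x-velocity, m/s) and `mu` (friction coefficient), as returned by the
#'   internal constructor; defaults to flat static ground.
#' @return A tibble with one row per contact point: `point`, `fx`, `fz` (N),
#'   plus attributes `surface_load_tangential` and `surface_load_vertical`,
#'   the equal-and-opposite load on the surface (used by the belt).
#' @export
contact_forces <- function(model, state, surface = ground_surface()) {
  stopifnot(inherits(model, "biped_model"), inherits(state, "sim_state"))
  if (surface$mu <= 0)
    abort("surface `mu` must be positive.", class = "treadgait_invalid_argument")
  res <- cpp_contact_forces(model, state$q, state$qd,
                            surface$height, surface$speed, surface$mu,
                            model$contact_kn, model$contact_cn,
                            model$contact_veps)
  out <- tibble(point = c("heel_l", "toe_l", "heel_r", "toe_r"),
                fx = res$forces[, 1], fz = res$forces[, 2])
  attr(out, "surface_load_tangential") <- res$surface_load_tangential
  attr(out, "surface_load_vertical") <- res$surface_load_vertical
  out
}

#' Advance the biped by one integration step
#'
#' One semi-implicit Euler step of the articulated equations of motion
#' `M(q) qdd = Q(tau, gravity, contact, external)`: velocities are updated
#' from the accelerations first, then positions from the new velocities.
#' The floating root is unactuated; `torques` act on the six joints only,
#' and the external wrench applies a vertical force and a pitch torque to
#' the trunk (never a horizontal force).
#'
#' @inheritParams contact_forces
#' @param torques Numeric vector of 6 joint torques (N m), order
#'   hip/knee/ankle left then right.
#' @param ext_wrench Numeric vector `c(fz, my)`: vertical force (N) and
#'   pitch torque (N m) on the trunk.
#' @param dt Time step (s), in (0, 2e-3].
#' @param pin_root If TRUE the root is welded (used for pinned passive-swing
#'   verification); the joint subsystem is solved on its own.
#' @return A new `sim_state` at `t + dt`, with the contact forces that acted
#'   during the step recorded.
#' @export
step_dynamics <- function(model, state, torques = rep(0, 6),
                          ext_wrench = c(0, 0), surface = ground_surface(),
                          dt = 5e-4, pin_root = FALSE) {
  stopifnot(inherits(model, "biped_model"), inherits(state, "sim_state"))
  if (!is.numeric(dt) || dt <= 0 || dt > 2e-3)
    abort("`dt` must lie in (0, 2e-3].", class = "treadgait_invalid_argument")
  if (length(torques) != 6)
    abort("`torques` must have length 6 (the root is unactuated).",
          class = "treadgait_invalid_argument")
  res <- cpp_step(model, state$q, state$qd, as.numeric(torques),
                  ext_wrench[1], ext_wrench[2],
                  surface$height, surface$speed, surface$mu,
                  model$contact_kn, model$contact_cn, model$contact_veps,
                  dt, pin_root)
  sim_state(res$q, res$qd, state$t + dt, res$contact_forces)
}

#' Total mechanical energy of the biped
#'
#' Kinetic energy `0.5 * qd' M(q) qd` plus gravitational potential energy
#' of the segment centres of mass (reference height z = 0).
#'
#' @inheritParams contact_forces
#' @return Energy in J.
#' @export
total_energy <- function(model, state) {
  stopifnot(inherits(model, "biped_model"), inherits(state, "sim_state"))
  cpp_energy(model, state$q, state$qd)
}
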