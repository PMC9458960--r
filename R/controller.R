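#' Joint PD and root-stabilizer gains
#'
#' Per-joint proportional/derivative gains for the tracking controller,
#' plus soft root-stabilizer gains (a restoring pitch torque and vertical
#' force toward the reference root trajectory; never a horizontal force,
#' so belt perturbations always propagate to the kinematics).
#'
#' @param hip,knee,ankle Length-2 numeric `c(kp, kd)` in N m/rad and
#'   N m s/rad.
#' @param tau_max Joint torque saturation (N m).
#' @param phase_lead Constant lead (s) applied to the joint target phase in
#'   closed-loop trials, compensating the tracking lag of a PD controller
#'   following a moving target; 0 disables it.
#' @param pitch Stabilizer `c(kp, kd)` for trunk pitch (N m/rad, N m s/rad).
#' @param height Stabilizer `c(kp, kd)` for root height (N/m, N s/m).
#' @param mass_ref Body mass (kg) the gains are specified for.  In
#'   closed-loop trials all gains and the torque limit are scaled in
#'   proportion to the simulated body mass, the planar analogue of training
#'   one controller per body mass: muscle strength grows with the body it
#'   moves, so tracking stiffness per unit inertia stays constant across
#'   subjects.  Set `NA` to disable scaling.
#' @return An object of class `pd_gains`.
#' @export
pd_gains <- function(hip = c(5000, 60), knee = c(5000, 60),
                     ankle = c(800, 15),
                     tau_max = 800, phase_lead = 0.03,
                     pitch = c(8000, 800), height = c(2000, 2500),
                     mass_ref = 63) {
  g <- list(hip = hip, knee = knee, ankle = ankle, tau_max = tau_max,
            phase_lead = phase_lead, pitch = pitch, height = height,
            mass_ref = mass_ref)
  if (any(unlist(g) < 0, na.rm = TRUE))
    abort("gains must be non-negative.", class = "treadgait_invalid_argument")
  g$kp6 <- rep(c(hip[1], knee[1], ankle[1]), 2)
  g$kd6 <- rep(c(hip[2], knee[2], ankle[2]), 2)
  structure(g, class = "pd_gains")
}

#' Imitation reward weights
#'
#' Weights of the pose, velocity, end-effector and centre-of-mass reward
#' terms; the defaults (0.65, 0.1, 0.15, 0.1) sum to one.
#'
#' @param wp,wv,we,wc Non-negative weights.
#' @return An object of class `reward_weights`.
#' @export
reward_weights <- function(wp = 0.65, wv = 0.1, we = 0.15, wc = 0.1) {
  w <- c(wp = wp, wv = wv, we = we, wc = wc)
  if (any(w < 0)) abort("weights must be non-negative.",
                        class = "treadgait_invalid_argument")
  structure(as.list(w), class = "reward_weights")
}

#' Assemble the controller observation vector
#'
#' Deterministic packing of the planar observation: root height (1), trunk
#' pitch (1), root linear velocity (2), root angular velocity (1), joint
#' angles (6), joint velocities (6), gait phase wrapped to `[0, 1)` (1) and
#' terrain height at 5 forward grid points spaced 0.25 m ahead of the root
#' (5) - 23 entries.
#'
#' @param model A `biped_model`.
#' @param state A `sim_state`.
#' @param phase Gait phase (any real; wrapped modulo 1).
#' @param terrain A function of x returning terrain height (m); default
#'   flat ground at height 0.
#' @return A named numeric vector of length 23.
#' @export
assemble_observation <- function(model, state, phase,
                                 terrain = function(x) rep(0, length(x))) {
  stopifnot(inherits(state, "sim_state"))
  grid_x <- state$q[1] + seq(0, 1, by = 0.25)
  obs <- c(root_height = unname(state$q[2]),
           root_pitch = unname(state$q[3]),
           root_vx = unname(state$qd[1]), root_vz = unname(state$qd[2]),
           root_pitch_rate = unname(state$qd[3]),
           stats::setNames(unname(state$q[4:9]), paste0("ang_", .joint_names)),
           stats::setNames(unname(state$qd[4:9]), paste0("vel_", .joint_names)),
           phase = phase %% 1,
           stats::setNames(as.numeric(terrain(grid_x)), paste0("terrain_", 1:5)))
  stopifnot(length(obs) == 23)
  obs
}

#' Reference-tracking policy
#'
#' The deterministic stand-in for a learned gait policy: the action is the
#' reference joint angles at the current phase, linearly interpolated on
#' the reference grid.  It implements the `Policy` interface
#' (observation/phase in, target joint angles out) so a learned policy can
#' be plugged in later.
#'
#' @param reference A `reference_motion`.
#' @param phase Gait phase in `[0, 1)`.
#' @return Named numeric vector of 6 target joint angles (rad).
#' @export
tracking_policy <- function(reference, phase) {
  cols <- paste0("ang_", .joint_names)
  if (!all(cols %in% names(reference)))
    abort("reference is missing joint angle columns.",
          class = "treadgait_schema_error")
  if (any(phase < 0 | phase >= 1))
    abort("`phase` must lie in [0, 1).", class = "treadgait_invalid_argument")
  n <- nrow(reference)
  x <- phase * (n - 1)
  i0 <- pmin(floor(x), n - 2)
  fr <- x - i0
  ang <- as.matrix(reference[cols])
  stats::setNames(ang[i0 + 1, ] * (1 - fr) + ang[i0 + 2, ] * fr, .joint_names)
}

#' Joint PD torques
#'
#' `tau_j = kp_j (theta_target_j - theta_j) - kd_j thetadot_j`, clipped to
#' `+/- tau_max`.
#'
#' @param gains A `pd_gains`.
#' @param action Named or plain numeric vector of 6 target joint angles
#'   (rad).
#' @param state A `sim_state`.
#' @return Numeric vector of 6 joint torques (N m).
#' @export
joint_pd_torques <- function(gains, action, state) {
  stopifnot(inherits(gains, "pd_gains"), inherits(state, "sim_state"))
  tau <- gains$kp6 * (as.numeric(action) - state$q[4:9]) -
    gains$kd6 * state$qd[4:9]
  unname(pmin(pmax(tau, -gains$tau_max), gains$tau_max))
}

#' Root stabilizer wrench
#'
#' Deterministic surrogate for the balance behaviour a learned policy
#' acquires: a restoring pitch torque and vertical force toward the
#' reference root trajectory.  No horizontal force is ever applied, so the
#' belt-to-kinematics causal path is preserved.
#'
#' @inheritParams joint_pd_torques
#' @param reference A `reference_motion`.
#' @param phase Gait phase in `[0, 1)`.
#' @return Named numeric `c(fz, my)`: vertical force (N) and pitch torque
#'   (N m) on the trunk.
#' @export
root_stabilizer <- function(gains, state, reference, phase) {
  stopifnot(inherits(gains, "pd_gains"), inherits(state, "sim_state"))
  r <- .interp_reference(reference, phase,
                         c("root_z", "root_zd", "root_pitch", "root_pitchd"))
  fz <- gains$height[1] * (r[["root_z"]] - state$q[2]) +
    gains$height[2] * (r[["root_zd"]] - state$qd[2])
  my <- gains$pitch[1] * (r[["root_pitch"]] - state$q[3]) +
    gains$pitch[2] * (r[["root_pitchd"]] - state$qd[3])
  c(fz = unname(fz), my = unname(my))
}

.interp_reference <- function(reference, phase, cols) {
  n <- nrow(reference)
  x <- (phase %% 1) * (n - 1)
  i0 <- pmin(floor(x), n - 2)
  fr <- x - i0
  vapply(cols, function(cl) {
    v <- reference[[cl]]
    v[i0 + 1] * (1 - fr) + v[i0 + 2] * fr
  }, numeric(length(phase)))
}

#' Motion-imitation rewards
#'
#' The four exponential similarity terms between the simulated state and
#' the reference motion at the current phase, and their weighted sum:
#' \deqn{r_p = \exp[-2 \sum_j (\hat\theta_j - \theta_j)^2]}
#' \deqn{r_v = \exp[-0.04 \sum_j (\dot{\hat\theta}_j - \dot\theta_j)^2]}
#' \deqn{r_e = \exp[-40 \sum_e \|\hat p_e - p_e\|^2]}
#' \deqn{r_c = \exp[-30 \|\hat p_c - p_c\|^2]}
#' with the end-effectors being the two feet (foot centres) and all
#' positions taken relative to the root in a non-rotating frame.  Every
#' term lies in (0, 1] and equals 1 only at an exact match;
#' `r = wp rp + wv rv + we re + wc rc`.
#'
#' @param state A `sim_state`.
#' @param model A `biped_model`.
#' @param reference A `reference_motion`.
#' @param phase Gait phase in `[0, 1)`.
#' @param weights A `reward_weights`.
#' @return A one-row tibble with columns `rp`, `rv`, `re`, `rc`, `r`.
#' @export
imitation_rewards <- function(state, model, reference, phase,
                              weights = reward_weights()) {
  stopifnot(inherits(state, "sim_state"), inherits(model, "biped_model"))
  if (phase < 0 || phase >= 1)
    abort("`phase` must lie in [0, 1).", class = "treadgait_invalid_argument")
  ref <- .interp_reference(reference, phase,
                           c(paste0("ang_", .joint_names),
                             paste0("vel_", .joint_names),
                             "foot_l_x", "foot_l_z", "foot_r_x", "foot_r_z",
                             "com_x", "com_z"))
  rp <- exp(-2 * sum((ref[1:6] - state$q[4:9])^2))
  rv <- exp(-0.04 * sum((ref[7:12] - state$qd[4:9])^2))
  pts <- fk_points_rel_root(model, state$q)
  re <- exp(-40 * (sum((c(ref[["foot_l_x"]], ref[["foot_l_z"]]) - pts$foot_l)^2) +
                   sum((c(ref[["foot_r_x"]], ref[["foot_r_z"]]) - pts$foot_r)^2)))
  rc <- exp(-30 * sum((c(ref[["com_x"]], ref[["com_z"]]) - pts$com)^2))
  r <- weights$wp * rp + weights$wv * rv + weights$we * re + weights$wc * rc
  tibble(rp = rp, rv = rv, re = re, rc = rc, r = r)
}
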