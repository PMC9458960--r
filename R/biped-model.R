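#' Build a sagittal-plane seven-segment biped
#'
#' Constructs a planar floating-base rigid-body model of a walking human:
#' a head-arms-trunk (HAT) segment and two three-segment legs
#' (thigh, shank, foot), connected at a common pelvis point (the root).
#' The model has 9 degrees of freedom: root translation (x forward, z up),
#' trunk pitch (counterclockwise positive), and hip, knee and ankle flexion
#' per leg.  Hip flexion moves the thigh forward, knee flexion is positive,
#' ankle dorsiflexion is positive.
#'
#' Segment masses are fixed fractions of total body mass (HAT 0.678,
#' each thigh 0.100, each shank 0.0465, each foot 0.0145; the fractions sum
#' to one) and segment lengths are fixed fractions of standing height
#' (thigh 0.245 H, shank 0.246 H, foot 0.152 H, ankle height 0.039 H),
#' in the style of Winter's anthropometric tables.  Moments of inertia use
#' slender-rod formulas for HAT, thigh and shank and a box formula for the
#' foot.  Each foot carries two contact points (heel and toe).
#'
#' @param total_mass Total body mass in kg.
#' @param height Standing height in m.
#' @param gravity Gravitational acceleration in m/s^2 (default 9.81).
#' @param contact_kn Contact normal stiffness (N/m per point).  The
#'   default `NULL` scales the stiffness with subject weight so the static
#'   two-point penetration depth is about 1 cm for every subject
#'   (3e4 N/m at 63 kg) - penalty-contact conditioning that keeps gait
#'   dynamics comparable across body masses.
#' @param contact_cn Hunt-Crossley contact damping (s/m): the normal force
#'   is scaled by `(1 + cn * penetration_rate)`, dissipating impact energy.
#' @param contact_veps Friction regularization velocity (m/s).
#' @param contact_mu Default foot-ground friction coefficient.
#' @return An object of class `biped_model`: a list with a `segments`
#'   tibble (name, mass, length, com offset, inertia), joint names and
#'   limits, contact-point geometry, and the packed numeric fields used by
#'   the compiled dynamics core.
#' @examples
#' m <- build_biped(63, 1.73)
#' m$segments
#' @export
build_biped <- function(total_mass, height, gravity = 9.81,
                        contact_kn = NULL, contact_cn = 0.5,
                        contact_veps = 0.05, contact_mu = 0.9) {
  contact_kn <- contact_kn %||% (3e4 * total_mass / 63)
  if (!is.numeric(total_mass) || length(total_mass) != 1 || total_mass <= 0)
    abort("`total_mass` must be a positive number.", class = "treadgait_invalid_argument")
  if (!is.numeric(height) || length(height) != 1 || height <= 0)
    abort("`height` must be a positive number.", class = "treadgait_invalid_argument")

  frac_mass <- c(hat = 0.678, thigh = 0.100, shank = 0.0465, foot = 0.0145)
  l_hat <- 0.470 * height
  l_th <- 0.245 * height
  l_sh <- 0.246 * height
  l_ft <- 0.152 * height
  h_ank <- 0.039 * height

  m_seg <- total_mass * frac_mass
  seg_names <- c("hat", "thigh_l", "shank_l", "foot_l",
                 "thigh_r", "shank_r", "foot_r")
  seg_mass <- unname(m_seg[c(1, 2, 3, 4, 2, 3, 4)])
  seg_len <- c(l_hat, l_th, l_sh, l_ft, l_th, l_sh, l_ft)
  # CoM distance from proximal joint along segment axis
  com_off <- c(0.350 * l_hat, 0.433 * l_th, 0.433 * l_sh, 0.500 * l_ft,
               0.433 * l_th, 0.433 * l_sh, 0.500 * l_ft)
  inertia <- c(m_seg[["hat"]] * l_hat^2 / 12,
               rep(c(m_seg[["thigh"]] * l_th^2 / 12,
                     m_seg[["shank"]] * l_sh^2 / 12,
                     m_seg[["foot"]] * (l_ft^2 + h_ank^2) / 12), 2)[c(1, 2, 3, 1, 2, 3)])

  # CoM offsets in segment frames: HAT points up from the root, thigh/shank
  # hang down from their proximal joint, the foot extends from heel
  # (-0.3 Lf) to toe (+0.7 Lf) around the ankle at depth h_ank.
  com_local <- rbind(c(0, 0.350 * l_hat),
                     c(0, -0.433 * l_th),
                     c(0, -0.433 * l_sh),
                     c(0.2 * l_ft, -0.5 * h_ank),
                     c(0, -0.433 * l_th),
                     c(0, -0.433 * l_sh),
                     c(0.2 * l_ft, -0.5 * h_ank))
  contact_local <- rbind(heel = c(-0.3 * l_ft, -h_ank),
                         toe = c(0.7 * l_ft, -h_ank))

  joint_lo <- c(hip = -0.70, knee = -0.05, ankle = -0.90)[c(1, 2, 3, 1, 2, 3)]
  joint_hi <- c(hip = 2.10, knee = 2.60, ankle = 0.60)[c(1, 2, 3, 1, 2, 3)]

  model <- list(
    total_mass = total_mass,
    height = height,
    gravity = gravity,
    segments = tibble(
      name = seg_names, mass = seg_mass, length = seg_len,
      com_offset = com_off, inertia = inertia),
    joints = .joint_names,
    joint_lo = unname(joint_lo),
    joint_hi = unname(joint_hi),
    standing_hip_height = l_th + l_sh + h_ank,
    l_thigh = l_th, l_shank = l_sh, l_foot = l_ft, ankle_height = h_ank,
    seg_mass = seg_mass,
    seg_inertia = inertia,
    com_local = com_local,
    contact_local = unname(contact_local),
    limit_stiffness = 500,
    limit_damping = 10,
    contact_kn = contact_kn, contact_cn = contact_cn,
    contact_veps = contact_veps, contact_mu = contact_mu
  )
  stopifnot(abs(sum(model$seg_mass) - total_mass) < 1e-9)
  structure(model, class = "biped_model")
}

#' @export
print.biped_model <- function(x, ...) {
  cat(sprintf("<biped_model> %.1f kg, %.2f m, 9 DoF (planar)\n",
              x$total_mass, x$height))
  cat(sprintf("  standing hip height %.3f m; joints: %s\n",
              x$standing_hip_height, paste(x$joints, collapse = ", ")))
  invisible(x)
}

#' Forward kinematics of the biped
#'
#' Positions of every joint, foot contact point, segment centre of mass and
#' the whole-body centre of mass for a configuration `q`.
#'
#' @param model A `biped_model`.
#' @param q Numeric vector of 9 generalized coordinates
#'   (root x, root z, trunk pitch, then hip/knee/ankle left, hip/knee/ankle
#'   right; metres and radians).
#' @return A tibble with columns `point`, `type` (`joint`, `contact`,
#'   `segment_com`, `com`) and planar coordinates `x`, `z` (m).
#' @export
forward_kinematics <- function(model, q) {
  stopifnot(inherits(model, "biped_model"))
  if (length(q) != 9 || !is.numeric(q))
    abort("`q` must be a numeric vector of length 9.",
          class = "treadgait_invalid_argument")
  k <- cpp_fk(model, as.numeric(q))
  tibble(
    point = c("root", "knee_l", "ankle_l", "knee_r", "ankle_r",
              "heel_l", "toe_l", "heel_r", "toe_r",
              "hat", "thigh_l", "shank_l", "foot_l",
              "thigh_r", "shank_r", "foot_r", "com"),
    type = c(rep("joint", 5), rep("contact", 4), rep("segment_com", 7), "com"),
    x = c(k$joints[, 1], k$contacts[, 1], k$seg_coms[, 1], k$com[1]),
    z = c(k$joints[, 2], k$contacts[, 2], k$seg_coms[, 2], k$com[2])
  )
}

#' Mass matrix of the biped
#'
#' Joint-space inertia matrix M(q) (9 x 9), assembled from segment CoM
#' Jacobians and rotational inertias.
#'
#' @inheritParams forward_kinematics
#' @return A 9 x 9 symmetric positive-definite matrix.
#' @export
mass_matrix <- function(model, q) {
  stopifnot(inherits(model, "biped_model"), length(q) == 9)
  cpp_mass_matrix(model, as.numeric(q))
}

# foot centres (midpoint of heel and toe) and whole-body CoM relative to the
# root, for one configuration; used by rewards and the reference generator
fk_points_rel_root <- function(model, q) {
  k <- cpp_fk(model, as.numeric(q))
  root <- q[1:2]
  list(
    foot_l = colMeans(k$contacts[1:2, , drop = FALSE]) - root,
    foot_r = colMeans(k$contacts[3:4, , drop = FALSE]) - root,
    com = as.numeric(k$com) - root
  )
}
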