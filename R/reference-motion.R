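#' Generate a periodic reference gait motion
#'
#' Builds one canonical gait cycle of kinematically consistent reference
#' motion for a biped model at a given speed, standing in for
#' mocap-derived inverse kinematics.  Joint angles come from the template's
#' Fourier series (left leg half a cycle out of phase); joint velocities
#' are analytic derivatives of the series, so the stored velocities match
#' the angles exactly up to interpolation.  The pelvis (root) trajectory is
#' constructed from the joint curves: the root height keeps the lower foot
#' at ground level (via a smooth soft-minimum over the four heel/toe
#' points) and the forward root velocity cancels the stance foot's velocity
#' relative to the pelvis, then receives a uniform correction so the mean
#' forward speed equals `speed` exactly.  The hip amplitude is rescaled so
#' the natural stride length matches `speed * T`, where `T` comes from the
#' template's cadence model.
#'
#' @param model A `biped_model`.
#' @param speed Walking (or running) speed in m/s; must be positive, with
#'   walking templates used up to 2 m/s and running templates above.
#' @param template A `gait_template`.
#' @param n Number of phase samples; the grid spans `[0, 1]` inclusive, the
#'   last row duplicating phase 0 by periodicity.
#' @param seed Integer seed; only consumed when `noise_sd > 0`.
#' @param noise_sd Standard deviation (rad) of optional coefficient noise
#'   for robustness studies; default 0 keeps the generator deterministic.
#' @return A tibble of class `reference_motion` with columns `phase`,
#'   `ang_*` and `vel_*` for the six joints, root pose and velocity
#'   (`root_x`, `root_z`, `root_pitch`, `root_xd`, `root_zd`,
#'   `root_pitchd`), foot centres and CoM relative to the root
#'   (`foot_l_x`, `foot_l_z`, `foot_r_x`, `foot_r_z`, `com_x`, `com_z`);
#'   attributes `speed`, `cycle_duration`, `mode`.
#' @examples
#' mdl <- build_biped(63, 1.73)
#' ref <- generate_reference(mdl, 1.05)
#' attr(ref, "cycle_duration")
#' @export
generate_reference <- function(model, speed, template = NULL,
                               n = 1001, seed = 1L, noise_sd = 0) {
  stopifnot(inherits(model, "biped_model"))
  if (!is.numeric(speed) || length(speed) != 1 || speed <= 0)
    abort("`speed` must be a positive number.", class = "treadgait_invalid_argument")
  if (is.null(template))
    template <- gait_template(if (speed > 2.0) "run" else "walk")
  mode <- attr(template, "mode")
  if (mode == "walk" && speed > 2.0)
    abort("walking template is limited to speeds <= 2 m/s; use the run template.",
          class = "treadgait_invalid_argument")
  if (mode == "run" && speed <= 2.0)
    abort("running template expects speeds > 2 m/s.",
          class = "treadgait_invalid_argument")
  base <- c("hip", "knee", "ankle")
  tpl_joints <- unique(template$joint)
  model_base <- unique(sub("_[lr]$", "", model$joints))
  if (!setequal(tpl_joints, model_base))
    abort(paste0("template joints {", paste(tpl_joints, collapse = ", "),
                 "} do not match model joints {",
                 paste(model_base, collapse = ", "), "}."),
          class = "treadgait_schema_error")

  T <- cycle_duration(template, speed)
  coefs <- lapply(base, function(j) {
    cf <- template[template$joint == j, ]
    cf <- cf[order(cf$harmonic), ]
    list(a = cf$a, b = cf$b)
  })
  names(coefs) <- base
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    coefs <- lapply(coefs, function(cf) {
      cf$a <- cf$a + stats::rnorm(length(cf$a), 0, noise_sd)
      cf$b[-1] <- cf$b[-1] + stats::rnorm(length(cf$b) - 1, 0, noise_sd)
      cf
    })
  }

  phi <- seq(0, 1, length.out = n)
  eps <- attr(template, "softmin_eps") %||% 0.008
  ank_ord <- attr(template, "ankle_order") %||% 8

  # stride calibration: scale the hip harmonics so one cycle of the
  # stance-consistent root construction travels speed * T
  target <- speed * T
  disp_of <- function(s) .root_construction(model, coefs, phi, s, eps, ank_ord)$disp
  lo <- 0.25; hi <- 3.0
  f_lo <- disp_of(lo) - target
  f_hi <- disp_of(hi) - target
  if (f_lo < 0 && f_hi > 0) {
    scale <- stats::uniroot(function(s) disp_of(s) - target,
                            c(lo, hi), tol = 1e-8)$root
  } else {
    # out of reachable range (e.g. long-flight running): closest amplitude,
    # the affine correction below makes up the remainder
    opt <- stats::optimize(function(s) abs(disp_of(s) - target), c(lo, hi))
    scale <- opt$minimum
  }

  rc <- .root_construction(model, coefs, phi, scale, eps, ank_ord)
  # contact preload allowance: the penalty contact carries body weight at a
  # static two-point penetration depth, so the simulated root rides that
  # much lower than pure kinematics suggests; lowering the reference
  # accordingly keeps the mean vertical stabilizer force near zero (the
  # legs, not the stabilizer, carry body weight)
  preload <- model$total_mass * model$gravity / (2 * model$contact_kn)
  # band-limit the pelvis height so weight transfer descends gently
  # (the raw soft-minimum construction has a sharp heel-strike dip that a
  # tracking controller can only follow ballistically)
  zs <- .fourier_smooth(rc$z - preload, order = 4)
  rc$z <- zs$value

  x_root <- rc$x + (target - rc$disp) * phi
  xd_root <- (rc$dxdphi + (target - rc$disp)) / T
  zd_root <- zs$dphase / T

  ang <- cbind(rc$ang_l, rc$ang_r)
  vel <- cbind(rc$dphase_l, rc$dphase_r) / T
  colnames(ang) <- paste0("ang_", .joint_names)
  colnames(vel) <- paste0("vel_", .joint_names)

  out <- tibble(phase = phi) %>%
    dplyr::bind_cols(as_tibble(ang), as_tibble(vel)) %>%
    mutate(root_x = x_root, root_z = rc$z, root_pitch = 0,
           root_xd = xd_root, root_zd = zd_root, root_pitchd = 0,
           foot_l_x = rc$foot_l[, 1], foot_l_z = rc$foot_l[, 2],
           foot_r_x = rc$foot_r[, 1], foot_r_z = rc$foot_r[, 2],
           com_x = rc$com[, 1], com_z = rc$com[, 2])
  structure(out, speed = speed, cycle_duration = T, mode = mode,
            seed = as.integer(seed), hip_scale = scale,
            class = c("reference_motion", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Joint curves plus the stance-consistent root construction on the phase
# grid.  The right leg is evaluated at phase phi (phase 0 = right heel
# strike), the left at phi + 0.5.  All foot geometry is computed relative
# to the root with zero trunk pitch.
.root_construction <- function(model, coefs, phi, hip_scale, eps, ankle_order = 8) {
  ev <- function(cf, p, scale = 1) {
    a <- cf$a; b <- cf$b
    if (scale != 1) { a[-1] <- a[-1] * scale; b[-1] <- b[-1] * scale }
    .eval_fourier(a, b, p)
  }
  # The ankle is scheduled from the foot attitude rather than tracked
  # directly: during stance the foot is flat on the ground
  # (ankle = knee - hip), during terminal swing the foot pitches toe-up
  # for heel-first contact, and in between (push-off, early swing) the
  # template's Fourier curve (plantarflexion bump) applies.
  legs <- lapply(list(r = phi, l = phi + 0.5), function(p) {
    hip <- ev(coefs$hip, p, hip_scale)
    knee_tpl <- ev(coefs$knee, p)
    ankle_tpl <- ev(coefs$ankle, p)
    # strike preparation: keep the reaching knee flexed through terminal
    # swing (the straight reaching leg would otherwise be longer than the
    # stance support and strike the ground early), extending only just
    # before heel strike
    prep <- (22 * pi / 180) * .bump(p, 0.91, 0.045)
    kne <- .fourier_smooth(knee_tpl$value + prep, order = ankle_order)
    w <- .ankle_schedule(p)
    reach_tilt <- 10 * pi / 180
    ankle_raw <- w$flat * (kne$value - hip$value) +
      w$reach * (reach_tilt + kne$value - hip$value) +
      (1 - w$flat - w$reach) * ankle_tpl$value
    # band-limit the scheduled curves so the stored joints are analytic
    # Fourier series like the template joints (velocities exact)
    ank <- .fourier_smooth(ankle_raw, order = ankle_order)
    list(ang = cbind(hip$value, kne$value, ank$value),
         dphase = cbind(hip$dphase, kne$dphase, ank$dphase))
  })

  leg_points <- function(ang) {
    a_th <- ang[, 1]; a_sh <- a_th - ang[, 2]; a_ft <- a_sh + ang[, 3]
    knee <- cbind(model$l_thigh * sin(a_th), -model$l_thigh * cos(a_th))
    ankle <- knee + cbind(model$l_shank * sin(a_sh), -model$l_shank * cos(a_sh))
    rotp <- function(cp) cbind(ankle[, 1] + cp[1] * cos(a_ft) - cp[2] * sin(a_ft),
                               ankle[, 2] + cp[1] * sin(a_ft) + cp[2] * cos(a_ft))
    heel <- rotp(model$contact_local[1, ])
    toe <- rotp(model$contact_local[2, ])
    list(knee = knee, ankle = ankle, heel = heel, toe = toe)
  }
  pl <- leg_points(legs$l$ang)
  pr <- leg_points(legs$r$ang)

  cz <- cbind(pl$heel[, 2], pl$toe[, 2], pr$heel[, 2], pr$toe[, 2])
  mn <- apply(cz, 1, min)
  smin <- mn - eps * log(rowSums(exp(-(cz - mn) / eps)))
  z_root <- -smin

  # forward progression: the stance foot's centre is stationary on the
  # ground, so the root moves at minus that foot's velocity relative to the
  # root.  Stance is scheduled by gait phase (right stance 0-0.6, left
  # 0.5-1.1) with smooth weight hand-over during the double-support windows.
  w_r <- .stance_weight(phi)
  w_l <- .stance_weight(phi + 0.5)
  wsum <- w_r + w_l
  w_r <- w_r / wsum; w_l <- w_l / wsum
  fx_r <- (pr$heel[, 1] + pr$toe[, 1]) / 2
  fx_l <- (pl$heel[, 1] + pl$toe[, 1]) / 2
  dxdphi <- -(w_r * .spectral_deriv(fx_r) + w_l * .spectral_deriv(fx_l))
  x <- .cumtrapz(phi, dxdphi)

  # mass-weighted CoM relative to root (pitch 0): trunk CoM is constant
  m <- model$seg_mass
  com_legs <- function(p, ang) {
    a_th <- ang[, 1]; a_sh <- a_th - ang[, 2]; a_ft <- a_sh + ang[, 3]
    thigh <- cbind(model$com_local[2, 1] * cos(a_th) - model$com_local[2, 2] * sin(a_th),
                   model$com_local[2, 1] * sin(a_th) + model$com_local[2, 2] * cos(a_th))
    shank <- p$knee +
      cbind(model$com_local[3, 1] * cos(a_sh) - model$com_local[3, 2] * sin(a_sh),
            model$com_local[3, 1] * sin(a_sh) + model$com_local[3, 2] * cos(a_sh))
    foot <- p$ankle +
      cbind(model$com_local[4, 1] * cos(a_ft) - model$com_local[4, 2] * sin(a_ft),
            model$com_local[4, 1] * sin(a_ft) + model$com_local[4, 2] * cos(a_ft))
    m[2] * thigh + m[3] * shank + m[4] * foot
  }
  hat <- matrix(rep(model$com_local[1, ], each = length(phi)), ncol = 2)
  com <- (m[1] * hat + com_legs(pl, legs$l$ang) + com_legs(pr, legs$r$ang)) /
    sum(m)

  list(ang_l = legs$l$ang, ang_r = legs$r$ang,
       dphase_l = legs$l$dphase, dphase_r = legs$r$dphase,
       z = z_root, x = x, dxdphi = dxdphi, disp = x[length(x)],
       foot_l = (pl$heel + pl$toe) / 2, foot_r = (pr$heel + pr$toe) / 2,
       com = com)
}

# smooth periodic weights for the foot-attitude schedule: `flat` holds the
# foot flat over the stance span (handed over from `reach` across early
# loading [0.02, 0.08], released across heel-off [0.40, 0.52]); `reach`
# pitches the foot toe-up through terminal swing (in from 0.84) until the
# handover after heel strike.  Elsewhere (push-off, early swing) both are
# zero and the template's own ankle curve applies.
.ankle_schedule <- function(phi) {
  p <- phi %% 1
  s <- function(u) { u <- pmin(pmax(u, 0), 1); u^3 * (10 - 15 * u + 6 * u^2) }
  hand <- s((p - 0.02) / 0.06)           # reach -> flat handover
  flat <- hand * (1 - s((p - 0.40) / 0.12))
  reach <- s((p - 0.84) / 0.06) + (p < 0.5) * (1 - hand) * (1 - s((p - 0.40) / 0.12))
  reach <- pmin(reach, 1 - flat)
  list(flat = flat, reach = reach)
}

# smooth periodic stance-weight window: full support over the single-stance
# span, smootherstep hand-over across the double-support windows
# [0, 0.1] (weight onto this foot) and [0.5, 0.6] (weight off it)
.stance_weight <- function(phi) {
  p <- phi %% 1
  sstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u^3 * (10 - 15 * u + 6 * u^2)
  }
  sstep(p / 0.1) * (1 - sstep((p - 0.5) / 0.1))
}

# project a periodic series (sampled on [0, 1] inclusive) onto Fourier
# harmonics <= order with a raised-cosine taper (keeps the top harmonics
# small enough that finite differences of the stored samples reproduce the
# stored derivative); returns the smoothed values and exact phase derivative
.fourier_smooth <- function(u, order = 8) {
  n <- length(u)
  v <- u[-n]
  N <- length(v)
  fh <- fft(v) / N
  k <- if (N %% 2 == 0) c(0:(N / 2 - 1), 0, -((N / 2 - 1):1))
       else c(0:((N - 1) / 2), -(((N - 1) / 2):1))
  w <- ifelse(abs(k) <= order, cos(pi * abs(k) / (2 * (order + 1)))^2, 0)
  fh <- fh * w
  val <- Re(fft(fh, inverse = TRUE))
  dval <- Re(fft(fh * (2i * pi * k), inverse = TRUE))
  list(value = c(val, val[1]), dphase = c(dval, dval[1]))
}

# spectral derivative of a periodic series sampled on [0, 1] inclusive
# (last value duplicates the first); returns d/dphase on the same grid
.spectral_deriv <- function(u) {
  n <- length(u)
  v <- u[-n]
  N <- length(v)
  k <- if (N %% 2 == 0) c(0:(N / 2 - 1), 0, -((N / 2 - 1):1))
       else c(0:((N - 1) / 2), -(((N - 1) / 2):1))
  du <- Re(fft(fft(v) * (2i * pi * k), inverse = TRUE)) / N
  c(du, du[1])
}

.cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Kinematic consistency diagnostics for a reference motion
#'
#' Recomputes the three contract quantities of a reference motion from its
#' stored samples: the worst mismatch between stored joint velocities and a
#' central finite difference of the stored angles, the relative error of
#' the mean forward root speed against the nominal speed, and the
#' periodicity gap between the first and last (phase 0 vs phase 1) joint
#' angle samples.
#'
#' @param motion A `reference_motion` (or a motion loaded from CSV).
#' @param model A `biped_model` whose joint set must match the motion.
#' @return A one-row tibble: `max_velocity_mismatch` (rad/s),
#'   `speed_error_pct`, `periodicity_gap` (rad), per-diagnostic pass flags
#'   and an overall `pass`.
#' @export
check_motion <- function(motion, model) {
  stopifnot(inherits(model, "biped_model"))
  need <- paste0("ang_", model$joints)
  missing_cols <- setdiff(c("phase", need, paste0("vel_", model$joints)),
                          names(motion))
  if (length(missing_cols) > 0)
    abort(paste0("motion is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "treadgait_schema_error")
  T <- attr(motion, "cycle_duration")
  v <- attr(motion, "speed")
  n <- nrow(motion)
  dphi <- motion$phase[2] - motion$phase[1]

  ang <- as.matrix(motion[need])
  vel <- as.matrix(motion[paste0("vel_", model$joints)])
  fd <- (ang[3:n, ] - ang[1:(n - 2), ]) / (2 * dphi * T)
  vel_mis <- max(abs(fd - vel[2:(n - 1), ]))
  speed_err <- abs((motion$root_x[n] - motion$root_x[1]) / T - v) / v * 100
  gap <- max(abs(ang[n, ] - ang[1, ]))
  tibble(max_velocity_mismatch = vel_mis,
         speed_error_pct = speed_err,
         periodicity_gap = gap,
         velocity_ok = vel_mis < 1e-3,
         speed_ok = speed_err < 1,
         periodic_ok = gap < 1e-9,
         pass = vel_mis < 1e-3 & speed_err < 1 & gap < 1e-9)
}
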