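#' Normative sagittal gait template
#'
#' A compact Fourier description (harmonics 0..5) of hip, knee and ankle
#' flexion over one gait cycle, standing in for subject-specific inverse
#' kinematics.  Phase 0 is right heel strike; the left leg reuses the same
#' coefficients half a cycle out of phase (symmetric gait).  The underlying
#' shapes are built from periodic bumps at the usual places: knee
#' stance-loading and swing flexion peaks, ankle push-off plantarflexion,
#' a first-harmonic-dominated hip.  Angles are stored in radians.
#'
#' The cadence model maps walking speed to cycle duration:
#' `T(v) = clamp(T0 + slope * (v - v0), Tmin, Tmax)` with walking defaults
#' `T0 = 1.12 s`, `slope = -0.25 s/(m/s)`, `v0 = 1.05 m/s`, clamp
#' `[0.75, 1.45] s` (normative stride lengths: 0.77 m at 0.63 m/s, 1.18 m
#' at 1.05 m/s, 1.40 m at 1.33 m/s); the running template uses a constant
#' `T = 0.70 s`.
#'
#' @param mode `"walk"` (speeds up to 2 m/s) or `"run"`.
#' @return An object of class `gait_template`: a tibble with columns
#'   `joint`, `harmonic`, `a`, `b` (cosine/sine coefficients, rad), plus
#'   attributes `mode`, `cadence` and `softmin_eps` (the smoothing length,
#'   m, used when the generator ties the pelvis height to the lower foot).
#' @examples
#' tpl <- gait_template()
#' dplyr::count(tpl, joint)
#' @export
gait_template <- function(mode = c("walk", "run")) {
  mode <- match.arg(mode)
  deg <- pi / 180
  if (mode == "walk") {
    shapes <- list(
      hip = function(p) (2 + 16 * cospi(2 * p) + 5 * sinpi(2 * p)
                         - 2 * cospi(4 * p) - 1.5 * sinpi(4 * p)) * deg,
      knee = function(p) (4 + 14 * .bump(p, 0.12, 0.11)
                          + 62 * .bump(p, 0.72, 0.12)) * deg,
      ankle = function(p) (-2 - 10 * .bump(p, 0.58, 0.08)
                           + 3 * .bump(p, 0.75, 0.10)) * deg)
    cadence <- list(T0 = 1.12, slope = -0.25, v0 = 1.05, Tmin = 0.75, Tmax = 1.45)
  } else {
    shapes <- list(
      hip = function(p) (6 + 26 * cospi(2 * p) + 7 * sinpi(2 * p)
                         - 3 * cospi(4 * p)) * deg,
      knee = function(p) (10 + 22 * .bump(p, 0.12, 0.11)
                          + 75 * .bump(p, 0.70, 0.10)) * deg,
      ankle = function(p) (-3 - 20 * .bump(p, 0.50, 0.08)) * deg)
    cadence <- list(T0 = 0.70, slope = 0, v0 = 3.91, Tmin = 0.70, Tmax = 0.70)
  }
  coef <- purrr::map(shapes, .project_fourier, order = 5)
  tpl <- purrr::imap(coef, function(cf, joint)
    tibble(joint = joint, harmonic = 0:5, a = cf$a, b = cf$b)) %>%
    bind_rows()
  structure(tpl, mode = mode, cadence = cadence, softmin_eps = 0.008,
            scale_joint = "hip",
            ankle_order = if (mode == "walk") 8 else 6,
            class = c("gait_template", class(tibble())))
}

# periodic Gaussian-like bump centred at c with width w (phase units)
.bump <- function(p, c, w) {
  d <- ((p - c + 0.5) %% 1) - 0.5
  exp(-0.5 * (d / w)^2)
}

# numeric projection of a periodic shape onto Fourier harmonics 0..order
.project_fourier <- function(f, order = 5, nproj = 512) {
  p <- (seq_len(nproj) - 1) / nproj
  y <- f(p)
  a <- c(mean(y), vapply(1:order, function(h) 2 * mean(y * cospi(2 * h * p)),
                         numeric(1)))
  b <- c(0, vapply(1:order, function(h) 2 * mean(y * sinpi(2 * h * p)),
                   numeric(1)))
  list(a = a, b = b)
}

# evaluate a template joint (Fourier series) and its phase derivative
.eval_fourier <- function(a, b, phase) {
  val <- rep(a[1], length(phase))
  dval <- rep(0, length(phase))
  for (h in 1:(length(a) - 1)) {
    ch <- cospi(2 * h * phase)
    sh <- sinpi(2 * h * phase)
    val <- val + a[h + 1] * ch + b[h + 1] * sh
    dval <- dval + 2 * pi * h * (-a[h + 1] * sh + b[h + 1] * ch)
  }
  list(value = val, dphase = dval)
}

# cycle duration from the cadence model
cycle_duration <- function(template, speed) {
  cad <- attr(template, "cadence")
  min(max(cad$T0 + cad$slope * (speed - cad$v0), cad$Tmin), cad$Tmax)
}
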