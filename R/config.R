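#' Read a trial configuration from a YAML file
#'
#' The file has `model`, `treadmill`, `controller` and `experiment`
#' sections; every field is optional and falls back to the package
#' defaults.  A missing or empty `treadmill` section gives an overground
#' trial; `treadmill: {ideal: true}` gives the kinematic belt.
#'
#' @param path Path to a YAML configuration file.
#' @return A [trial_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path),
          class = "treadgait_io_error")
  cfg <- yaml::read_yaml(path)
  mdl <- cfg$model %||% list()
  tmc <- cfg$treadmill
  ctl <- cfg$controller %||% list()
  exp <- cfg$experiment %||% list()
  speed <- exp$speed %||% 1.05
  environment <- if (is.null(tmc)) "overground" else
    treadmill_spec(tmc$target_speed %||% speed,
                   max_force = tmc$max_force %||% 300,
                   control_freq = tmc$control_freq %||% 17,
                   kp = tmc$kp, kd = tmc$kd,
                   m_belt = tmc$m_belt %||% 10,
                   mu_deck = tmc$mu_deck %||% 0.05,
                   mu = tmc$mu %||% 0.9,
                   ideal = isTRUE(tmc$ideal))
  d <- pd_gains()
  gains <- pd_gains(
    hip = ctl$hip %||% d$hip, knee = ctl$knee %||% d$knee,
    ankle = ctl$ankle %||% d$ankle, tau_max = ctl$tau_max %||% d$tau_max,
    phase_lead = ctl$phase_lead %||% d$phase_lead,
    pitch = ctl$pitch %||% d$pitch, height = ctl$height %||% d$height,
    mass_ref = ctl$mass_ref %||% d$mass_ref)
  trial_config(environment = environment,
               mass = mdl$mass %||% 63, height = mdl$height %||% 1.73,
               speed = speed,
               duration = exp$duration,
               dt = exp$dt %||% 5e-4,
               seed = exp$seed %||% 1L,
               gains = gains,
               stabilizer = ctl$stabilizer %||% TRUE,
               mu = exp$mu %||% 0.9,
               n_transient = exp$n_transient %||% 3)
}

#' Write a trial configuration to a YAML file
#'
#' @param config A [trial_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  tm <- config$environment
  out <- list(
    model = list(mass = config$mass, height = config$height),
    treadmill = if (inherits(tm, "treadmill_spec")) {
      list(target_speed = tm$target_speed, max_force = tm$max_force,
           control_freq = tm$control_freq, kp = tm$kp, kd = tm$kd,
           m_belt = tm$m_belt, mu_deck = tm$mu_deck, mu = tm$mu,
           ideal = tm$ideal)
    },
    controller = list(hip = config$gains$hip, knee = config$gains$knee,
                      ankle = config$gains$ankle,
                      tau_max = config$gains$tau_max,
                      pitch = config$gains$pitch,
                      height = config$gains$height,
                      stabilizer = config$stabilizer),
    experiment = list(speed = config$speed, duration = config$duration,
                      dt = config$dt, seed = config$seed, mu = config$mu,
                      n_transient = config$n_transient))
  yaml::write_yaml(out, path)
  invisible(path)
}
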