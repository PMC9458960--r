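# shared fixtures, built once per test run
model63 <- build_biped(63, 1.73)
ref105 <- generate_reference(model63, 1.05)

joint_cols <- c("hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")
ang_cols <- paste0("ang_", joint_cols)
vel_cols <- paste0("vel_", joint_cols)

# a state lying exactly on the reference at a given row
state_on_reference <- function(ref, row = 1) {
  sim_state(
    q = c(ref$root_x[row], ref$root_z[row], ref$root_pitch[row],
          as.numeric(ref[row, ang_cols])),
    qd = c(ref$root_xd[row], ref$root_zd[row], ref$root_pitchd[row],
           as.numeric(ref[row, vel_cols])))
}

# cached trials (computed on first use)
.trial_cache <- new.env(parent = emptyenv())
cached_trial <- function(key, config) {
  if (is.null(.trial_cache[[key]])) .trial_cache[[key]] <- run_trial(config)
  .trial_cache[[key]]
}
trial_overground_105 <- function() {
  cached_trial("ov105", trial_config(speed = 1.05, reference = ref105))
}
trial_ideal_105 <- function() {
  cached_trial("id105",
               trial_config(environment = treadmill_spec(1.05, ideal = TRUE),
                            speed = 1.05, reference = ref105))
}

# minimal hand-built trial_result for analysis-stage tests
fake_trial <- function(mean_curves, fell = FALSE, cycles = 5) {
  structure(list(mean_curves = mean_curves, fell = fell,
                 retained_cycles = cycles),
            class = "trial_result")
}
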