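test_that("observation vector packs 23 entries deterministically", {
  s <- sim_state(c(0, 0.9, rep(0, 7)))
  obs <- assemble_observation(model63, s, phase = 0.25)
  expect_length(obs, 23)
  expect_equal(unname(obs[paste0("terrain_", 1:5)]), rep(0, 5))
  expect_equal(unname(obs[["phase"]]), 0.25)
  # static state: all velocity entries zero
  expect_equal(unname(obs[c("root_vx", "root_vz", "root_pitch_rate")]),
               rep(0, 3))
  # phase wraps modulo one
  obs2 <- assemble_observation(model63, s, phase = 1.37)
  expect_equal(unname(obs2[["phase"]]), 0.37)
  # terrain function is queried at 5 forward points
  ramp <- assemble_observation(model63, s, 0, terrain = function(x) 0.1 * x)
  expect_equal(unname(ramp[paste0("terrain_", 1:5)]),
               0.1 * seq(0, 1, by = 0.25))
})

test_that("tracking policy interpolates the reference grid", {
  a0 <- tracking_policy(ref105, 0)
  expect_equal(unname(a0), as.numeric(ref105[1, ang_cols]))
  # midway between grid points: linear interpolation of the neighbours
  n <- nrow(ref105)
  ph_mid <- 0.5 * (ref105$phase[11] + ref105$phase[12])
  a_mid <- tracking_policy(ref105, ph_mid)
  hand <- (as.numeric(ref105[11, ang_cols]) +
             as.numeric(ref105[12, ang_cols])) / 2
  expect_equal(unname(a_mid), hand, tolerance = 1e-12)
  # periodicity: phase just under one approaches the phase-zero action
  a_end <- tracking_policy(ref105, 1 - 1e-9)
  expect_equal(unname(a_end), unname(a0), tolerance = 1e-6)
  expect_error(tracking_policy(ref105, 1.0),
               class = "treadgait_invalid_argument")
  expect_error(tracking_policy(dplyr::select(ref105, -"ang_hip_r"), 0.5),
               class = "treadgait_schema_error")
})

test_that("joint PD torques follow kp e minus kd thetadot with saturation", {
  g <- pd_gains(hip = c(300, 15), knee = c(300, 15), ankle = c(100, 5),
                tau_max = 250)
  q <- c(0, 0.9, 0, 0.1, 0.2, 0, -0.1, 0.3, 0.05)
  s0 <- sim_state(q)
  # at the target with zero velocity: zero torque
  expect_equal(joint_pd_torques(g, q[4:9], s0), rep(0, 6))
  # 0.1 rad error on the left hip: kp * e = 30 N m
  tgt <- q[4:9] + c(0.1, 0, 0, 0, 0, 0)
  expect_equal(joint_pd_torques(g, tgt, s0), c(30, rep(0, 5)))
  # saturation: kp * e = 400 clips to 250
  tgt2 <- q[4:9] + c(400 / 300, 0, 0, 0, 0, 0)
  expect_equal(joint_pd_torques(g, tgt2, s0)[1], 250)
  # damping acts on the measured joint velocity
  s1 <- sim_state(q, c(rep(0, 3), 2, rep(0, 5)))
  expect_equal(joint_pd_torques(g, q[4:9], s1)[1], -30)
})

test_that("root stabilizer restores toward the reference and never pushes horizontally", {
  g <- pd_gains(pitch = c(200, 20), height = c(500, 50))
  s_ref <- state_on_reference(ref105, 1)
  w0 <- root_stabilizer(g, s_ref, ref105, 0)
  expect_equal(unname(w0), c(0, 0), tolerance = 1e-9)
  # zero gains: zero wrench anywhere
  g0 <- pd_gains(pitch = c(0, 0), height = c(0, 0))
  s_off <- sim_state(c(0, 0.5, 0.5, rep(0, 6)))
  expect_equal(unname(root_stabilizer(g0, s_off, ref105, 0.3)), c(0, 0))
  # 0.1 rad pitch error with kp = 200: restoring torque 20 N m
  s_p <- state_on_reference(ref105, 1)
  s_p$q[["pitch"]] <- s_p$q[["pitch"]] - 0.1
  w <- root_stabilizer(g, s_p, ref105, 0)
  expect_equal(w[["my"]], 20, tolerance = 1e-9)
  # the wrench has no horizontal component by construction
  expect_named(w, c("fz", "my"))
})

test_that("imitation rewards equal one at an exact match and their closed forms off it", {
  w <- reward_weights()
  expect_equal(w$wp + w$wv + w$we + w$wc, 1)
  s <- state_on_reference(ref105, 1)
  r0 <- imitation_rewards(s, model63, ref105, 0)
  expect_equal(r0$rp, 1, tolerance = 1e-12)
  expect_equal(r0$rv, 1, tolerance = 1e-10)
  expect_equal(r0$re, 1, tolerance = 1e-10)
  expect_equal(r0$rc, 1, tolerance = 1e-10)
  expect_equal(r0$r, 1, tolerance = 1e-10)

  # one joint 0.5 rad off: rp = exp(-2 * 0.25) = exp(-0.5)
  s_j <- state_on_reference(ref105, 1)
  s_j$q[["knee_r"]] <- s_j$q[["knee_r"]] + 0.5
  expect_equal(imitation_rewards(s_j, model63, ref105, 0)$rp, exp(-0.5),
               tolerance = 1e-12)

  # one joint velocity 5 rad/s off: rv = exp(-0.04 * 25) = exp(-1)
  s_v <- state_on_reference(ref105, 1)
  s_v$qd[["hip_l"]] <- s_v$qd[["hip_l"]] + 5
  expect_equal(imitation_rewards(s_v, model63, ref105, 0)$rv, exp(-1),
               tolerance = 1e-12)

  # one foot 0.1 m off (via the reference): re = exp(-40 * 0.01) = exp(-0.4)
  ref_e <- ref105
  ref_e$foot_r_x <- ref_e$foot_r_x + 0.1
  expect_equal(imitation_rewards(s, model63, ref_e, 0)$re, exp(-0.4),
               tolerance = 1e-10)

  # CoM 0.1 m off: rc = exp(-30 * 0.01) = exp(-0.3)
  ref_c <- ref105
  ref_c$com_x <- ref_c$com_x + 0.1
  expect_equal(imitation_rewards(s, model63, ref_c, 0)$rc, exp(-0.3),
               tolerance = 1e-10)

  # the total is the hand-computed weighted sum
  rj <- imitation_rewards(s_j, model63, ref105, 0)
  expect_equal(rj$r, 0.65 * rj$rp + 0.1 * rj$rv + 0.15 * rj$re + 0.1 * rj$rc)
})

test_that("each reward term decreases strictly with its deviation and stays in (0, 1]", {
  s <- state_on_reference(ref105, 1)
  devs <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
  rp <- vapply(devs, function(d) {
    sd <- s
    sd$q[["hip_r"]] <- sd$q[["hip_r"]] + d
    imitation_rewards(sd, model63, ref105, 0)$rp
  }, numeric(1))
  expect_true(all(diff(rp) < 0))
  expect_true(all(rp > 0 & rp <= 1))
  rv <- vapply(devs, function(d) {
    sd <- s
    sd$qd[["knee_l"]] <- sd$qd[["knee_l"]] + 10 * d
    imitation_rewards(sd, model63, ref105, 0)$rv
  }, numeric(1))
  expect_true(all(diff(rv) < 0))
  expect_true(all(rv > 0 & rv <= 1))
})
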