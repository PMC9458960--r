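test_that("gain auto-tuning follows the half-stability-bound rule", {
  s25 <- treadmill_spec(1.05, control_freq = 25, m_belt = 10)
  g25 <- auto_tune_gains(s25)
  expect_equal(g25[["kp"]], 250)
  expect_equal(g25[["kd"]], 1.0)
  s50 <- treadmill_spec(1.05, control_freq = 50, m_belt = 10)
  expect_equal(auto_tune_gains(s50)[["kp"]], 500)
  # the rule always sits at half the discrete stability bound
  for (f in c(10, 13, 17, 25, 50)) {
    sp <- treadmill_spec(1.05, control_freq = f, m_belt = 10)
    expect_equal(sp$kp * (1 / f) / sp$m_belt, 1)
  }
  expect_error(auto_tune_gains(treadmill_spec(1.05, ideal = TRUE)),
               class = "treadgait_invalid_argument")
})

test_that("belt control force saturates, holds between updates, and is zero at target", {
  sp <- treadmill_spec(1.05, max_force = 300, control_freq = 10,
                       kp = 1000, kd = 0)
  b <- belt_state(velocity = 1.05 - 1)  # 1 m/s error
  out <- belt_control_force(sp, b, 0)
  expect_equal(out$force, 300)  # clipped from 1000
  # 5 ms later (period 100 ms): held unchanged even though velocity moved
  out$belt$velocity <- 1.05
  out2 <- belt_control_force(sp, out$belt, 0.005)
  expect_equal(out2$force, 300)
  # at the target with no history: zero force
  sp2 <- treadmill_spec(1.05, kp = 500, kd = 2)
  z <- belt_control_force(sp2, belt_state(velocity = 1.05), 0)
  expect_equal(z$force, 0)
})

test_that("ideal belt is kinematic and the loaded belt balances forces", {
  sp <- treadmill_spec(1.05, ideal = TRUE)
  b <- belt_state(velocity = 0)
  for (i in 1:200) b <- step_belt(sp, b, foot_tangential_load = -500, dt = 1e-3)
  expect_identical(b$velocity, 1.05)
  expect_equal(b$position, 1.05 * 200 * 1e-3)

  # equilibrium: no load, no friction, at speed -> unchanged
  spn <- treadmill_spec(1.05, kp = 1000, kd = 0, mu_deck = 0)
  bn <- belt_state(velocity = 1.05)
  f <- belt_control_force(spn, bn, 0)
  bn <- step_belt(spn, f$belt, 0, 0, dt = 1e-3, v_eps = 0.05)
  expect_lt(abs(bn$velocity - 1.05), 1e-12)
})

test_that("steady-state speed error under constant braking equals F over Kp", {
  sp <- treadmill_spec(1.05, max_force = 1e4, control_freq = 200,
                       kp = 1000, kd = 0, mu_deck = 0)
  dist <- data.frame(time = 0, force = -100)
  sim <- run_belt_sim(sp, dist, horizon = 3, dt = 1e-4)
  err <- 1.05 - tail(sim$speed, 1)
  expect_lt(abs(err - 0.1) / 0.1, 0.01)
})

test_that("belt oracle matches the fixed-step integrator and the continuous closed form", {
  sp <- treadmill_spec(1.05, max_force = 500, control_freq = 25,
                       m_belt = 10, mu_deck = 0)
  dist <- data.frame(time = c(0, 0.5), force = c(0, -200))
  orc <- belt_response_oracle(sp, dist, horizon = 2)
  sim <- run_belt_sim(sp, dist, horizon = 2, dt = 1e-5)
  v_orc <- approx(orc$time, orc$speed, xout = sim$time, rule = 2)$y
  expect_lt(max(abs(v_orc - sim$speed)), 1e-4)

  # continuous-time P-control limit: error decays as (F/Kp)(1 - e^(-Kp t / m))
  spc <- treadmill_spec(1.05, max_force = 1e5, control_freq = 400,
                        kp = 500, kd = 0, m_belt = 10, mu_deck = 0)
  distc <- data.frame(time = 0, force = -150)
  orc2 <- belt_response_oracle(spc, distc, horizon = 0.4)
  tq <- c(0.05, 0.1, 0.2, 0.4)
  pred <- (150 / 500) * (1 - exp(-500 * tq / 10))
  got <- 1.05 - approx(orc2$time, orc2$speed, xout = tq, rule = 2)$y
  expect_equal(got, pred, tolerance = 0.02)

  # zero disturbance: no error ever
  orc0 <- belt_response_oracle(sp, data.frame(time = 0, force = 0), horizon = 1)
  expect_equal(orc0$speed, rep(1.05, nrow(orc0)))
})

test_that("held force respects the saturation limit and the ZOH grid", {
  sp <- treadmill_spec(1.05, max_force = 120, control_freq = 17,
                       m_belt = 10, mu_deck = 0)
  dist <- data.frame(time = c(0, 0.3, 0.5), force = c(0, -300, 0))
  sim <- run_belt_sim(sp, dist, horizon = 1.5, dt = 1e-4)
  expect_true(all(abs(sim$force) <= 120 + 1e-12))
  # force changes only at multiples of the control period
  chg <- sim$time[which(diff(sim$force) != 0) + 1]
  on_grid <- abs(chg * 17 - round(chg * 17)) * (1 / 17)
  expect_lt(max(c(0, on_grid)), 2.5e-4)
})

test_that("peak speed error shrinks with more force and faster control", {
  pulse <- data.frame(time = c(0.2, 0.4), force = c(-300, 0))
  peak_err <- function(fmax, fctrl) {
    sp <- treadmill_spec(1.05, max_force = fmax, control_freq = fctrl,
                         mu_deck = 0)
    sim <- run_belt_sim(sp, pulse, horizon = 1.2, dt = 2e-5)
    max(abs(1.05 - sim$speed))
  }
  # tolerance of 0.02 m/s absorbs ZOH sampling interplay at the saturation edge
  errs_f <- vapply(c(100, 200, 300, 400, 500), peak_err, numeric(1),
                   fctrl = 17)
  expect_true(all(diff(errs_f) <= 0.02))
  errs_h <- vapply(c(10, 13, 17, 25, 50), peak_err, numeric(1), fmax = 300)
  expect_true(all(diff(errs_h) <= 0.02))
})

test_that("treadmill_spec validates its fields", {
  expect_error(treadmill_spec(-1), class = "treadgait_invalid_argument")
  expect_error(treadmill_spec(1, max_force = 0),
               class = "treadgait_invalid_argument")
  expect_error(treadmill_spec(1, control_freq = -5),
               class = "treadgait_invalid_argument")
  expect_silent(treadmill_spec(1, max_force = 0, ideal = TRUE))
})
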