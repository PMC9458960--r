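test_that("gait events are the rising threshold crossings of a square wave", {
  dt <- 0.005
  t <- seq(0, 6, by = dt)
  period <- 1.1
  duty <- 0.6
  fz <- ifelse((t %% period) < duty * period, 400, 0)
  ev <- detect_gait_events(data.frame(time = t, fz = fz), threshold = 20)
  expected <- seq(0, 6, by = period)[-1]  # wave starts high, first rise at t = period
  expect_equal(length(ev$time), length(expected))
  expect_lt(max(abs(ev$time - expected)), dt + 1e-12)
})

test_that("degenerate GRF input yields no events, chatter is debounced", {
  t <- seq(0, 2, by = 0.005)
  empty <- detect_gait_events(data.frame(time = t, fz = rep(0, length(t))))
  expect_equal(nrow(empty), 0)
  # three crossings inside 100 ms collapse to one event
  fz <- rep(0, length(t))
  fz[t >= 1.00 & t < 1.01] <- 50
  fz[t >= 1.03 & t < 1.04] <- 50
  fz[t >= 1.06 & t < 1.50] <- 50
  ev <- detect_gait_events(data.frame(time = t, fz = fz))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, 1.00, tolerance = 0.01)
  expect_error(detect_gait_events(data.frame(time = t, fz = fz), threshold = 0),
               class = "treadgait_invalid_argument")
})

test_that("the stance-confirmation window rejects brief grazes", {
  t <- seq(0, 3, by = 0.005)
  fz <- rep(0, length(t))
  fz[t >= 0.5 & t < 0.56] <- 100   # 60 ms graze
  fz[t >= 1.0 & t < 1.6] <- 500    # true stance
  ev <- detect_gait_events(data.frame(time = t, fz = fz), min_stance = 0.3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, 1.0, tolerance = 0.01)
})

test_that("cycle normalization recovers periodic signals exactly", {
  T <- 1.1
  dt <- 0.002
  t <- seq(0, 5.5, by = dt)
  ser <- data.frame(time = t, ang = sin(2 * pi * t / T))
  events <- seq(0, 5.5, by = T)
  cn <- cycle_normalize(ser, events, n = 101)
  p <- cn$mean$pct / 100
  expect_lt(max(abs(cn$mean$ang - sin(2 * pi * p))), 1e-4)
  # every cycle identical, so the mean equals each cycle
  c1 <- cn$cycles[cn$cycles$cycle == 1, ]
  expect_equal(cn$mean$ang, c1$ang, tolerance = 1e-9)
})

test_that("cycle normalization interpolates linearly and validates inputs", {
  ser <- data.frame(time = seq(0, 2, by = 0.01),
                    ramp = seq(0, 2, by = 0.01))
  cn <- cycle_normalize(ser, c(0, 1), n = 3)
  expect_equal(cn$mean$ramp, c(0, 0.5, 1), tolerance = 1e-9)
  expect_error(cycle_normalize(ser, c(0.5)),
               class = "treadgait_insufficient_cycles")
  expect_error(cycle_normalize(ser, c(0, 1), n = 1),
               class = "treadgait_invalid_argument")
})

test_that("kinematic comparison reports max and RMS of the curve difference", {
  pct <- seq(0, 100, length.out = 101)
  base <- tibble::tibble(pct = pct, hip = 10 * cos(2 * pi * pct / 100),
                         knee = 20 + 5 * sin(2 * pi * pct / 100),
                         ankle = rep(0, 101))
  same <- compare_kinematics(fake_trial(base), fake_trial(base))
  expect_equal(same$max_diff_deg, rep(0, 3))
  expect_equal(same$rms_diff_deg, rep(0, 3))

  # constant 2 degree knee offset
  off <- base
  off$knee <- off$knee + 2
  cmp <- compare_kinematics(fake_trial(off), fake_trial(base))
  expect_equal(cmp$max_diff_deg[cmp$joint == "knee"], 2)
  expect_equal(cmp$rms_diff_deg[cmp$joint == "knee"], 2)
  expect_equal(cmp$max_diff_deg[cmp$joint == "hip"], 0)

  # sinusoidal 3 degree difference: max 3, RMS 3 / sqrt(2)
  sine <- base
  sine$hip <- sine$hip + 3 * sin(2 * pi * pct / 100)
  cmp2 <- compare_kinematics(fake_trial(sine), fake_trial(base))
  expect_equal(cmp2$max_diff_deg[cmp2$joint == "hip"], 3, tolerance = 1e-3)
  expect_equal(cmp2$rms_diff_deg[cmp2$joint == "hip"], 3 / sqrt(2),
               tolerance = 0.01)
})

test_that("RMS never exceeds the maximum difference", {
  set.seed(11)
  pct <- seq(0, 100, length.out = 101)
  for (i in 1:25) {
    a <- tibble::tibble(pct = pct,
                        hip = cumsum(rnorm(101)), knee = cumsum(rnorm(101)),
                        ankle = cumsum(rnorm(101)))
    b <- tibble::tibble(pct = pct,
                        hip = cumsum(rnorm(101)), knee = cumsum(rnorm(101)),
                        ankle = cumsum(rnorm(101)))
    cmp <- compare_kinematics(fake_trial(a), fake_trial(b))
    expect_true(all(cmp$rms_diff_deg <= cmp$max_diff_deg + 1e-12))
  }
})

test_that("falls propagate as missing numbers", {
  pct <- seq(0, 100, length.out = 101)
  base <- tibble::tibble(pct = pct, hip = pct, knee = pct, ankle = pct)
  fell <- fake_trial(NULL, fell = TRUE, cycles = 0)
  cmp <- compare_kinematics(fell, fake_trial(base))
  expect_true(all(is.na(cmp$max_diff_deg)))
  expect_true(attr(cmp, "fell_treadmill"))
  expect_false(attr(cmp, "fell_overground"))
})

test_that("fall detection triggers on root height and trunk pitch thresholds", {
  hh <- model63$standing_hip_height
  t <- seq(0, 5, by = 0.01)
  # steady walking heights: no fall
  ok <- data.frame(time = t, root_z = hh * (0.95 + 0.02 * sin(t)), pitch = 0.1 * sin(t))
  expect_false(detect_fall(ok, model63)$fell)
  # root height ramps below half standing hip height at a known time
  z <- hh * (1 - 0.35 * pmax(t - 1, 0))
  drop <- data.frame(time = t, root_z = z, pitch = 0)
  res <- detect_fall(drop, model63)
  expect_true(res$fell)
  expect_equal(res$time, 1 + 0.5 / 0.35, tolerance = 0.02)
  # trunk pitch passing 60 degrees with normal height
  tip <- data.frame(time = t, root_z = hh,
                    pitch = ifelse(t >= 1.2, 70 * pi / 180, 0))
  res2 <- detect_fall(tip, model63)
  expect_true(res2$fell)
  expect_equal(res2$time, 1.2, tolerance = 0.011)
})

test_that("cycle-normalized GRF balances body weight and vanishes in swing", {
  tr <- trial_overground_105()
  g <- extract_grf(tr, "right")
  gl <- extract_grf(tr, "left")
  # impulse balance: both feet together support one body weight on average
  mean_total <- mean(g$mean$fz) + mean(gl$mean$fz)
  expect_lt(abs(mean_total - 63 * 9.81) / (63 * 9.81), 0.05)
  # swing phase carries no load
  expect_lt(min(g$mean$fz), 1)
  # braking-then-propulsion shape: horizontal GRF has both signs
  expect_lt(min(g$mean$fx), 0)
  expect_gt(max(g$mean$fx), 0)
})
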