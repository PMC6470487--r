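test_that("step length integrates speed over the step", {
  rate <- 400
  t <- seq(0, 2, by = 1 / rate)
  seg <- manual_segment(t, 0.5, 1.0)
  expect_equal(step_length(rep(2, length(t)), t, seg), 1.0, tolerance = 1e-9)
  expect_equal(step_length(numeric(length(t)), t, seg), 0)
  expect_error(step_length(rep(2, length(t)), t,
                           manual_segment(t, 1.5, 2.5)), "outside")
})

test_that("per-step lengths telescope into the total distance", {
  tr <- clean_walk(n_steps = 30)
  anat <- anatomical_series(tr$sensor)
  seg <- segment_steps(anat$v_vertical, anat$t, edge_guard = 0)
  met <- step_metrics_table(anat, anat$v_vertical, seg)
  total <- sum(met$step_length)
  direct <- trapz_between_oracle(anat$t, anat$speed,
                                 min(seg$t_start), max(seg$t_end))
  expect_lt(abs(total - direct) / direct, 0.001)
  # cadence * step_length = 60 * speed_mean (m/min identity)
  expect_lt(max(abs(met$cadence * met$step_length - 60 * met$speed_mean)),
            1e-6)
})

test_that("vertical displacement matches the closed-form integral", {
  rate <- 400
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  A <- 0.5; f <- 1.5
  v <- A * sin(2 * pi * f * t)
  seg <- segment_steps(v, t, edge_guard = 0)
  vd <- vertical_displacement(v, t, seg)
  expect_lt(max(abs(vd$per_step$p2p - 2 * A / (2 * pi * f))), 1e-3)
  # closure residual is pure trapezoid discretization error, O(dt^2)
  expect_lt(max(abs(vd$per_step$closure)), 1e-5)

  vz <- vertical_displacement(numeric(length(t)), t, seg)
  expect_lt(max(abs(vz$series$h)), 1e-12)
  expect_equal(vz$per_step$p2p, rep(0, nrow(seg)))
})

test_that("peak-to-peak speed matches a brute-force scan", {
  rate <- 400
  t <- seq(0, 1, by = 1 / rate)
  seg <- manual_segment(t, 0, 1)
  expect_equal(speed_p2p(rep(3, length(t)), t, seg), 0)
  s <- 3 + 0.2 * sin(2 * pi * t)
  expect_equal(speed_p2p(s, t, seg), 0.4, tolerance = 1e-6)
  set.seed(6)
  r <- runif(length(t), 2, 4)
  expect_equal(speed_p2p(r, t, seg),
               max(r[seg$i_start:seg$i_end]) - min(r[seg$i_start:seg$i_end]),
               tolerance = 1e-9)
})

test_that("forward lean and body rotation summarize orientation per step", {
  rate <- 400
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  seg <- manual_segment(t, 0, 1 - 1 / rate)
  expect_equal(forward_lean(numeric(length(t)), t, seg), 0)
  expect_equal(forward_lean(rep(5 * pi / 180, length(t)), t, seg), 5)
  pitch <- (4 + 1.5 * sin(2 * pi * t)) * pi / 180
  # equals the sample-mean oracle exactly; 4 deg up to edge-sample effects
  oracle <- mean(pitch[seg$i_start:seg$i_end]) * 180 / pi
  expect_equal(forward_lean(pitch, t, seg), oracle, tolerance = 1e-12)
  expect_equal(forward_lean(pitch, t, seg), 4, tolerance = 1e-3)

  psi <- rep(0.3, length(t))
  expect_equal(body_rotation(psi, psi, t, seg), 0)
  yaw <- psi + 6 * pi / 180 * sin(2 * pi * t)
  expect_equal(body_rotation(yaw, psi, t, seg), 12, tolerance = 1e-6)
  # invariant to a constant heading offset on both angles
  expect_equal(body_rotation(yaw + 1, psi + 1, t, seg),
               body_rotation(yaw, psi, t, seg), tolerance = 1e-9)
})

test_that("duty factor and flight metrics follow the contact series", {
  rate <- 400
  t <- seq(0, 0.35, by = 1 / rate)
  n <- length(t)
  cl <- as.integer(t >= 0.05 & t < 0.30)     # 0.25 s stance
  con <- contact_series(t, cl, integer(n), rate = rate)
  seg <- manual_segment(t, 0, 0.35)
  df <- duty_and_flight(con, rep(5, n), t, seg)
  expect_equal(df$contact_time, 0.25, tolerance = 1 / rate)
  expect_equal(df$duty_factor, 100 * df$contact_time / 0.35)
  expect_equal(df$foot, "left")

  # walking with double support never leaves the ground
  trw <- clean_walk(n_steps = 16)
  pipe <- list(anat = anatomical_series(trw$sensor))
  segw <- segment_steps(pipe$anat$v_vertical, pipe$anat$t, edge_guard = 0)
  k <- 8
  dfw <- duty_and_flight(trw$contact, pipe$anat$speed, pipe$anat$t,
                         segw[k, ])
  expect_equal(dfw$flight_time, 0)
  expect_equal(dfw$flight_distance, 0)
  expect_gt(dfw$duty_factor, 100)   # stance spans more than one step

  # running: airborne distance matches the generator's airborne integral
  trr <- generate_gait(gait_scenario("run", n_steps = 16, jitter = 0,
                                     errors = NULL, seed = 8))
  anr <- anatomical_series(trr$sensor)
  segr <- segment_steps(anr$v_vertical, anr$t, edge_guard = 0)
  kk <- 8
  dfr <- duty_and_flight(trr$contact, anr$speed, anr$t, segr[kk, ])
  truth_flight <- (1 - 2 * trr$scenario$duty_factor / 100) *
    trr$truth$steps$duration[kk + 1]
  expect_equal(dfr$flight_time, truth_flight, tolerance = 0.01)
  # oracle: integral of speed over the truly airborne windows, which sit
  # at the step edges (own stance is centred on the step)
  st <- trr$truth$stances[kk + 1, ]
  truth_dist <-
    trapz_between_oracle(anr$t, anr$speed, segr$t_start[kk],
                         st$touchdown) +
    trapz_between_oracle(anr$t, anr$speed, st$toeoff, segr$t_end[kk])
  expect_equal(dfr$flight_distance, truth_dist, tolerance = 0.01)
})

test_that("mechanical energy combines kinetic and potential terms", {
  rate <- 400
  t <- seq(0, 1, by = 1 / rate)
  n <- length(t)
  seg <- manual_segment(t, 0, 1)
  e <- mech_energy(rep(3, n), numeric(n), numeric(n), t, seg, mass = 70)
  expect_equal(e, 0.5 * 70 * 9, tolerance = 1e-9)
  expect_equal(mech_energy(numeric(n), numeric(n), numeric(n), t, seg,
                           mass = 70), 0)
  expect_true(is.na(mech_energy(rep(3, n), numeric(n), numeric(n), t, seg,
                                mass = NULL)))

  # pendular walking: total energy fluctuates less than kinetic alone
  tr <- clean_walk(n_steps = 24)
  anat <- anatomical_series(tr$sensor)
  seg2 <- segment_steps(anat$v_vertical, anat$t, edge_guard = 0)
  vd <- vertical_displacement(anat$v_vertical, anat$t, seg2)
  m <- tr$scenario$mass
  idx <- seg2$i_start[3]:seg2$i_end[nrow(seg2) - 2]
  ke <- 0.5 * m * (anat$speed[idx]^2 + anat$v_vertical[idx]^2)
  tot <- ke + m * 9.81 * vd$series$h[idx]
  expect_lt(stats::var(tot), stats::var(ke))
})

test_that("windowed speeds equal distance over traversal time", {
  rate <- 400
  t <- seq(0, 30, by = 1 / rate)
  n <- length(t)
  ws <- windowed_speed(rep(4, n), t, at_times = c(0, 5, 10),
                       distances = 20)
  expect_equal(ws$speed, rep(4, 3), tolerance = 1e-9)

  # 2 m/s for 10 s then 4 m/s: over the full 80 m, mean = total D / total T
  sp <- ifelse(t < 10, 2, 4)
  D <- pracma::trapz(t, sp)
  ws2 <- windowed_speed(sp, t, at_times = 0, distances = floor(D))
  brute <- floor(D) / (approx(pracma::cumtrapz(t, sp)[, 1], t,
                              xout = floor(D))$y)
  expect_equal(ws2$speed, brute, tolerance = 1e-9)
  # beyond the trial: absent
  expect_true(is.na(windowed_speed(sp, t, 0, distances = 1e4)$speed))
})

test_that("metrics are invariant to shifting the whole trial in time", {
  tr <- clean_walk(n_steps = 12)
  anat <- anatomical_series(tr$sensor)
  seg <- segment_steps(anat$v_vertical, anat$t, edge_guard = 0)
  met <- step_metrics_table(anat, anat$v_vertical, seg)

  anat2 <- anat; anat2$t <- anat$t + 1234.5
  seg2 <- segment_steps(anat2$v_vertical, anat2$t, edge_guard = 0)
  met2 <- step_metrics_table(anat2, anat2$v_vertical, seg2)
  for (col in c("duration", "step_length", "speed_mean", "speed_p2p",
                "vertical_p2p"))
    expect_equal(met2[[col]], met[[col]], tolerance = 1e-6)
})
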