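test_that("apex counts follow cadence arithmetic", {
  tr <- generate_gait(gait_scenario("walk", duration = 60, seed = 21))
  expect_equal(nrow(tr$truth$steps), 120, tolerance = 1)
  expect_equal(length(tr$truth$boundaries), nrow(tr$truth$steps) + 1)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_gait(gait_scenario("walk", n_steps = 10, seed = 33))
  b <- generate_gait(gait_scenario("walk", n_steps = 10, seed = 33))
  expect_identical(a$sensor, b$sensor)
  expect_identical(a$insole, b$insole)
  c <- generate_gait(gait_scenario("walk", n_steps = 10, seed = 34))
  expect_false(identical(a$sensor$v_north, c$sensor$v_north))
})

test_that("noise-free streams segment back to the truth within 1 ms", {
  tr <- clean_walk(n_steps = 40, seed = 22)
  pipe <- segment_gait(tr$sensor)
  reg <- pipe$segments[pipe$segments$quality_flag == "regular", ]
  truth <- tr$truth$steps$t_start
  err <- vapply(reg$t_start, function(x) min(abs(x - truth)), numeric(1))
  expect_lt(max(err), 1e-3)
})

test_that("per-stance impulse balances body weight over the cycle", {
  for (mode in c("walk", "run")) {
    tr <- generate_gait(gait_scenario(mode, n_steps = 24, errors = NULL,
                                      seed = 23))
    st <- tr$truth$stances
    g <- 9.81; m <- tr$scenario$mass
    t <- tr$sensor$t
    fl <- ifelse(tr$contact$contact_left == 1, 1, 0)
    for (k in 6:10) {
      f <- if (st$foot[k] == "left") "force_left" else "force_right"
      # independent quadrature on a dense grid of the emitted insole data
      ins <- resample_insole(tr$insole, 800)
      idx <- ins$t >= st$touchdown[k] & ins$t <= st$toeoff[k]
      imp <- pracma::trapz(ins$t[idx], ins[[f]][idx])
      expect_lt(abs(imp - m * g * tr$truth$steps$duration[k]) /
                  (m * g * tr$truth$steps$duration[k]), 0.05)
    }
    # running implies flight: summed contact below 100% of the cycle
    if (mode == "run") {
      both <- tr$contact$contact_left + tr$contact$contact_right
      expect_lt(mean(both > 0), 1)
      expect_gt(mean(both == 0), 0.1)
    } else {
      expect_gt(mean(tr$contact$contact_left +
                       tr$contact$contact_right == 2), 0.05)
    }
  }
})

test_that("the error model perturbs exactly what it claims", {
  tr <- clean_walk(n_steps = 10, seed = 24)
  zero <- error_model(accel_bias = 0, accel_noise_density = 0,
                      accel_nonlinearity = 0, vel_white_sd = 0,
                      vel_wander_sd = 0, att_noise_deg = 0,
                      heading_noise_deg = 0, gyro_noise_sd = 0,
                      force_noise_sd = 0)
  same <- inject_sensor_errors(tr$sensor, zero, seed = 5)
  for (col in names(as.data.frame(tr$sensor)))
    expect_equal(same[[col]], tr$sensor[[col]], tolerance = 1e-12)

  # bias-only: acceleration channels offset by exactly the bias
  bias_only <- error_model(accel_bias = 0.02, accel_noise_density = 0,
                           accel_nonlinearity = 0, vel_white_sd = 0,
                           vel_wander_sd = 0, att_noise_deg = 0,
                           heading_noise_deg = 0, gyro_noise_sd = 0,
                           force_noise_sd = 0)
  pert <- inject_sensor_errors(tr$sensor, bias_only, seed = 5)
  off <- pert$a_up - tr$sensor$a_up
  expect_lt(max(abs(abs(off) - 0.02)), 1e-12)
  expect_equal(pert$v_north, tr$sensor$v_north)

  # full model keeps the velocity error inside the stated bound
  full <- inject_sensor_errors(tr$sensor, error_model(), seed = 6)
  expect_lt(max(abs(full$v_down - tr$sensor$v_down)), 0.05 + 1e-12)
})

test_that("scenario validation and mixed-mode scheduling", {
  expect_error(gait_scenario("run", duty_factor = 55), "duty_factor < 50")
  expect_error(gait_scenario("walk", insole_rate = 60), "50 or 100")
  tr <- generate_gait(gait_scenario("mixed", duration = 150,
                                    block_seconds = 50, seed = 25))
  expect_setequal(unique(tr$truth$steps$mode), c("walk", "run"))
  # blocks alternate on the block grid
  first_block <- tr$truth$steps$mode[tr$truth$steps$t_start < 49]
  expect_true(all(first_block == "walk"))
})
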