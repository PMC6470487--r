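test_that("zero crossings of a pure sinusoid land on the analytic roots", {
  rate <- 400
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  v <- sin(2 * pi * 1.5 * t)
  cr <- find_zero_crossings(v, t)
  neg <- cr$time[cr$direction < 0]
  expect_equal(length(neg), 6)
  expect_lt(max(abs(neg - c(1, 3, 5, 7, 9, 11) / 3)), 1e-3)

  expect_equal(nrow(find_zero_crossings(rep(1, 100), (1:100) / rate)), 0)

  # additive noise does not create or destroy crossings
  set.seed(5)
  v2 <- 0.4 * sin(2 * pi * 2 * t)
  v2n <- v2 + rnorm(length(t), sd = 0.01)
  expect_equal(nrow(find_zero_crossings(v2n, t)),
               nrow(find_zero_crossings(v2, t)))
})

test_that("step counts follow crossing arithmetic at gait cadences", {
  rate <- 400
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  # walking cadence: 2 Hz step frequency -> 8 apexes, 7 complete steps
  seg2 <- segment_steps(sin(2 * pi * 2 * t), t, edge_guard = 0)
  expect_equal(nrow(seg2), 7)
  expect_true(all(is.finite(seg2$t_midzero)))
  # running cadence: 3 Hz -> 12 apexes, 11 complete steps
  seg3 <- segment_steps(sin(2 * pi * 3 * t), t, edge_guard = 0)
  expect_equal(nrow(seg3), 11)
  # segment count equals negative-going crossings minus one
  cr <- find_zero_crossings(sin(2 * pi * 3 * t), t)
  expect_equal(nrow(seg3), sum(cr$direction < 0) - 1)

  expect_warning(out <- segment_steps(numeric(0), numeric(0)),
                 "fewer than two")
  expect_equal(nrow(out), 0)
})

test_that("segments tile the trial and recover noise-free truth under 1 ms", {
  tr <- clean_walk(n_steps = 50)
  pipe <- segment_gait(tr$sensor)
  seg <- pipe$segments
  # consecutive segments tile with no gaps or overlaps
  expect_lt(max(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)])), 1e-12)
  reg <- seg[seg$quality_flag == "regular", ]
  expect_gt(nrow(reg), 25)
  truth <- tr$truth$steps$t_start
  err <- vapply(reg$t_start, function(x) min(abs(x - truth)), numeric(1))
  expect_lt(max(err), 1e-3)
})

test_that("irregular-motion windows are flagged, not segmented", {
  rate <- 400
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  v <- 0.2 * sin(2 * pi * 2 * t)
  # uniform gait: everything regular
  seg <- reject_irregular(segment_steps(v, t, edge_guard = 0), v, t)
  expect_true(all(seg$quality_flag == "regular"))

  # 2 s standstill in the middle: overlapping segments flagged
  v2 <- v
  v2[t >= 14 & t < 16] <- 0
  seg2 <- reject_irregular(segment_steps(v2, t, edge_guard = 0), v2, t)
  hit <- seg2$t_end > 14 & seg2$t_start < 16
  expect_true(all(seg2$quality_flag[hit] == "irregular"))
  expect_true(any(seg2$quality_flag == "regular"))

  # a lone 3 s "step" trips the duration bound
  seg3 <- data.frame(step = 1L, t_start = 0, t_end = 3, i_start = 1L,
                     i_end = 1200L, t_midzero = 1.5, duration = 3,
                     quality_flag = "regular", stringsAsFactors = FALSE)
  out <- reject_irregular(seg3, v, t)
  expect_equal(out$quality_flag, "irregular")
})

test_that("segmentation is insensitive to non-gait padding at the window edges", {
  rate <- 400
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  v <- 0.25 * sin(2 * pi * 2 * t)
  base <- reject_irregular(segment_steps(v, t, edge_guard = 0), v, t)
  base_reg <- base[base$quality_flag == "regular", ]

  pad <- numeric(4 * rate)
  v2 <- c(pad, v, pad)
  t2 <- seq(0, by = 1 / rate, length.out = length(v2))
  seg2 <- reject_irregular(segment_steps(v2, t2, edge_guard = 0), v2, t2)
  reg2 <- seg2[seg2$quality_flag == "regular", ]
  # same regular steps, shifted by the 4 s prepad
  expect_equal(nrow(reg2), nrow(base_reg))
  expect_lt(max(abs((reg2$t_start - 4) - base_reg$t_start)), 1e-6)
})
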