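test_that("windowing arithmetic and coverage are exact", {
  f <- matrix(rnorm(2401 * 6), ncol = 6)
  b <- make_sequences(f, seq_len = 1201)
  expect_equal(b$starts, c(1, 601, 1201))
  expect_equal(dim(b$x), c(6, 1201, 3))
  expect_equal(sum(!b$mask), 600)

  b1 <- make_sequences(f[1:1201, ], seq_len = 1201)
  expect_equal(b1$starts, 1)
  expect_error(make_sequences(f[1:1000, ], seq_len = 1201), "seq_len")

  # stitching covers every sample after warm-up exactly once
  n <- 3000
  pred <- array(0, dim = c(1, 1201, 0))
  bb <- make_sequences(matrix(rnorm(n * 2), ncol = 2), seq_len = 1201)
  pl <- array(seq_len(1201 * length(bb$starts)),
              dim = c(1, 1201, length(bb$starts)))
  st <- stitch_windows(pl, bb$starts, 1201, n)
  expect_true(all(is.na(st[1:600, 1])))
  expect_true(all(!is.na(st[601:n, 1])))
})

test_that("feature scaling lands inputs in [-1, 1] and is stored", {
  f <- cbind(rnorm(1300, sd = 30), rnorm(1300, sd = 0.1))
  b <- make_sequences(f, seq_len = 401)
  expect_lte(max(abs(b$x)), 1)
  expect_equal(length(b$scaling), 2)
  b2 <- make_sequences(f, seq_len = 401, scaling = b$scaling)
  expect_identical(b$x, b2$x)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  for (type in c("gru", "lstm")) {
    spec <- model_spec(units = c(4, 3), type = type, dropout = 0, seed = 9)
    nf <- 2; Tt <- 7; B <- 3; K <- 2
    params <- gaitkine:::init_params(spec, nf, K)
    x <- array(rnorm(nf * Tt * B), dim = c(nf, Tt, B))
    y <- array(rbinom(K * Tt * B, 1, 0.5), dim = c(K, Tt, B))
    mask <- c(rep(FALSE, 3), rep(TRUE, 4))
    lg <- gaitkine:::net_loss_grads(params, x, y, mask, "contact")
    flat <- gaitkine:::flatten_params(params)
    gflat <- gaitkine:::flatten_params(list(layers = lg$grads$layers,
                                            V = lg$grads$V, d = lg$grads$d))
    eps <- 1e-6; worst <- 0
    for (nm in names(flat)) {
      for (i in seq_len(min(length(flat[[nm]]), 3))) {
        f2 <- flat
        f2[[nm]][i] <- f2[[nm]][i] + eps
        l2 <- gaitkine:::net_loss_grads(
          gaitkine:::unflatten_params(f2, params), x, y, mask,
          "contact")$loss
        f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
        l1 <- gaitkine:::net_loss_grads(
          gaitkine:::unflatten_params(f2, params), x, y, mask,
          "contact")$loss
        num <- (l2 - l1) / (2 * eps)
        worst <- max(worst, abs(num - gflat[[nm]][i]) /
                       max(1e-8, abs(num) + abs(gflat[[nm]][i])))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("the masked loss ignores the warm-up half entirely", {
  set.seed(7)
  spec <- model_spec(units = 5, dropout = 0, seed = 7)
  params <- gaitkine:::init_params(spec, 3, 2)
  x <- array(rnorm(3 * 10 * 4), dim = c(3, 10, 4))
  y <- array(rbinom(2 * 10 * 4, 1, 0.5), dim = c(2, 10, 4))
  mask <- c(rep(FALSE, 5), rep(TRUE, 5))
  for (head in c("contact", "grf")) {
    fwd <- gaitkine:::net_forward(params, x, cache = TRUE)
    ml <- gaitkine:::masked_loss(fwd$logits, y, mask, head)
    # gradient w.r.t. warm-up predictions is exactly zero
    expect_true(all(ml$dlogit[, !mask, ] == 0))
    # perturbing warm-up targets cannot change the loss
    y2 <- y; y2[, !mask, ] <- 1 - y2[, !mask, ]
    ml2 <- gaitkine:::masked_loss(fwd$logits, y2, mask, head)
    expect_identical(ml$loss, ml2$loss)
  }
})

test_that("training fits a toy problem and is seed-deterministic", {
  set.seed(11)
  n <- 400
  f <- cbind(sin(2 * pi * (1:n) / 40), cos(2 * pi * (1:n) / 40))
  targ <- cbind(as.integer(f[, 1] > 0), as.integer(f[, 2] > 0))
  b <- make_sequences(f, targ, seq_len = 41)
  spec <- model_spec(units = 8, dropout = 0, lr = 2e-2, epochs = 50,
                     batch_size = 8, patience = 50, seed = 3)
  m1 <- train_rnn(b, spec, head = "contact")
  expect_lt(min(m1$history$train), 0.05)
  m2 <- train_rnn(b, spec, head = "contact")
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  # constant-target regression collapses to near-zero squared error
  bg <- make_sequences(f, cbind(rep(0.7, n), rep(0.7, n)), seq_len = 41)
  mg <- train_rnn(bg, model_spec(units = 4, dropout = 0, lr = 3e-2,
                                 epochs = 50, batch_size = 8,
                                 patience = 50, seed = 4), head = "grf")
  expect_lt(min(mg$history$val), 1e-3)
})

test_that("predictions are windowing-invariant after warm-up", {
  set.seed(13)
  n <- 4000
  f <- matrix(rnorm(n * 3), ncol = 3)
  spec <- model_spec(units = 6, dropout = 0, seed = 5)
  params <- gaitkine:::init_params(spec, 3, 2)
  model <- structure(list(params = params, spec = spec, head = "grf",
                          scaling = rep(1, 3), seq_len = 1201,
                          n_features = 3, n_outputs = 2),
                     class = "gait_rnn")
  p1 <- predict(model, f)$grf
  p2 <- predict(model, f[301:n, ])$grf
  # compare where both have exited their warm-up regions
  i1 <- 1300:n; i2 <- i1 - 300
  ok <- !is.na(p2[i2, 1]) & !is.na(p1[i1, 1])
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(p1[i1, ][ok, ] - p2[i2, ][ok, ])), 1e-4)

  # ReLU head output is non-negative wherever defined
  expect_gte(min(p1, na.rm = TRUE), 0)
})

test_that("ground contact times come from run lengths with a minimum stance", {
  expect_equal(gct_from_contact(rep(1, 100), rate = 400)$duration, 0.25)
  expect_equal(nrow(gct_from_contact(numeric(50), rate = 400)), 0)
  # sub-minimum blips are discarded
  x <- c(rep(0, 10), rep(1, 5), rep(0, 10), rep(1, 100), rep(0, 10))
  g <- gct_from_contact(x, rate = 400)
  expect_equal(nrow(g), 1)
  expect_equal(g$duration, 0.25)

  # noise-free generator stances are recovered within one sample
  tr <- clean_walk(n_steps = 20)
  g2 <- gct_from_contact(tr$contact$contact_right, t = tr$contact$t)
  ref <- tr$truth$stances[tr$truth$stances$foot == "right", ]
  ref <- ref[ref$touchdown > 0 & ref$toeoff < max(tr$contact$t), ]
  m <- match_stances(g2, ref)
  expect_equal(attr(m, "match_fraction"), 1)
  expect_lt(max(abs(m$pred_gct - m$ref_gct)), 2 / 400 + 1e-9)
})

test_that("nRMSE is range-normalized percent error", {
  x <- rnorm(100)
  expect_equal(nrmse(x, x), 0)
  ref <- c(rep(0, 50), rep(1000, 50))
  expect_equal(nrmse(ref + 50, ref), 5)
  set.seed(14)
  p <- rnorm(200); r <- rnorm(200)
  expect_equal(nrmse(p, r),
               100 * sqrt(mean((p - r)^2)) / (max(r) - min(r)))
  expect_error(nrmse(rnorm(10), rep(1, 10)), "constant")
  expect_error(nrmse(rnorm(9), rnorm(10)), "equal length")
})
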