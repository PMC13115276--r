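test_that("per-sample gradients match central finite differences", {
  set.seed(7)
  n_checked <- 0
  for (kind in c("softmax_regression", "mlp_1hidden")) {
    for (rep in 1:18) {
      d <- sample(2:6, 1)
      k <- sample(2:4, 1)
      p <- init_params(kind, d, k, hidden = 4, seed = rep)
      p$w <- rnorm(length(p$w), sd = 0.5)
      m <- sample(2:5, 1)
      x <- matrix(rnorm(m * d), m, d)
      y <- sample(0:(k - 1), m, replace = TRUE)
      g <- per_sample_gradients(p, x, y)
      for (i in seq_len(m)) {
        num <- fd_gradient(p, x[i, , drop = FALSE], y[i])
        expect_equal(g[i, ], num, tolerance = 1e-5)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 100)
})

test_that("gradients vanish at a perfect prediction and are deterministic", {
  # drive the correct-class logit to dominance: probabilities ~ one-hot
  p <- init_params("softmax_regression", 2, 2)
  p$w <- c(50, -50, 0, 0, 0, 0) # W = [[50, 0, 0], [-50, 0, 0]]
  g <- per_sample_gradients(p, matrix(c(1, 0), 1, 2), 0L)
  expect_lt(max(abs(g)), 1e-15)
  # duplicated example gives identical rows
  x <- matrix(rnorm(6), 3, 2)
  x[2, ] <- x[1, ]
  p$w <- rnorm(6)
  g2 <- per_sample_gradients(p, x, c(1L, 1L, 0L))
  expect_identical(g2[1, ], g2[2, ])
  expect_error(per_sample_gradients(p, matrix(0, 1, 5), 0L), "dimension")
  expect_error(per_sample_gradients(p, x, c(0L, 1L, 5L)), "range")
})

test_that("clipping bounds the norm and preserves direction", {
  g <- c(3, 4)
  expect_equal(clip_gradient(g, 1), c(0.6, 0.8))
  expect_identical(clip_gradient(g, 50), g) # inside the ball: untouched
  expect_identical(clip_gradient(c(0, 0), 1), c(0, 0))
  expect_error(clip_gradient(g, 0), "positive")
  set.seed(1)
  gm <- matrix(rnorm(200, sd = 3), 20, 10)
  cl <- sddsgd:::clip_rows(gm, 2)
  expect_true(all(sqrt(rowSums(cl^2)) <= 2 + 1e-9))
  keep <- sqrt(rowSums(gm^2)) <= 2
  expect_equal(cl[keep, ], gm[keep, ])
})

test_that("privatization adds noise at the stated scale and is reproducible", {
  rows <- rbind(c(1, 1), c(3, 3))
  s <- sddsgd:::rng_stream(5)
  expect_equal(privatize_batch(rows, clip = 1, sigma = 0, s, divisor = 2), c(2, 2))
  # same stream seed twice gives identical output
  out1 <- privatize_batch(rows, 1, 2, sddsgd:::rng_stream(9), divisor = 2)
  out2 <- privatize_batch(rows, 1, 2, sddsgd:::rng_stream(9), divisor = 2)
  expect_identical(out1, out2)
  expect_error(privatize_batch(rows, 1, 1, NULL, 2), "noise_stream")
  # Monte Carlo: std of the aggregate noise under noise_on_sum is sigma*C/B
  stream <- sddsgd:::rng_stream(123)
  b <- 8
  draws <- replicate(2e4, privatize_batch(
    matrix(0, 0, 2), 2, 0.5, stream,
    divisor = b
  )[1])
  expect_equal(sd(draws), 0.5 * 2 / b, tolerance = 0.02)
  # literal_mean puts the same absolute noise on the mean
  stream2 <- sddsgd:::rng_stream(321)
  draws2 <- replicate(2e4, privatize_batch(rows, 2, 0.5, stream2,
    divisor = b, convention = "literal_mean"
  )[1])
  expect_equal(sd(draws2), 0.5 * 2, tolerance = 0.02)
  expect_equal(mean(draws2), 2, tolerance = 0.05)
})

test_that("the SGD update is plain arithmetic", {
  expect_equal(sgd_step(c(1, 1), c(1, -1), 0.5), c(0.5, 1.5))
  expect_equal(sgd_step(c(1, 1), c(0, 0), 0.7), c(1, 1))
  expect_error(sgd_step(c(1, 1), c(1, 1, 1), 0.5), "shape")
})

test_that("the no-privacy limit reproduces a plain SGD reference loop", {
  ds <- desk_dataset(n = 300, seed = 5)
  total <- 60L
  eta <- 0.2
  b <- 32L
  sched <- schedule_config(total,
    gamma = 1, beta = 1, a = 1, rho = 0.3, n = 1,
    sigma0 = 0, c0 = 1e9
  )
  cfg <- train_config(sched,
    learning_rate = eta, batch_size = b,
    sampling = "fixed_size", seed = 77
  )
  fit <- train_dpsgd_static(ds, cfg)
  expect_null(fit$ledger)
  # independent reference: same batch stream, textbook mean softmax gradient
  seeds <- sddsgd:::derive_seeds(77, 3L)
  bstream <- sddsgd:::rng_stream(seeds[1])
  k <- 7L
  d1 <- ncol(ds$features) + 1L
  w <- matrix(0, k, d1)
  for (t in seq_len(total)) {
    idx <- sddsgd:::with_stream(bstream, function() sample.int(nrow(ds$features), b))
    xb <- cbind(ds$features[idx, , drop = FALSE], 1)
    z <- xb %*% t(w)
    z <- z - apply(z, 1, max)
    pr <- exp(z) / rowSums(exp(z))
    oh <- matrix(0, b, k)
    oh[cbind(seq_len(b), ds$labels[idx] + 1L)] <- 1
    w <- w - eta * (t(pr - oh) %*% xb) / b
  }
  expect_equal(fit$params$w, as.numeric(w), tolerance = 1e-12)
})

test_that("a degenerate dual schedule equals the static baseline bit for bit", {
  ds <- desk_dataset(n = 300, seed = 6)
  sched <- schedule_config(50,
    gamma = 1, beta = 1, a = 1, rho = 0.3, n = 1,
    sigma0 = 1.5, c0 = 4
  )
  cfg <- train_config(sched, learning_rate = 0.1, batch_size = 32, seed = 13)
  fit_dual <- train_sdd(ds, cfg)
  fit_static <- train_dpsgd_static(ds, cfg)
  expect_identical(fit_dual$params$w, fit_static$params$w)
  expect_identical(fit_dual$loss_trace, fit_static$loss_trace)
})

test_that("training is reproducible, logs stage transitions, and ledgers match the accountant", {
  ds <- desk_dataset(n = 400, seed = 8)
  sched <- desk_schedule(total = 120, sigma0 = 2, c0 = 5)
  cfg <- train_config(sched, learning_rate = 0.1, batch_size = 48, seed = 21)
  fit1 <- train_sdd(ds, cfg)
  fit2 <- train_sdd(ds, cfg)
  expect_identical(fit1$params$w, fit2$params$w)
  # stage transitions at the cumulative boundaries of the realized table
  tab <- stage_table(sched)
  expect_identical(fit1$stage_log, tab$cumulative_start)
  # ledger totals the executed iterations and feeds the accountant
  expect_identical(sum(fit1$ledger$count), 120L)
  expect_equal(unique(fit1$ledger$q), 48 / 400)
  # calibration round trip: epsilon of the run's own ledger hits the target
  cal <- calibrate_sigma0(8, 1e-3, sched, q = 48 / 400)
  cfg_cal <- train_config(cal$config, learning_rate = 0.1, batch_size = 48, seed = 21)
  fit_cal <- train_sdd(ds, cfg_cal)
  eps_run <- rdp_to_dp(compose_rdp(fit_cal$ledger), 1e-3)$epsilon
  expect_lte(abs(eps_run - 8), 1e-3)
})

test_that("per-iteration clipping caps every per-sample gradient at the stage threshold", {
  ds <- desk_dataset(n = 200, seed = 9)
  sched <- desk_schedule(total = 30, sigma0 = 1, c0 = 0.5)
  tab <- stage_table(sched)
  p <- init_params("softmax_regression", ncol(ds$features), 7)
  p$w <- rnorm(length(p$w))
  for (t in c(0L, tab$cumulative_start[-1], 29L)) {
    cl <- schedule_lookup(tab, t)$clip
    g <- per_sample_gradients(p, ds$features[1:20, ], ds$labels[1:20])
    gc_ <- sddsgd:::clip_rows(g, cl)
    expect_true(all(sqrt(rowSums(gc_^2)) <= cl + 1e-9))
  }
})

test_that("training rejects invalid configurations and aborts on divergence", {
  ds <- desk_dataset(n = 100, seed = 10)
  sched <- desk_schedule(total = 20)
  expect_error(
    train_config(sched, learning_rate = -1),
    "learning_rate"
  )
  cfg_big <- train_config(sched, batch_size = 5000)
  expect_error(train_sdd(ds, cfg_big), "batch_size")
  # absurd learning rate with noise drives the softmax loss to overflow
  cfg_div <- train_config(desk_schedule(total = 300, sigma0 = 5, c0 = 100),
    learning_rate = 1e305, batch_size = 32, seed = 2
  )
  expect_error(train_sdd(ds, cfg_div), "diverged|non-finite")
})
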