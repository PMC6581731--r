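test_that("parameter counts match hand counts and enumeration", {
  expect_identical(count_sae_params(c(32, 64, 12)), 5804L)
  expect_identical(count_sae_params(c(1, 1)), 4L)
  expect_identical(count_sae_params(c(32, 64, 12), mirrored = FALSE), 2892L)
  expect_error(count_sae_params(c(32, 0, 12)), class = "eegemo_argument_error")
  expect_error(count_sae_params(32), class = "eegemo_argument_error")

  set.seed(1)
  for (i in 1:10) {
    widths <- sample(1:20, sample(2:4, 1))
    m <- new_sae(widths, seed = i)
    expect_identical(enumerate_params(m), count_sae_params(widths))
  }
})

test_that("reconstruction is linear and respects widths", {
  m <- new_sae(c(6, 8, 3), seed = 2)
  set.seed(3)
  x <- rnorm(6); y <- rnorm(6)
  lhs <- reconstruct(m, 2.5 * x - 1.5 * y)
  rhs <- 2.5 * reconstruct(m, x) - 1.5 * reconstruct(m, y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(reconstruct(m, rep(0, 6)), rep(0, 6))
  expect_error(reconstruct(m, rnorm(5)), class = "eegemo_argument_error")
})

test_that("adjusted R-squared follows its definition", {
  set.seed(4)
  x <- matrix(rnorm(1000 * 4), 1000, 4)
  self <- adjusted_r2(x, x, p = 32)
  expect_equal(self$r2, 1); expect_equal(self$adjusted_r2, 1)

  # residuals scaled to give R^2 = 0.95 exactly, then Eq. adjustment
  resid <- matrix(rnorm(1000 * 4), 1000, 4)
  resid <- resid * sqrt(0.05 * sum((x - mean(x))^2) / sum(resid^2))
  met <- adjusted_r2(x, x - resid, p = 32, N = 1000)
  expect_equal(met$r2, 0.95, tolerance = 1e-12)
  expect_equal(met$adjusted_r2, 1 - 0.05 * 999 / 967, tolerance = 1e-12)
  expect_equal(met$adjusted_r2, 0.9483, tolerance = 1e-4)

  # predicting the mean gives R^2 = 0, adjusted below zero for N > p + 1
  mu <- matrix(mean(x), nrow(x), ncol(x))
  met0 <- adjusted_r2(x, mu, p = 32, N = 1000)
  expect_equal(met0$r2, 0, tolerance = 1e-12)
  expect_lt(met0$adjusted_r2, 0)
  expect_equal(met0$adjusted_r2, 1 - 999 / 967, tolerance = 1e-12)

  expect_error(adjusted_r2(matrix(1, 100, 2), matrix(1, 100, 2), p = 2),
               class = "eegemo_undefined_metric")
  expect_error(adjusted_r2(x[1:30, ], x[1:30, ], p = 32),
               class = "eegemo_argument_error")
})

test_that("adjusted R-squared never exceeds R-squared when N > p + 1", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(40:200, 1); d <- sample(1:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    xh <- x + matrix(rnorm(n * d, sd = runif(1, 0, 2)), n, d)
    met <- adjusted_r2(x, xh, p = sample(1:30, 1), N = n)
    expect_lte(met$adjusted_r2, met$r2)
    expect_lte(met$r2, 1)
  }
})

test_that("analytic SAE gradients match central finite differences", {
  m <- new_sae(c(3, 4, 2), seed = 6)
  set.seed(7)
  x <- matrix(rnorm(15), 5, 3)
  l1 <- 1e-3; l2 <- 1e-2
  gr <- eegemo:::sae_loss_grad(m, x, lambda_l2 = l2, lambda_l1 = l1)
  lossfn <- function(model) {
    eegemo:::sae_loss_grad(model, x, lambda_l2 = l2, lambda_l1 = l1)$loss
  }
  eps <- 1e-6
  for (l in seq_along(m$W)) {
    for (i in seq_len(length(m$W[[l]]))) {
      mp <- m; mp$W[[l]][i] <- mp$W[[l]][i] + eps
      mm <- m; mm$W[[l]][i] <- mm$W[[l]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(gr$gW[[l]][i], num, tolerance = 1e-5)
    }
    for (i in seq_along(m$b[[l]])) {
      mp <- m; mp$b[[l]][i] <- mp$b[[l]][i] + eps
      mm <- m; mm$b[[l]][i] <- mm$b[[l]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(gr$gb[[l]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training on noiseless rank-12 mixtures reaches the 0.9 criterion", {
  ts <- simulate_trialset(n_trials = 6, duration_s = 16, seed = 11)
  m <- train_sae(ts, control = sae_control(max_samples = 10000), seed = 11)
  expect_true(isTRUE(m$trained))
  expect_gte(m$val_metrics$adjusted_r2, 0.9)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$n_params, 5804)
})

test_that("unpenalised training on noiseless data has a non-increasing loss", {
  ts <- simulate_trialset(n_trials = 2, duration_s = 8, seed = 12)
  ctrl <- sae_control(max_epochs = 15, lambda_l1 = 0, lambda_l2 = 0,
                      target_adj_r2 = 2, max_samples = 4000)
  m <- train_sae(ts, control = ctrl, seed = 12)
  dl <- diff(m$log$val_mse)
  expect_true(all(dl <= 1e-6))
})

test_that("all-zero input is flagged, not fatal", {
  z <- trialset(array(0, c(2, 4, 400)), matrix(5, 2, 2), fs = 128)
  expect_warning(
    m <- train_sae(z, layer_widths = c(4, 6, 2),
                   control = sae_control(max_epochs = 3, max_samples = 500),
                   seed = 13),
    "zero variance")
  expect_true(all(is.na(m$log$val_adj_r2)))
})

test_that("decompose emits n_sources channels and honours overrides", {
  ts <- simulate_trialset(n_trials = 2, duration_s = 4, seed = 14)
  m <- train_sae(ts, control = sae_control(max_epochs = 10, max_samples = 3000),
                 seed = 14)
  est <- decompose(m, ts)
  expect_equal(dim(est$sources), c(2, 12, 512))

  expect_error(decompose(new_sae(seed = 1), ts), class = "eegemo_state_error")

  # encoder fixed to pinv(A): codes reproduce the true sources exactly
  A <- ts$truth$A
  over <- sae_with_encoder(pinv_full_rank(A))
  est2 <- decompose(over, ts)
  expect_equal(est2$sources, ts$truth$sources$sources, tolerance = 1e-8)
})

test_that("a trained model reconstructs in-subspace samples accurately", {
  # R^2 of 0.9 only bounds the relative error by sqrt(0.1) ~ 0.32, so train
  # close to convergence before asking for a 10 % reconstruction error
  ts <- simulate_trialset(n_trials = 4, duration_s = 10, seed = 15)
  m <- train_sae(ts, control = sae_control(max_samples = 6000,
                                           target_adj_r2 = 0.995,
                                           max_epochs = 400, lr = 0.02,
                                           decay_every = 120, lambda_l1 = 0,
                                           lambda_l2 = 0), seed = 15)
  x <- t(ts$data[1, , 1:200])
  xh <- reconstruct(m, x)
  rel_err <- sqrt(sum((x - xh)^2) / sum(x^2))
  expect_lt(rel_err, 0.1)
})
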