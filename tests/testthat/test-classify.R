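test_that("classifier parameter counts match the closed form and enumeration", {
  expect_identical(count_classifier_params(classifier_spec()), 2040376L)
  expect_identical(count_classifier_params(classifier_spec(1, 1, 1, 1, 1)), 16L)
  expect_error(classifier_spec(input_dim = 0), class = "eegemo_argument_error")

  set.seed(1)
  for (i in 1:10) {
    sp <- classifier_spec(input_dim = sample(1:10, 1),
                          seq_len = sample(1:10, 1),
                          lstm_hidden = sample(1:10, 1),
                          fc_units = sample(1:10, 1),
                          output_units = sample(1:3, 1))
    m <- new_classifier(sp, seed = i)
    expect_identical(enumerate_params(m), count_classifier_params(sp))
  }

  # doubling fc_units doubles exactly the FC-dependent terms
  base <- classifier_spec(7, 11, 5, 10, 1)
  dbl <- classifier_spec(7, 11, 5, 20, 1)
  lstm_term <- 4 * ((7 + 5) * 5 + 5)
  expect_identical(count_classifier_params(dbl) - lstm_term - 1L,
                   2L * (count_classifier_params(base) - lstm_term - 1L))
})

test_that("the forward pass matches an independent recurrence oracle", {
  sp <- classifier_spec(input_dim = 2, seq_len = 5, lstm_hidden = 3,
                        fc_units = 2, dropout_lstm = 0, dropout_fc = 0)
  set.seed(2)
  for (i in 1:5) {
    m <- new_classifier(sp, seed = i)
    m$center <- rnorm(2); m$scale <- runif(2, 0.5, 2)
    x <- matrix(rnorm(10), 5, 2)
    expect_equal(classifier_forward(m, x), reference_lstm_forward(m, x),
                 tolerance = 1e-10)
  }
})

test_that("outputs live strictly inside (0, 1) and zero weights give 0.5", {
  sp <- classifier_spec(3, 4, 2, 2, dropout_lstm = 0, dropout_fc = 0)
  m <- new_classifier(sp, seed = 3)
  set.seed(4)
  p <- classifier_forward(m, matrix(rnorm(12), 4, 3))
  expect_gt(p, 0); expect_lt(p, 1)

  m0 <- m
  m0$Wg[] <- 0; m0$bg[] <- 0; m0$Wfc[] <- 0; m0$bfc[] <- 0
  m0$Wout[] <- 0; m0$bout[] <- 0
  expect_equal(classifier_forward(m0, matrix(rnorm(12), 4, 3)), 0.5)
  expect_error(classifier_forward(m, matrix(0, 3, 3)),
               class = "eegemo_argument_error")
})

test_that("analytic classifier gradients match finite differences", {
  sp <- classifier_spec(2, 3, 2, 2, dropout_lstm = 0, dropout_fc = 0)
  m <- new_classifier(sp, seed = 5)
  set.seed(6)
  xt <- lapply(1:3, function(t) matrix(rnorm(4), 2, 2))
  y <- c(1, 0)
  l2 <- 1e-3
  cache <- eegemo:::lstm_forward_batch(m, xt)
  gr <- eegemo:::lstm_backward_batch(m, cache, y, lambda_l2 = l2)
  lossfn <- function(model) {
    out <- eegemo:::lstm_forward_batch(model, xt)$out
    mean((out - y)^2) +
      l2 * (sum(model$Wg^2) + sum(model$Wfc^2) + sum(model$Wout^2))
  }
  eps <- 1e-6
  for (field in c("Wg", "bg", "Wfc", "bfc", "Wout", "bout")) {
    g <- gr[[paste0("g", field)]]
    ix <- seq_len(length(g))
    for (i in ix) {
      mp <- m; mp[[field]][i] <- mp[[field]][i] + eps
      mm <- m; mm[[field]][i] <- mm[[field]][i] - eps
      num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
      expect_equal(unname(g[i]), num, tolerance = 2e-5)
    }
  }
})

test_that("the loss decreases over early steps on a fixed mini-batch", {
  sp <- classifier_spec(4, 10, 6, 6, dropout_lstm = 0, dropout_fc = 0)
  set.seed(7)
  seqs <- lapply(1:8, function(i) matrix(rnorm(40), 10, 4))
  y <- rep(c(0, 1), 4)
  m <- new_classifier(sp, seed = 7)
  xt <- lapply(1:10, function(t)
    do.call(rbind, lapply(seqs, function(s) s[t, ])))
  losses <- numeric(10)
  lr <- 1e-2
  for (step in 1:10) {
    cache <- eegemo:::lstm_forward_batch(m, xt)
    gr <- eegemo:::lstm_backward_batch(m, cache, y)
    losses[step] <- gr$loss
    for (f in c("Wg", "bg", "Wfc", "bfc", "Wout", "bout")) {
      m[[f]] <- m[[f]] - lr * gr[[paste0("g", f)]]
    }
  }
  expect_true(all(diff(losses) < 0))
})

test_that("training separates a linearly separable synthetic contrast", {
  # sequences whose late-half mean shifts with the class
  set.seed(8)
  make_seq <- function(shift) {
    m <- matrix(rnorm(20 * 4, sd = 0.5), 20, 4)
    m[11:20, ] <- m[11:20, ] + shift
    m
  }
  n <- 60
  y <- rep(c(0, 1), n / 2)
  seqs <- lapply(y, function(lab) make_seq(if (lab == 1) 1 else -1))
  sp <- classifier_spec(4, 20, 8, 8, dropout_lstm = 0.1, dropout_fc = 0.1)
  tr <- 1:40; te <- 41:60
  fit <- train_classifier(seqs[tr], y[tr], spec = sp,
                          control = lstm_control(max_epochs = 40,
                                                 stage_epochs = 30,
                                                 batch_size = 8), seed = 8)
  acc <- mean(as.numeric(predict_label(fit, seqs[te]) == "High") == y[te])
  expect_gte(acc, 0.9)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_params, count_classifier_params(sp))
})

test_that("training is bit-reproducible with dropout off and a fixed seed", {
  set.seed(9)
  seqs <- lapply(1:10, function(i) matrix(rnorm(24), 6, 4))
  y <- rep(c(0, 1), 5)
  sp <- classifier_spec(4, 6, 3, 3, dropout_lstm = 0, dropout_fc = 0)
  ctrl <- lstm_control(max_epochs = 5, stage_epochs = 3, batch_size = 4)
  f1 <- train_classifier(seqs, y, spec = sp, control = ctrl, seed = 10)
  f2 <- train_classifier(seqs, y, spec = sp, control = ctrl, seed = 10)
  expect_identical(f1$Wg, f2$Wg)
  expect_identical(f1$Wfc, f2$Wfc)
  expect_identical(f1$log, f2$log)
})

test_that("prediction thresholds follow the documented tie rule", {
  sp <- classifier_spec(2, 3, 2, 2, dropout_lstm = 0, dropout_fc = 0)
  m <- new_classifier(sp, seed = 11)
  m$Wg[] <- 0; m$bg[] <- 0; m$Wfc[] <- 0; m$bfc[] <- 0
  m$Wout[] <- 0; m$bout[] <- 0   # probability exactly 0.5
  s <- matrix(0, 3, 2)
  expect_equal(as.character(predict_label(m, s)), "Low")       # tie -> Low
  expect_equal(as.character(predict_label(m, s, threshold = 0)), "High")
  expect_equal(as.character(predict_label(m, s, threshold = 1)), "Low")
  m$bout[] <- 2   # probability sigmoid(2) ~ 0.88
  expect_equal(as.character(predict_label(m, s)), "High")
})

test_that("single-class label sets warn but still train", {
  set.seed(12)
  seqs <- lapply(1:6, function(i) matrix(rnorm(24), 6, 4))
  sp <- classifier_spec(4, 6, 2, 2, dropout_lstm = 0, dropout_fc = 0)
  expect_warning(
    train_classifier(seqs, rep(1, 6), spec = sp,
                     control = lstm_control(max_epochs = 2, batch_size = 3),
                     seed = 12),
    "single class")
})
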