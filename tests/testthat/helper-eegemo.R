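# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles deliberately avoid the package's own code paths.

# small trialset without going through the generator
tiny_trialset <- function(n_trials = 2, n_channels = 4, n_samples = 256,
                          fs = 128, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_samples),
                dim = c(n_trials, n_channels, n_samples))
  ratings <- cbind(valence = runif(n_trials, 1, 9),
                   arousal = runif(n_trials, 1, 9))
  trialset(data, ratings, fs = fs)
}

# brute-force frame counter: slide every placement and count the full ones
frames_by_enumeration <- function(n_samples, window, step) {
  count <- 0L
  start <- 1L
  while (start + window - 1L <= n_samples) {
    count <- count + 1L
    start <- start + step
  }
  count
}

# independent single-sequence LSTM + FC + sigmoid recurrence, scalar loops
# over gates (no shared code with the package's batched implementation)
reference_lstm_forward <- function(model, x) {
  sp <- model$spec
  H <- sp$lstm_hidden; D <- sp$input_dim; L <- sp$seq_len
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  sig <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, H); cc <- rep(0, H)
  hall <- numeric(0)
  for (t in seq_len(L)) {
    z <- c(xs[t, ], h)
    a <- drop(z %*% model$Wg) + model$bg
    gi <- sig(a[1:H]); gf <- sig(a[(H + 1):(2 * H)])
    gg <- tanh(a[(2 * H + 1):(3 * H)]); go <- sig(a[(3 * H + 1):(4 * H)])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    hall <- c(hall, h)
  }
  fc <- tanh(drop(hall %*% model$Wfc) + model$bfc)
  sig(drop(fc %*% model$Wout) + model$bout)
}

# paired t-test from first principles
reference_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# Moore-Penrose pseudoinverse via the normal equations (full column rank)
pinv_full_rank <- function(A) solve(t(A) %*% A) %*% t(A)

# encoder override: an sae_model whose code equals W_enc %*% x
sae_with_encoder <- function(W_enc, n_hidden = 2 * nrow(W_enc)) {
  k <- nrow(W_enc); d <- ncol(W_enc)
  W1 <- rbind(W_enc, matrix(0, n_hidden - k, d))
  W2 <- cbind(diag(k), matrix(0, k, n_hidden - k))
  W3 <- matrix(0, n_hidden, k)
  W4 <- matrix(0, d, n_hidden)
  sae_model(list(W1, W2, W3, W4),
            list(rep(0, n_hidden), rep(0, k), rep(0, n_hidden), rep(0, d)),
            trained = TRUE)
}
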