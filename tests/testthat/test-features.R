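test_that("frame counts match brute-force window enumeration", {
  expect_equal(n_frames(8064, 128), 125L)
  expect_equal(n_frames(128, 128), 1L)
  expect_equal(n_frames(256, 128), 3L)
  set.seed(1)
  for (i in 1:25) {
    fs <- sample(32:256, 1)
    w_s <- runif(1, 0.25, 2)
    s_s <- runif(1, 0.1, w_s)
    w <- as.integer(round(w_s * fs)); s <- as.integer(round(s_s * fs))
    if (w < 2 || s < 1) next
    n <- sample(w:(w * 20), 1)
    expect_equal(n_frames(n, fs, frame_spec(w_s, s_s)),
                 frames_by_enumeration(n, w, s))
  }
  expect_error(n_frames(100, 128), class = "eegemo_argument_error")
})

test_that("frame_signal slices with the right stride and length", {
  x <- matrix(seq_len(2 * 256), nrow = 2, byrow = TRUE)
  fr <- frame_signal(x, fs = 128)
  expect_length(fr, 3L)
  expect_equal(dim(fr[[1]]), c(2, 128))
  expect_equal(fr[[2]][1, 1], x[1, 65])   # 0.5 s step
  expect_equal(fr[[3]][1, 128], x[1, 256])
})

test_that("the Hanning window matches its closed form", {
  expect_equal(hanning(4), c(0, 0.75, 0.75, 0))
  w <- hanning(65)
  expect_equal(w[1], 0); expect_equal(w[65], 0)
  expect_equal(w[33], 1)  # odd-length midpoint
  k <- 0:127
  expect_equal(hanning(128), 0.5 * (1 - cos(2 * pi * k / 127)))
  expect_error(hanning(1), class = "eegemo_argument_error")
})

test_that("the Welch PSD localises tones and satisfies Parseval", {
  t <- (0:127) / 128
  wp <- welch_psd(sin(2 * pi * 10 * t), fs = 128)
  expect_equal(wp$frequencies[which.max(wp$psd)], 10)
  expect_equal(wp$frequencies[2] - wp$frequencies[1], 1)  # 1 Hz resolution

  expect_true(all(welch_psd(rep(3.7, 128), fs = 128)$psd == 0))
  expect_true(all(welch_psd(rep(0, 128), fs = 128)$psd == 0))

  # integral of the PSD over frequency ~ signal power (white noise); the
  # single-frame estimate is noisy, so compare averages over draws
  set.seed(2)
  ratio <- replicate(10, {
    x <- rnorm(2048)
    wp <- welch_psd(x, fs = 128)
    df <- wp$frequencies[2] - wp$frequencies[1]
    (sum(wp$psd) * df) / (mean((x - mean(x))^2))
  })
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("band powers integrate the right bins and sum to total power", {
  t <- (0:127) / 128
  wp <- welch_psd(sin(2 * pi * 10 * t), fs = 128)
  total <- band_power(wp$frequencies, wp$psd, c(4, 45))
  expect_gte(band_power(wp$frequencies, wp$psd, c(8, 13)) / total, 0.95)

  wp40 <- welch_psd(sin(2 * pi * 40 * t), fs = 128)
  bands <- eeg_bands()
  bp <- vapply(names(bands), function(b)
    band_power(wp40$frequencies, wp40$psd, bands[[b]]), numeric(1))
  expect_equal(names(which.max(bp)), "gamma")

  expect_equal(band_power(wp$frequencies, wp$psd * 0, c(8, 13)), 0)
  expect_error(band_power(wp$frequencies, wp$psd, c(80, 90)),
               class = "eegemo_argument_error")

  # five full bands cover at most the total power
  set.seed(3)
  x <- rnorm(128)
  wpx <- welch_psd(x, fs = 128)
  df <- wpx$frequencies[2] - wpx$frequencies[1]
  all_bands <- sum(vapply(names(bands), function(b)
    band_power(wpx$frequencies, wpx$psd, bands[[b]]), numeric(1)))
  expect_lte(all_bands, sum(wpx$psd) * df + 1e-12)
})

test_that("pcc matches the closed form and its invariances", {
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, y), pcc(y, x))
  expect_equal(pcc(3 * x + 2, y), pcc(x, y))
  expect_equal(pcc(-3 * x + 2, y), -pcc(x, y))
  expect_error(pcc(rep(1, 10), rnorm(10)), class = "eegemo_undefined_metric")
})

test_that("FBP sequences have the documented layout and band concentration", {
  sp <- simulate_sources(1, 2, duration_s = 4, fs = 128, seed = 5,
                         band_profile = list(c(alpha = 1), c(beta = 1)),
                         noise_rel_power = 0)
  fset <- extract_fbp_sequence(sp$sources, fs = 128)
  m <- fset$sequences[[1]]
  expect_equal(dim(m), c(7, 8))  # 4 s -> 7 frames; 2 channels x 4 bands
  expect_equal(colnames(m)[1:4],
               c("ch01_theta", "ch01_alpha", "ch01_beta", "ch01_gamma"))
  # an alpha-band source concentrates its feature mass in the alpha column
  ch1 <- colSums(m[, 1:4])
  expect_gte(ch1[["ch01_alpha"]] / sum(ch1), 0.9)
  ch2 <- colSums(m[, 5:8])
  expect_gte(ch2[["ch02_beta"]] / sum(ch2), 0.9)

  zero <- array(0, c(1, 2, 512))
  fz <- extract_fbp_sequence(zero, fs = 128)
  expect_true(all(fz$sequences[[1]] == 0))
})

test_that("a 63 s 12-source trial yields a 125 x 48 FBP sequence", {
  sp <- simulate_sources(1, 12, duration_s = 63, fs = 128, seed = 6)
  fset <- extract_fbp_sequence(sp$sources, fs = 128)
  expect_equal(dim(fset$sequences[[1]]), c(125, 48))
})

test_that("PCC sequences use the reference channel as documented", {
  arr <- array(0, c(1, 3, 256))
  set.seed(7)
  base <- rnorm(256)
  arr[1, 1, ] <- base; arr[1, 2, ] <- base; arr[1, 3, ] <- base
  fset <- extract_pcc_sequence(arr, fs = 128)
  expect_equal(ncol(fset$sequences[[1]]), 2L)  # n_channels - 1
  expect_true(all(abs(fset$sequences[[1]] - 1) < 1e-12))

  # orthogonal-by-construction reference: correlations stay near zero
  t <- (0:255) / 128
  arr2 <- array(0, c(1, 3, 256))
  arr2[1, 1, ] <- sin(2 * pi * 8 * t)
  arr2[1, 2, ] <- sin(2 * pi * 16 * t)
  arr2[1, 3, ] <- sin(2 * pi * 24 * t)
  f2 <- extract_pcc_sequence(arr2, fs = 128)
  expect_lt(max(abs(f2$sequences[[1]])), 0.1)

  # constant channel -> feature 0, flagged
  arr3 <- arr2; arr3[1, 2, ] <- 5
  f3 <- extract_pcc_sequence(arr3, fs = 128)
  expect_true(all(f3$sequences[[1]][, 1] == 0))
  expect_gt(f3$n_degenerate, 0)

  # pairwise mode has choose(n, 2) columns
  f4 <- extract_pcc_sequence(arr2, fs = 128, pairwise = TRUE)
  expect_equal(ncol(f4$sequences[[1]]), 3L)
  expect_error(extract_pcc_sequence(arr2, fs = 128, reference_channel = 9),
               class = "eegemo_argument_error")
})

test_that("feature sets tidy into long tibbles", {
  sp <- simulate_sources(2, 2, duration_s = 2, fs = 128, seed = 8)
  td <- tidy(extract_fbp_sequence(sp$sources, fs = 128))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("trial", "frame", "feature", "value"))
  expect_equal(nrow(td), 2 * 3 * 8)
})
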