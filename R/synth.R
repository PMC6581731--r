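# Synthetic EEG under the linear scalp-mixing model X = AS: band-limited
# cortical sources with slowly ramping band amplitudes, a distance-decay
# mixing matrix, optional sensor noise, and ratings coupled to the sources'
# band-power dynamics. Ground truth (A, S) is kept so that decomposition
# quality can be scored exactly.

#' Simulate band-limited cortical source signals
#'
#' Each source is a sum of within-band sinusoids (random frequency inside the
#' band, random phase, jittered amplitudes) riding on a small 1/f (pink)
#' background. Band amplitudes are drawn per trial (Rayleigh) and ramp
#' linearly from a start to an end level across the trial, so band power has
#' genuine temporal dynamics that ratings can be coupled to.
#'
#' @param n_trials,n_sources Counts; defaults 1 trial, 12 sources.
#' @param duration_s Trial length in seconds (default 63).
#' @param fs Sampling rate in Hz (default 128).
#' @param seed Integer seed; the panel is a deterministic function of it.
#' @param band_profile Either `NULL` (every source carries all active bands of
#'   `bands` with unit base weight) or a list of length `n_sources` of named
#'   numeric vectors of relative band powers, e.g. `list(c(alpha = 1))`.
#' @param bands A [eeg_bands()] band set.
#' @param n_osc Sinusoids per (source, band); default 3.
#' @param noise_rel_power Pink-noise power relative to oscillatory power
#'   (default 0.1; 0 disables the background).
#' @return A `source_panel`: list with `sources` (array `n_trials x n_sources
#'   x samples`), `fs`, `band_profile`.
#' @examples
#' sp <- simulate_sources(n_trials = 1, n_sources = 2, duration_s = 2,
#'                        fs = 128, seed = 1)
#' dim(sp$sources)
#' @export
simulate_sources <- function(n_trials, n_sources = 12, duration_s = 63,
                             fs = 128, seed = 1, band_profile = NULL,
                             bands = eeg_bands(), n_osc = 3,
                             noise_rel_power = 0.1) {
  n_trials <- check_count(n_trials, "n_trials")
  n_sources <- check_count(n_sources, "n_sources")
  duration_s <- check_positive(duration_s, "duration_s")
  fs <- check_positive(fs, "fs")
  n_osc <- check_count(n_osc, "n_osc")
  noise_rel_power <- check_nonneg(noise_rel_power, "noise_rel_power")
  n_samp <- as.integer(round(duration_s * fs))

  if (is.null(band_profile)) {
    act <- active_bands(bands)
    w <- rep(1, length(act))
    names(w) <- names(act)
    band_profile <- rep(list(w), n_sources)
  }
  if (length(band_profile) != n_sources) {
    stop_arg("`band_profile` must have one entry per source (", n_sources, ")")
  }

  tt <- (seq_len(n_samp) - 1) / fs       # time in s
  tau <- (seq_len(n_samp) - 1) / (n_samp - 1)  # ramp coordinate in [0, 1]
  sources <- array(0, dim = c(n_trials, n_sources, n_samp))

  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      for (j in seq_len(n_sources)) {
        prof <- band_profile[[j]]
        if (is.null(names(prof)) || !all(names(prof) %in% names(bands))) {
          stop_arg("band_profile entries must be named by bands: ",
                   paste(names(bands), collapse = ", "))
        }
        sig <- numeric(n_samp)
        for (b in names(prof)) {
          wgt <- prof[[b]]
          if (wgt < 0) stop_arg("band weights must be nonnegative")
          if (wgt == 0) next
          lim <- bands[[b]]
          lim[2] <- min(lim[2], fs / 2)  # clamp to Nyquist
          # Rayleigh start/end amplitudes -> linear envelope
          a0 <- sqrt(wgt) * sqrt(-2 * log(runif(1)))
          a1 <- sqrt(wgt) * sqrt(-2 * log(runif(1)))
          env <- a0 + (a1 - a0) * tau
          freqs <- runif(n_osc, lim[1], lim[2])
          phases <- runif(n_osc, 0, 2 * pi)
          amps <- runif(n_osc, 0.5, 1.5)
          amps <- amps / sqrt(sum(amps^2) / 2)  # unit mean-square carrier
          carrier <- numeric(n_samp)
          for (k in seq_len(n_osc)) {
            carrier <- carrier + amps[k] * sin(2 * pi * freqs[k] * tt + phases[k])
          }
          sig <- sig + env * carrier
        }
        p_sig <- mean(sig^2)
        if (noise_rel_power > 0) {
          pn <- pink_noise(n_samp)
          # zero-power oscillation (all-zero profile) gets no noise floor so
          # the nonzero-variance invariant can catch it
          sig <- sig + sqrt(noise_rel_power * p_sig) * pn
        }
        if (var(sig) == 0) {
          stop_arg("source ", j, " in trial ", tr, " has zero variance; ",
                   "check its band profile")
        }
        sources[tr, j, ] <- sig
      }
    }
  })

  structure(list(sources = sources, fs = fs, band_profile = band_profile,
                 bands = bands, seed = seed),
            class = "source_panel")
}

# 1/f-amplitude gaussian noise with unit variance, via spectral shaping
pink_noise <- function(n) {
  x <- rnorm(n)
  xf <- fft(x)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)    # mirrored frequency index
  xf <- xf / sqrt(f)
  out <- Re(fft(xf, inverse = TRUE)) / n
  out / sd(out)
}

#' Draw a scalp mixing matrix with distance-decay structure
#'
#' Channels and sources are placed on concentric scalp rings; each entry of
#' `A` is a gaussian decay of the channel-source distance with multiplicative
#' jitter, so every channel mixes a handful of nearby sources strongly.
#' Candidates are rejection-sampled until the condition number is below
#' `cond_max` (keeps the unmixing problem well posed).
#'
#' @param n_channels,n_sources Matrix dimensions (sources must not exceed
#'   channels so `A` can have full column rank).
#' @param seed Integer seed.
#' @param noise_sd Sensor-noise standard deviation later applied by [mix()].
#' @param cond_max Upper bound for the 2-norm condition number (default 100).
#' @return A `mixing_truth`: list with `A` (`n_channels x n_sources`),
#'   `noise_sd` and `seed`.
#' @examples
#' mt <- mixing_truth(seed = 1)
#' dim(mt$A)
#' @export
mixing_truth <- function(n_channels = 32, n_sources = 12, seed = 1,
                         noise_sd = 0, cond_max = 100) {
  n_channels <- check_count(n_channels, "n_channels")
  n_sources <- check_count(n_sources, "n_sources")
  noise_sd <- check_nonneg(noise_sd, "noise_sd")
  cond_max <- check_positive(cond_max, "cond_max")
  if (n_sources > n_channels) {
    stop_arg("n_sources (", n_sources, ") must not exceed n_channels (",
             n_channels, ") for a full-column-rank mixing matrix")
  }
  ang_ch <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  ang_sr <- 2 * pi * (seq_len(n_sources) - 1) / n_sources
  ch_xy <- cbind(cos(ang_ch), sin(ang_ch))
  sr_xy <- 0.75 * cbind(cos(ang_sr), sin(ang_sr))
  d2 <- outer(seq_len(n_channels), seq_len(n_sources), function(i, j) {
    (ch_xy[i, 1] - sr_xy[j, 1])^2 + (ch_xy[i, 2] - sr_xy[j, 2])^2
  })
  sigma <- 0.6  # decay length: each channel sees ~2-4 sources strongly

  A <- with_seed(seed, {
    for (try in seq_len(200L)) {
      jit <- matrix(runif(n_channels * n_sources, 0.6, 1.4),
                    n_channels, n_sources)
      cand <- exp(-d2 / (2 * sigma^2)) * jit
      sv <- svd(cand, nu = 0, nv = 0)$d
      if (sv[n_sources] > 0 && sv[1] / sv[n_sources] < cond_max) break
      cand <- NULL
    }
    if (is.null(cand)) {
      stop_arg("could not draw a mixing matrix with condition number < ",
               cond_max, " in 200 attempts")
    }
    cand
  })
  structure(list(A = A, noise_sd = noise_sd, seed = seed),
            class = "mixing_truth")
}

#' Mix sources into scalp channels
#'
#' Applies the linear mixing model `X = A S` trial by trial and adds i.i.d.
#' gaussian sensor noise of standard deviation `truth$noise_sd`.
#'
#' @param sources A `source_panel` from [simulate_sources()].
#' @param truth A `mixing_truth` from [mixing_truth()].
#' @param ratings Optional `n_trials x 2` matrix (valence, arousal) to attach;
#'   defaults to neutral 5s until [attach_ratings()] is used.
#' @return A [trialset()] with the ground truth stored in its `truth` field.
#' @examples
#' sp <- simulate_sources(2, 3, duration_s = 2, fs = 128, seed = 1)
#' ts <- mix(sp, mixing_truth(8, 3, seed = 2))
#' dim(ts$data)
#' @export
mix <- function(sources, truth, ratings = NULL) {
  if (!inherits(sources, "source_panel")) stop_arg("`sources` must be a source_panel")
  if (!inherits(truth, "mixing_truth")) stop_arg("`truth` must be a mixing_truth")
  dims <- dim(sources$sources)
  n_trials <- dims[1]; n_src <- dims[2]; n_samp <- dims[3]
  if (ncol(truth$A) != n_src) {
    stop_arg("mixing matrix has ", ncol(truth$A), " columns but the panel has ",
             n_src, " sources")
  }
  n_ch <- nrow(truth$A)
  data <- array(0, dim = c(n_trials, n_ch, n_samp))
  with_seed(truth$seed, {
    for (tr in seq_len(n_trials)) {
      x <- truth$A %*% matrix(sources$sources[tr, , ], n_src, n_samp)
      if (truth$noise_sd > 0) {
        x <- x + matrix(rnorm(n_ch * n_samp, sd = truth$noise_sd), n_ch, n_samp)
      }
      data[tr, , ] <- x
    }
  })
  if (is.null(ratings)) ratings <- matrix(5, n_trials, 2,
                                          dimnames = list(NULL, c("valence", "arousal")))
  trialset(data, ratings, fs = sources$fs,
           channel_names = sprintf("Ch%02d", seq_len(n_ch)),
           truth = list(A = truth$A, noise_sd = truth$noise_sd,
                        sources = sources))
}

#' Couple valence/arousal ratings to source band-power dynamics
#'
#' Valence is a monotone function of the trials' late-minus-early
#' alpha+gamma band-power contrast (arousal: beta+gamma overall level),
#' standardised across trials, scaled by `effect_size`, centred at the
#' midpoint 5 of the 1--9 rating scale, perturbed with gaussian noise and
#' clipped to [1, 9]. `effect_size = 0` yields ratings independent of the
#' signals.
#'
#' @param sources A `source_panel`.
#' @param effect_size Nonnegative coupling strength on the rating scale per
#'   standard deviation of contrast (default 3).
#' @param seed Integer seed for the rating noise.
#' @param rating_noise_sd Gaussian noise on the rating scale (default 0.5).
#' @param bands Band set used to measure the contrasts.
#' @return `n_trials x 2` matrix with columns `valence`, `arousal` in [1, 9].
#' @examples
#' sp <- simulate_sources(4, 3, duration_s = 4, fs = 128, seed = 1)
#' attach_ratings(sp, effect_size = 3, seed = 2)
#' @export
attach_ratings <- function(sources, effect_size = 3, seed = 1,
                           rating_noise_sd = 0.5, bands = eeg_bands()) {
  if (!inherits(sources, "source_panel")) stop_arg("`sources` must be a source_panel")
  effect_size <- check_nonneg(effect_size, "effect_size")
  rating_noise_sd <- check_nonneg(rating_noise_sd, "rating_noise_sd")
  dims <- dim(sources$sources)
  n_trials <- dims[1]; n_src <- dims[2]; n_samp <- dims[3]
  fs <- sources$fs

  # frame-wise band powers of the true sources, measured exactly as the
  # features module measures them
  fbp <- extract_fbp_sequence(sources, fs = fs, bands = bands)
  val_con <- numeric(n_trials)
  aro_con <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    m <- fbp$sequences[[tr]]
    nf <- nrow(m)
    early <- colMeans(m[seq_len(nf %/% 2), , drop = FALSE])
    late <- colMeans(m[(nf %/% 2 + 1):nf, , drop = FALSE])
    ag <- grepl("_(alpha|gamma)$", names(early))
    bg <- grepl("_(beta|gamma)$", names(early))
    # late-vs-early contrast of total alpha+gamma power (pooled over
    # sources: a subspace-level quantity that survives linear remixing)
    e_tot <- sum(early[ag]); l_tot <- sum(late[ag])
    val_con[tr] <- (l_tot - e_tot) / (l_tot + e_tot + 1e-12)
    aro_con[tr] <- log(sum(early[bg] + late[bg]) / 2 + 1e-12)
  }

  z <- function(x) {
    if (length(x) < 2L || sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / sd(x)
  }
  ratings <- with_seed(seed, {
    val <- 5 + effect_size * z(val_con) + rnorm(n_trials, sd = rating_noise_sd)
    aro <- 5 + effect_size * z(aro_con) + rnorm(n_trials, sd = rating_noise_sd)
    cbind(valence = pmin(9, pmax(1, val)), arousal = pmin(9, pmax(1, aro)))
  })
  ratings
}

#' Simulate a complete DEAP-shaped trial set
#'
#' Convenience wrapper chaining [simulate_sources()], [mixing_truth()],
#' [mix()] and [attach_ratings()]. The default shape is 40 trials x 32
#' channels x 8064 samples at 128 Hz (63 s per trial) with 12 latent sources.
#'
#' @inheritParams simulate_sources
#' @inheritParams mixing_truth
#' @inheritParams attach_ratings
#' @param n_channels Scalp channels (default 32).
#' @return A [trialset()] carrying its mixing ground truth.
#' @examples
#' ts <- simulate_trialset(n_trials = 2, duration_s = 2, seed = 1)
#' dim(ts$data)
#' @export
simulate_trialset <- function(n_trials = 40, n_channels = 32, n_sources = 12,
                              duration_s = 63, fs = 128, seed = 1,
                              noise_sd = 0, effect_size = 3,
                              rating_noise_sd = 0.5, bands = eeg_bands(),
                              band_profile = NULL, noise_rel_power = 0.1) {
  sp <- simulate_sources(n_trials, n_sources, duration_s, fs, seed = seed,
                         band_profile = band_profile, bands = bands,
                         noise_rel_power = noise_rel_power)
  mt <- mixing_truth(n_channels, n_sources, seed = seed + 1L,
                     noise_sd = noise_sd)
  ratings <- attach_ratings(sp, effect_size = effect_size, seed = seed + 2L,
                            rating_noise_sd = rating_noise_sd, bands = bands)
  mix(sp, mt, ratings = ratings)
}

#' Multi-channel EEG trial container
#'
#' Bundles a `trials x channels x samples` array with per-trial valence and
#' arousal ratings on the 1--9 scale, the sampling rate, channel names and
#' (for synthetic data) the mixing ground truth.
#'
#' @param data 3-D numeric array, `trials x channels x samples`.
#' @param ratings `trials x 2` numeric matrix in [1, 9].
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of length `channels`.
#' @param truth Optional list with ground-truth `A`, `noise_sd` and the
#'   `source_panel` that generated the data.
#' @return An object of class `trialset`.
#' @export
trialset <- function(data, ratings, fs, channel_names = NULL, truth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_arg("`data` must be a 3-D array (trials x channels x samples)")
  }
  if (!all(is.finite(data))) stop_arg("`data` contains non-finite values")
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != dim(data)[1] || ncol(ratings) != 2L) {
    stop_arg("`ratings` must be a trials x 2 matrix (valence, arousal)")
  }
  if (any(ratings < 1 | ratings > 9)) stop_arg("ratings must lie in [1, 9]")
  fs <- check_positive(fs, "fs")
  if (is.null(channel_names)) {
    channel_names <- sprintf("Ch%02d", seq_len(dim(data)[2]))
  }
  if (length(channel_names) != dim(data)[2]) {
    stop_arg("`channel_names` length must equal the channel dimension")
  }
  colnames(ratings) <- c("valence", "arousal")
  structure(list(data = data, ratings = ratings, fs = fs,
                 channel_names = as.character(channel_names), truth = truth),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[3] / x$fs))
  cat(sprintf("  ratings: valence %.2f-%.2f, arousal %.2f-%.2f\n",
              min(x$ratings[, 1]), max(x$ratings[, 1]),
              min(x$ratings[, 2]), max(x$ratings[, 2])))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: %d x %d mixing matrix, sensor noise sd %g\n",
                nrow(x$truth$A), ncol(x$truth$A), x$truth$noise_sd))
  }
  invisible(x)
}
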