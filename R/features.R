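# Frame-wise feature extraction: Hanning-windowed Welch power spectral
# density per 1 s frame (50 % overlap), band powers over the canonical EEG
# rhythm bands, and inter-channel Pearson correlations against a reference
# channel. A 63 s trial at 128 Hz yields the 125-frame sequences consumed by
# the LSTM classifier.

#' Framing specification
#'
#' @param window_s Window length in seconds (default 1).
#' @param step_s Hop between window starts in seconds (default 0.5, i.e.
#'   50 percent overlap).
#' @return A `frame_spec` list.
#' @export
frame_spec <- function(window_s = 1, step_s = 0.5) {
  window_s <- check_positive(window_s, "window_s")
  step_s <- check_positive(step_s, "step_s")
  if (step_s > window_s) stop_arg("`step_s` must not exceed `window_s`")
  structure(list(window_s = window_s, step_s = step_s), class = "frame_spec")
}

#' Number of full frames in a signal
#'
#' `floor((T - W) / S) + 1` with signal length `T`, window `W` and step `S`
#' in samples; trailing partial windows are dropped.
#'
#' @param n_samples Signal length in samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [frame_spec()].
#' @return Integer frame count.
#' @examples
#' n_frames(8064, 128)  # 63 s at 128 Hz -> 125
#' @export
n_frames <- function(n_samples, fs, spec = frame_spec()) {
  n_samples <- check_count(n_samples, "n_samples")
  w <- as.integer(round(spec$window_s * fs))
  s <- as.integer(round(spec$step_s * fs))
  if (n_samples < w) stop_arg("signal (", n_samples,
                              " samples) shorter than the window (", w, ")")
  (n_samples - w) %/% s + 1L
}

#' Slice a multi-channel signal into overlapping frames
#'
#' @param signal `channels x samples` matrix (a plain vector is treated as
#'   one channel).
#' @inheritParams n_frames
#' @return List of `channels x window` matrices, one per frame.
#' @examples
#' x <- matrix(rnorm(2 * 256), 2)
#' length(frame_signal(x, fs = 128))  # 3 frames of 1 s at 0.5 s step
#' @export
frame_signal <- function(signal, fs, spec = frame_spec()) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.matrix(signal)) stop_arg("`signal` must be a channels x samples matrix")
  w <- as.integer(round(spec$window_s * fs))
  s <- as.integer(round(spec$step_s * fs))
  nf <- n_frames(ncol(signal), fs, spec)
  lapply(seq_len(nf), function(k) {
    start <- (k - 1L) * s
    signal[, (start + 1L):(start + w), drop = FALSE]
  })
}

#' Hanning window
#'
#' `w[k] = 0.5 * (1 - cos(2 pi k / (n - 1)))`, `k = 0, ..., n-1`; the
#' spectral-leakage-suppressing taper applied before every PSD estimate.
#'
#' @param n Window length (>= 2).
#' @return Numeric vector of length `n` with zero endpoints.
#' @examples
#' hanning(4)
#' @export
hanning <- function(n) {
  n <- check_count(n, "n", min = 2L)
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' Welch power spectral density of one frame
#'
#' One Hanning-windowed segment spanning the whole frame (a 1 s frame at
#' 128 Hz gives 1 Hz resolution; sub-segmenting such a short frame would
#' halve the resolution and blur the 4--7 Hz theta band). One-sided, with
#' the standard Welch normalisation `|FFT|^2 / (fs * sum(w^2))` and doubling
#' off DC/Nyquist, so that the PSD integrates to the signal's power.
#'
#' @param frame Numeric vector (one channel's samples).
#' @param fs Sampling rate in Hz.
#' @param detrend Remove the frame mean first (default TRUE); the DC bin of
#'   a biosignal frame is offset, not rhythm.
#' @return List with `frequencies` (Hz, 0..fs/2) and `psd` (power/Hz).
#' @examples
#' wp <- welch_psd(sin(2 * pi * 10 * (0:127) / 128), fs = 128)
#' wp$frequencies[which.max(wp$psd)]  # 10 Hz
#' @export
welch_psd <- function(frame, fs, detrend = TRUE) {
  if (!is.numeric(frame) || length(frame) < 2L) {
    stop_arg("`frame` must be a numeric vector of length >= 2")
  }
  fs <- check_positive(fs, "fs")
  psd <- psd_matrix(matrix(frame, ncol = 1), fs, detrend = detrend)
  list(frequencies = attr(psd, "frequencies"), psd = as.vector(psd))
}

# Vectorised one-sided Welch periodogram: columns of `frames` are frames of
# equal length; returns n_freq x n_frames matrix with a "frequencies" attr.
psd_matrix <- function(frames, fs, detrend = TRUE) {
  n <- nrow(frames)
  if (detrend) frames <- sweep(frames, 2, colMeans(frames))
  w <- hanning(n)
  xf <- mvfft(frames * w)
  n_half <- n %/% 2 + 1L
  p <- (Mod(xf[seq_len(n_half), , drop = FALSE])^2) / (fs * sum(w^2))
  # double interior bins (one-sided); DC always single, Nyquist single when n even
  dbl <- rep(2, n_half)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half] <- 1
  p <- p * dbl
  attr(p, "frequencies") <- (seq_len(n_half) - 1) * fs / n
  p
}

#' Power in a frequency band
#'
#' Sums `psd * delta_f` over bins with `band[1] <= f <= band[2]` (both edges
#' inclusive).
#'
#' @param frequencies,psd As returned by [welch_psd()].
#' @param band `c(low, high)` in Hz; must contain at least one bin and lie
#'   below the Nyquist frequency.
#' @return Nonnegative power.
#' @examples
#' wp <- welch_psd(sin(2 * pi * 10 * (0:127) / 128), fs = 128)
#' band_power(wp$frequencies, wp$psd, c(8, 13))
#' @export
band_power <- function(frequencies, psd, band) {
  if (length(band) != 2L || band[1] > band[2]) {
    stop_arg("`band` must be c(low, high) with low <= high")
  }
  if (band[1] > max(frequencies)) {
    stop_arg("band [", band[1], ", ", band[2], "] lies beyond the Nyquist ",
             "frequency ", max(frequencies), " Hz")
  }
  sel <- frequencies >= band[1] & frequencies <= band[2]
  if (!any(sel)) stop_arg("band [", band[1], ", ", band[2],
                          "] contains no frequency bin")
  df <- frequencies[2] - frequencies[1]
  sum(psd[sel]) * df
}

#' Pearson correlation coefficient
#'
#' `sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`; the inter-channel linear-synchrony measure.
#'
#' @param x,y Numeric vectors of equal length with nonzero variance.
#' @return Correlation in [-1, 1].
#' @examples
#' pcc(c(1, 2, 3), c(1, 2, 4))
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop_arg("`x` and `y` must have equal length")
  if (length(x) < 2L) stop_arg("need at least two samples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop(errorCondition("Pearson correlation undefined for a zero-variance input",
                        class = c("eegemo_undefined_metric", "error")))
  }
  cor(x, y)
}

#' Frequency-band-power feature sequences
#'
#' Frames every channel of every trial, estimates the Welch PSD per frame and
#' stacks the active-band powers into a `n_frames x (channels * bands)`
#' matrix per trial. Columns are channel-major: all active bands of channel
#' 1, then channel 2, and so on — 12 sources x 4 bands gives the classifier's
#' 48-wide input.
#'
#' @param x A [trialset()], a `source_estimate` from [decompose()], or a 3-D
#'   `trials x channels x samples` array.
#' @param fs Sampling rate in Hz (taken from `x` when it carries one).
#' @param spec A [frame_spec()].
#' @param bands An [eeg_bands()] band set; its active subset is used.
#' @param log_power Apply `log(power + 1e-12)` (default FALSE).
#' @return A `feature_set`: list of per-trial matrices plus `feature_names`,
#'   `fs`, `spec`.
#' @examples
#' ts <- simulate_trialset(n_trials = 1, n_channels = 4, n_sources = 3,
#'                         duration_s = 2, seed = 1)
#' fs <- extract_fbp_sequence(ts)
#' dim(fs$sequences[[1]])
#' @export
extract_fbp_sequence <- function(x, fs = NULL, spec = frame_spec(),
                                 bands = eeg_bands(), log_power = FALSE) {
  arr <- as_trial_array(x)
  if (is.null(fs)) fs <- attr(arr, "fs")
  if (is.null(fs)) stop_arg("`fs` is required when `x` carries no sampling rate")
  act <- active_bands(bands)
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]; n_samp <- dim(arr)[3]
  w <- as.integer(round(spec$window_s * fs))
  s <- as.integer(round(spec$step_s * fs))
  nf <- n_frames(n_samp, fs, spec)
  starts <- (seq_len(nf) - 1L) * s

  # frame index template and per-band bin masks, shared across channels
  idx <- outer(seq_len(w), starts, `+`)
  freqs <- (seq_len(w %/% 2 + 1L) - 1) * fs / w
  df <- fs / w
  masks <- lapply(act, function(b) {
    sel <- freqs >= b[1] & freqs <= min(b[2], fs / 2)
    if (!any(sel)) stop_arg("band contains no frequency bin at this resolution")
    sel
  })

  feature_names <- as.vector(t(outer(seq_len(n_ch), names(act),
                                     function(i, b) sprintf("ch%02d_%s", i, b))))
  sequences <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    feat <- matrix(0, nf, n_ch * length(act))
    for (ch in seq_len(n_ch)) {
      sig <- arr[tr, ch, ]
      frames <- matrix(sig[idx], nrow = w)
      p <- psd_matrix(frames, fs)
      for (bi in seq_along(masks)) {
        bp <- colSums(p[masks[[bi]], , drop = FALSE]) * df
        feat[, (ch - 1L) * length(act) + bi] <- bp
      }
    }
    if (log_power) feat <- log(feat + 1e-12)
    colnames(feat) <- feature_names
    sequences[[tr]] <- feat
  }
  structure(list(sequences = sequences, feature_names = feature_names,
                 fs = fs, spec = spec, kind = "fbp"),
            class = "feature_set")
}

#' Reference-channel Pearson-correlation feature sequences
#'
#' Per frame, the Pearson correlation between each non-reference channel and
#' the reference channel (`n_channels - 1` features per frame), or all
#' pairwise correlations with `pairwise = TRUE`. A channel that is constant
#' within a frame yields feature 0 and is counted in the `n_degenerate`
#' attribute.
#'
#' @inheritParams extract_fbp_sequence
#' @param reference_channel 1-based reference index (default 1).
#' @param pairwise Use all `choose(n, 2)` pairs instead of the reference mode.
#' @return A `feature_set` (see [extract_fbp_sequence()]).
#' @export
extract_pcc_sequence <- function(x, fs = NULL, spec = frame_spec(),
                                 reference_channel = 1, pairwise = FALSE) {
  arr <- as_trial_array(x)
  if (is.null(fs)) fs <- attr(arr, "fs")
  if (is.null(fs)) stop_arg("`fs` is required when `x` carries no sampling rate")
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]; n_samp <- dim(arr)[3]
  reference_channel <- check_count(reference_channel, "reference_channel")
  if (reference_channel > n_ch) {
    stop_arg("reference channel ", reference_channel, " out of range (",
             n_ch, " channels)")
  }
  w <- as.integer(round(spec$window_s * fs))
  s <- as.integer(round(spec$step_s * fs))
  nf <- n_frames(n_samp, fs, spec)
  starts <- (seq_len(nf) - 1L) * s
  if (pairwise) {
    prs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
    feature_names <- sprintf("pcc_%02d_%02d", prs[, 1], prs[, 2])
  } else {
    others <- setdiff(seq_len(n_ch), reference_channel)
    feature_names <- sprintf("pcc_ref%02d_%02d", reference_channel, others)
  }
  n_degenerate <- 0L
  sequences <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    feat <- matrix(0, nf, length(feature_names))
    for (k in seq_len(nf)) {
      fr <- arr[tr, , (starts[k] + 1L):(starts[k] + w), drop = TRUE]
      sds <- apply(fr, 1, sd)
      cm <- suppressWarnings(cor(t(fr)))
      cm[!is.finite(cm)] <- 0
      n_degenerate <- n_degenerate + sum(sds == 0)
      if (pairwise) {
        feat[k, ] <- cm[upper.tri(cm)]
      } else {
        feat[k, ] <- cm[reference_channel, -reference_channel]
      }
    }
    colnames(feat) <- feature_names
    sequences[[tr]] <- feat
  }
  structure(list(sequences = sequences, feature_names = feature_names,
                 fs = fs, spec = spec, kind = "pcc",
                 n_degenerate = n_degenerate),
            class = "feature_set")
}

# Accept trialset / source_estimate / bare array and return the 3-D array
# with an fs attribute when known.
as_trial_array <- function(x) {
  if (inherits(x, "trialset")) {
    arr <- x$data; attr(arr, "fs") <- x$fs; return(arr)
  }
  if (inherits(x, "source_estimate")) {
    arr <- x$sources; attr(arr, "fs") <- x$fs; return(arr)
  }
  if (inherits(x, "source_panel")) {
    arr <- x$sources; attr(arr, "fs") <- x$fs; return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_arg("`x` must be a trialset, source_estimate, source_panel or 3-D array")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$sequences[[1]])
  cat(sprintf("<feature_set> %s: %d trials x %d frames x %d features\n",
              toupper(x$kind), length(x$sequences), d[1], d[2]))
  invisible(x)
}

#' Tidy a feature set into a long tibble
#'
#' @param x A `feature_set`.
#' @param ... Unused.
#' @return Tibble with columns `trial`, `frame`, `feature`, `value`.
#' @method tidy feature_set
#' @export
tidy.feature_set <- function(x, ...) {
  out <- lapply(seq_along(x$sequences), function(tr) {
    m <- x$sequences[[tr]]
    tibble(trial = tr,
           frame = rep(seq_len(nrow(m)), times = ncol(m)),
           feature = rep(colnames(m), each = nrow(m)),
           value = as.vector(m))
  })
  do.call(rbind, out)
}
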