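#' EEG rhythm band definitions
#'
#' The canonical scalp-EEG frequency bands: delta 0.5--3.5 Hz, theta 4--7 Hz,
#' alpha 8--13 Hz, beta 14--30 Hz and gamma 31--50 Hz. Band-power feature
#' extraction defaults to the theta/alpha/beta/gamma subset because typical
#' affective-EEG recordings are band-pass filtered from 4 Hz upward, which
#' removes the delta range.
#'
#' @param active Character vector naming the bands used for frequency-band
#'   -power (FBP) features. Defaults to theta, alpha, beta and gamma.
#' @return A `band_set`: named list of `c(low, high)` intervals in Hz with an
#'   `active` attribute.
#' @examples
#' eeg_bands()
#' eeg_bands(active = c("alpha", "beta"))
#' @export
eeg_bands <- function(active = c("theta", "alpha", "beta", "gamma")) {
  bands <- list(
    delta = c(0.5, 3.5),
    theta = c(4, 7),
    alpha = c(8, 13),
    beta  = c(14, 30),
    gamma = c(31, 50)
  )
  validate_band_set(bands)
  if (!all(active %in% names(bands))) {
    stop_arg("unknown band name(s): ",
             paste(setdiff(active, names(bands)), collapse = ", "))
  }
  structure(bands, active = active, class = "band_set")
}

validate_band_set <- function(bands) {
  if (length(bands) == 0L || is.null(names(bands))) {
    stop_arg("a band set must be a named list of c(low, high) intervals")
  }
  m <- do.call(rbind, bands)
  if (any(m[, 1] >= m[, 2])) stop_arg("band intervals must satisfy low < high")
  # non-overlapping and increasing
  if (is.unsorted(as.vector(t(m)), strictly = TRUE)) {
    stop_arg("band intervals must be non-overlapping and increasing")
  }
  invisible(bands)
}

active_bands <- function(bands) {
  act <- attr(bands, "active")
  if (is.null(act)) act <- names(bands)
  bands[act]
}
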