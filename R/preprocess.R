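#' Detect blinks on an EOG channel
#'
#' Band-passes the EOG 1-15 Hz (zero-phase, forward-backward), z-scores it,
#' and returns local maxima exceeding `threshold` standard deviations, with a
#' refractory period: within any `refractory_ms` run, only the largest
#' maximum is kept.
#'
#' @param eog EOG series (vector).
#' @param fs Sampling rate (Hz).
#' @param threshold Detection threshold in SD units (default 3).
#' @param refractory_ms Minimum separation between detections.
#' @param band Band-pass edges (Hz).
#' @param filter_order Butterworth order (applied twice by filtfilt).
#' @return Integer vector of blink peak sample indices (1-based, ascending).
#' @export
detect_blinks <- function(eog, fs, threshold = 3, refractory_ms = 200,
                          band = c(1, 15), filter_order = 3) {
  if (sd(eog) == 0) stop("flat EOG channel: zero variance")
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, eog)
  z <- (x - mean(x)) / sd(x)
  n <- length(z)
  i <- 2:(n - 1L)
  peaks <- i[z[i] > z[i - 1L] & z[i] >= z[i + 1L] & z[i] > threshold]
  if (length(peaks) == 0L) return(integer(0))
  # keep the largest peak within each refractory window
  gap <- refractory_ms * fs / 1000
  keep <- integer(0)
  for (p in peaks[order(-z[peaks])]) {
    if (all(abs(p - keep) >= gap)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Remove blink artifacts by spatial template regression
#'
#' Epochs the data channels around each detected blink, averages them into a
#' mean blink time course per channel, extracts the top `n_components`
#' spatial principal components of that average, and projects these
#' topographies out of the continuous data (ordinary least squares across
#' channels at every sample). Events and sampling rate are untouched.
#'
#' @param data `channels x samples` continuous data.
#' @param blink_samples Blink peak sample indices from [detect_blinks()].
#' @param n_components Number of spatial components to remove (default 1).
#' @param fs Sampling rate (Hz).
#' @param window_ms Blink-template window around each peak (default
#'   -200..400 ms).
#' @return List with `data` (cleaned), `topographies`
#'   (`channels x n_components`), and `template` (mean blink,
#'   `channels x samples`).
#' @export
remove_blinks <- function(data, blink_samples, fs, n_components = 1,
                          window_ms = c(-200, 400)) {
  stopifnot(is.matrix(data))
  if (n_components >= nrow(data))
    stop("n_components must be smaller than the number of channels")
  if (length(blink_samples) == 0L)
    return(list(data = data, topographies = NULL, template = NULL))
  off <- round(fs * window_ms[1L] / 1000):(round(fs * window_ms[2L] / 1000) - 1L)
  ok <- blink_samples + min(off) >= 1L & blink_samples + max(off) <= ncol(data)
  bs <- blink_samples[ok]
  if (length(bs) == 0L) stop("no blink falls fully inside the recording")
  template <- matrix(0, nrow(data), length(off))
  for (b in bs) template <- template + data[, b + off, drop = FALSE]
  template <- template / length(bs)
  # spatial PCA of the averaged blink
  sv <- svd(template - rowMeans(template))
  U <- sv$u[, seq_len(n_components), drop = FALSE]
  proj <- U %*% solve(crossprod(U), t(U))
  list(data = data - proj %*% data, topographies = U, template = template)
}

#' Epoch continuous data around events
#'
#' Slices half-open windows `[t_start, t_end)` around each event sample and
#' optionally subtracts the per-channel mean over a baseline window. Events
#' whose window leaves the recording are flagged in the rejection mask (their
#' data are zero-filled), never silently dropped.
#'
#' @param data `channels x samples` continuous data.
#' @param events Event sample indices (1-based).
#' @param fs Sampling rate (Hz).
#' @param window_ms Half-open epoch window (ms) relative to each event.
#' @param baseline_ms Optional baseline window (ms), a sub-interval of
#'   `window_ms`.
#' @param channel_names Optional channel labels.
#' @return An [epochs_container()]; out-of-bounds trials have
#'   `rejected = TRUE`.
#' @export
epoch_data <- function(data, events, fs, window_ms, baseline_ms = NULL,
                       channel_names = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  n_samples <- round(fs * diff(window_ms) / 1000)
  off <- round(fs * window_ms[1L] / 1000) + 0:(n_samples - 1L)
  if (!is.null(baseline_ms)) {
    if (baseline_ms[1L] < window_ms[1L] || baseline_ms[2L] > window_ms[2L])
      stop("baseline window must lie inside the epoch window")
  }
  n_trials <- length(events)
  out <- array(0, c(n_trials, nrow(data), n_samples))
  rejected <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    idx <- events[i] + off
    if (idx[1L] < 1L || idx[length(idx)] > ncol(data)) {
      rejected[i] <- TRUE
      next
    }
    ep <- data[, idx, drop = FALSE]
    if (!is.null(baseline_ms)) {
      t_ms <- window_ms[1L] + 1000 / fs * (0:(n_samples - 1L))
      bidx <- t_ms >= baseline_ms[1L] & t_ms < baseline_ms[2L]
      ep <- ep - rowMeans(ep[, bidx, drop = FALSE])
    }
    out[i, , ] <- ep
  }
  epochs_container(out, fs = fs, window_ms = window_ms,
                   baseline_ms = baseline_ms, channel_names = channel_names,
                   rejected = rejected)
}

#' Automated artifact rejection by peak-to-peak and flatness thresholds
#'
#' Marks epochs whose peak-to-peak range on any channel exceeds
#' `peak_to_peak_limit` or falls below `flat_limit`. The data are untouched;
#' only the rejection mask is updated (OR-ed with any existing mask).
#'
#' @param epochs An [epochs_container()].
#' @param peak_to_peak_limit Upper peak-to-peak bound (> 0).
#' @param flat_limit Lower peak-to-peak bound (> 0, below = flat channel).
#' @return The epochs with an updated `rejected` mask.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_limit, flat_limit = 1e-12) {
  stopifnot(inherits(epochs, "epochs"),
            peak_to_peak_limit > 0, flat_limit > 0)
  ptp <- apply(epochs$data, c(1L, 2L), function(x) diff(range(x)))
  bad <- apply(ptp > peak_to_peak_limit | ptp < flat_limit, 1L, any)
  epochs$rejected <- epochs$rejected | bad
  epochs
}
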