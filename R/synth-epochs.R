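#' Ground truth for synthetic oscillatory epochs
#'
#' Collects the generative parameters of the source-level signal model: a
#' beta-band carrier whose instantaneous amplitude is modulated around `a0`
#' by the standardized trial value regressor (`g_value`, peaking `tau_value`
#' ms after the locking event) and the signed choice regressor (`g_choice`
#' at `tau_choice` ms), under a raised-cosine envelope of width
#' `env_width_ms`, on top of 1/f ("pink") plus white noise. Negative `g`
#' models desynchronization (power decreasing with the regressor).
#'
#' @param g_value,g_choice Fractional amplitude modulation per unit regressor.
#' @param tau_value_ms,tau_choice_ms Effect latencies (ms from locking event).
#' @param env_width_ms Full width of the raised-cosine effect envelope.
#' @param carrier_hz Carrier frequency; default 20 Hz, inside the beta band.
#' @param a0 Baseline carrier amplitude.
#' @param noise_exponent Spectral exponent of the coloured noise (1 = pink).
#' @param noise_pink_sd,noise_white_sd Noise standard deviations.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(g_value = -0.3, g_choice = -0.3,
                         tau_value_ms = 500, tau_choice_ms = 700,
                         env_width_ms = 400, carrier_hz = 20, a0 = 1,
                         noise_exponent = 1, noise_pink_sd = 1,
                         noise_white_sd = 0.5) {
  stopifnot(env_width_ms > 0, carrier_hz > 0, a0 >= 0,
            noise_pink_sd >= 0, noise_white_sd >= 0)
  structure(list(g_value = g_value, g_choice = g_choice,
                 tau_value_ms = tau_value_ms, tau_choice_ms = tau_choice_ms,
                 env_width_ms = env_width_ms, carrier_hz = carrier_hz,
                 a0 = a0, noise_exponent = noise_exponent,
                 noise_pink_sd = noise_pink_sd,
                 noise_white_sd = noise_white_sd),
            class = "ground_truth")
}

# Raised-cosine envelope of full width `width` centred at `center` (ms).
raised_cosine <- function(t_ms, center_ms, width_ms) {
  u <- (t_ms - center_ms) / width_ms
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# Coloured (1/f^exponent power) noise, one column per trial, unit variance
# before scaling. Spectrum shaped in the frequency domain.
pink_noise <- function(n_samples, n_trials, fs, exponent) {
  freqs <- seq(0, fs - fs / n_samples, length.out = n_samples)
  freqs <- pmin(freqs, fs - freqs)           # two-sided frequency axis
  amp <- c(0, freqs[-1L]^(-exponent / 2))    # kill DC
  w <- matrix(rnorm(n_samples * n_trials), n_samples, n_trials)
  x <- Re(mvfft(mvfft(w) * amp, inverse = TRUE)) / n_samples
  sds <- apply(x, 2L, sd)
  sweep(x, 2L, pmax(sds, .Machine$double.eps), "/")
}

#' Epochs container
#'
#' In-memory container for event-locked single-trial data: a
#' `trials x channels x samples` array plus sampling rate, half-open epoch
#' window `[t_start, t_end)` in ms, optional baseline window, trial ids and a
#' rejection mask.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param fs Sampling rate (Hz).
#' @param window_ms Length-2 epoch window (ms), half-open.
#' @param baseline_ms Optional length-2 baseline window (ms) already applied.
#' @param trial_ids Trial identifiers (default 1..n).
#' @param channel_names Channel labels.
#' @param rejected Logical rejection mask per trial.
#' @return An object of class `epochs`.
#' @export
epochs_container <- function(data, fs, window_ms, baseline_ms = NULL,
                             trial_ids = NULL, channel_names = NULL,
                             rejected = NULL) {
  stopifnot(length(dim(data)) == 3L, fs > 0)
  n_expected <- round(fs * diff(window_ms) / 1000)
  if (dim(data)[3L] != n_expected)
    stop(sprintf("window %g..%g ms at %g Hz implies %d samples, got %d",
                 window_ms[1L], window_ms[2L], fs, n_expected, dim(data)[3L]))
  structure(list(
    data = data, fs = fs, window_ms = window_ms, baseline_ms = baseline_ms,
    times_ms = window_ms[1L] + 1000 / fs * (seq_len(dim(data)[3L]) - 1L),
    trial_ids = if (is.null(trial_ids)) seq_len(dim(data)[1L]) else trial_ids,
    channel_names = if (is.null(channel_names))
      paste0("ch", seq_len(dim(data)[2L])) else channel_names,
    rejected = if (is.null(rejected)) rep(FALSE, dim(data)[1L]) else rejected
  ), class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("epochs: %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
              dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L], x$fs,
              x$window_ms[1L], x$window_ms[2L]))
  invisible(x)
}

#' Simulate source-level oscillatory epochs with injected effects
#'
#' Per trial the single (virtual-channel) time series is
#' `A(t) * sin(2 pi f t + phi) + pink + white` with
#' `A(t) = a0 * (1 + g_value * z_v * env(t - tau_value)
#'                 + g_choice * c * env(t - tau_choice))`,
#' where `z_v` is the standardized trial value regressor, `c` the +-1 choice
#' coding, and `env` a raised-cosine envelope. The carrier phase is random
#' per trial so that induced (non-phase-locked) power carries the effect.
#'
#' @param trials Trial table with choices (used for default regressors), or
#'   NULL if `value` and `choice` are given directly.
#' @param truth A [ground_truth()] object.
#' @param fs Sampling rate, default 200 Hz.
#' @param window_ms Half-open epoch window in ms (default -1000..2000,
#'   stimulus-locked convention).
#' @param seed Integer seed.
#' @param value Per-trial value regressor (standardized internally). Default:
#'   objective expected-value difference `p1 m1 - p2 m2` of `trials`.
#' @param choice Per-trial +-1 choice coding. Default: +1 where option 1
#'   was chosen.
#' @return An [epochs_container()] with attributes `value_z` and
#'   `choice_sign` recording the regressors actually injected.
#' @export
simulate_epochs <- function(trials = NULL, truth = ground_truth(), fs = 200,
                            window_ms = c(-1000, 2000), seed = NULL,
                            value = NULL, choice = NULL) {
  if (fs <= 0) stop("sampling rate must be positive")
  if (is.null(value)) {
    if (is.null(trials)) stop("need `trials` or an explicit `value` vector")
    value <- trials$p1 * trials$m1 - trials$p2 * trials$m2
  }
  if (is.null(choice)) {
    if (is.null(trials)) stop("need `trials` or an explicit `choice` vector")
    choice <- ifelse(trials$choice == 1L, 1, -1)
  }
  n_trials <- length(value)
  stopifnot(length(choice) == n_trials, all(choice %in% c(-1, 1)))
  for (tau in c(truth$tau_value_ms, truth$tau_choice_ms))
    if (tau < window_ms[1L] || tau >= window_ms[2L])
      stop("effect latency lies outside the epoch window")
  z_v <- if (sd(value) > 0) (value - mean(value)) / sd(value) else value * 0
  n_samples <- round(fs * diff(window_ms) / 1000)
  t_ms <- window_ms[1L] + 1000 / fs * (0:(n_samples - 1L))
  env_v <- raised_cosine(t_ms, truth$tau_value_ms, truth$env_width_ms)
  env_c <- raised_cosine(t_ms, truth$tau_choice_ms, truth$env_width_ms)
  with_seed(seed, {
    # amplitude: samples x trials
    amp <- truth$a0 *
      (1 + outer(env_v, truth$g_value * z_v) +
           outer(env_c, truth$g_choice * choice))
    phi <- runif(n_trials, 0, 2 * pi)
    carrier <- sin(outer(2 * pi * truth$carrier_hz * t_ms / 1000,
                         phi, "+"))
    x <- amp * carrier
    if (truth$noise_pink_sd > 0)
      x <- x + truth$noise_pink_sd *
        pink_noise(n_samples, n_trials, fs, truth$noise_exponent)
    if (truth$noise_white_sd > 0)
      x <- x + truth$noise_white_sd * matrix(rnorm(n_samples * n_trials),
                                             n_samples, n_trials)
    ep <- epochs_container(array(t(x), c(n_trials, 1L, n_samples)),
                           fs = fs, window_ms = window_ms,
                           trial_ids = if (is.null(trials)) seq_len(n_trials)
                                       else trials$trial_id,
                           channel_names = "virtual")
    attr(ep, "value_z") <- z_v
    attr(ep, "choice_sign") <- choice
    ep
  })
}

#' Inject stereotyped blinks into an EOG channel and data channels
#'
#' Blink events are drawn from a Poisson process (with a refractory gap); each
#' adds a raised-cosine pulse of `amplitude` (default 8 background SDs) to the
#' EOG channel and the same time course scaled by a fixed spatial `topography`
#' to the data channels.
#'
#' @param eog Background EOG series (vector).
#' @param data Optional `channels x samples` matrix to contaminate.
#' @param fs Sampling rate (Hz).
#' @param rate Blink rate (events per second), >= 0.
#' @param topography Per-channel blink gains; default linearly decaying.
#' @param amplitude Pulse peak; default `8 * sd(eog)`.
#' @param width_ms Pulse full width.
#' @param min_gap_ms Minimum separation between blink peaks.
#' @param seed Integer seed.
#' @return List with `eog`, `data`, `blink_samples` (peak sample indices,
#'   1-based), and `course` (the full-length added EOG time course).
#' @export
inject_blinks <- function(eog, data = NULL, fs, rate, topography = NULL,
                          amplitude = NULL, width_ms = 150, min_gap_ms = 500,
                          seed = NULL) {
  stopifnot(rate >= 0, fs > 0)
  n <- length(eog)
  if (is.null(amplitude)) amplitude <- 8 * sd(eog)
  half <- round(fs * width_ms / 2000)
  with_seed(seed, {
    k <- rpois(1L, rate * n / fs)
    peaks <- integer(0)
    if (k > 0) {
      cand <- sort(sample((half + 1L):(n - half), k))
      keep <- diff(c(-Inf, cand)) * 1000 / fs >= min_gap_ms
      peaks <- cand[keep]
    }
    course <- numeric(n)
    for (p in peaks) {
      idx <- (p - half):(p + half)
      course[idx] <- course[idx] +
        amplitude * raised_cosine(idx, p, 2 * half)
    }
    if (!is.null(data)) {
      if (is.null(topography))
        topography <- seq(1, 0.2, length.out = nrow(data))
      data <- data + topography %o% course
    }
    list(eog = eog + course, data = data, blink_samples = peaks,
         course = course, topography = if (is.null(data)) NULL else topography)
  })
}
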