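#' Time-frequency decomposition configuration
#'
#' @param freqs Analysis frequencies (Hz), strictly increasing; default 40
#'   bins linearly spaced 1-40 Hz.
#' @param morlet_factor Number of carrier cycles per Gaussian SD of the
#'   wavelet ("Morlet factor"), > 1; default 5.
#' @param beta_band Beta-band limits (Hz) used by band summaries.
#' @return An object of class `tf_config`.
#' @export
tf_config <- function(freqs = seq(1, 40, length.out = 40), morlet_factor = 5,
                      beta_band = c(13, 30)) {
  stopifnot(all(freqs > 0), all(diff(freqs) > 0), morlet_factor > 1)
  structure(list(freqs = freqs, morlet_factor = morlet_factor,
                 beta_band = beta_band), class = "tf_config")
}

#' Morlet wavelet basis for fixed epoch geometry
#'
#' Precomputes the (conjugated, unit-energy) complex Morlet wavelets placed
#' at every requested output time, as one `n_samples x (n_freqs * n_times)`
#' matrix, so that single-trial spectral amplitudes are one matrix product
#' (`trials x samples` data times the basis). The wavelet at frequency `f`
#' has Gaussian SD `morlet_factor / (2 pi f)` in time and is truncated at
#' +-3 SD; output bins whose wavelet support leaves the epoch are flagged as
#' unreliable edges.
#'
#' Precomputing the basis once and reusing it across subjects is what makes
#' large permutation/replication studies affordable.
#'
#' @param fs Sampling rate (Hz).
#' @param n_samples Samples per epoch.
#' @param window_ms Epoch window (ms), half-open.
#' @param cfg A [tf_config()].
#' @param time_step_ms Output time-grid step (default 25 ms).
#' @param time_range_ms Optional output time range (ms, inclusive of start;
#'   default the whole epoch).
#' @return An object of class `morlet_basis` with elements `W` (complex),
#'   `freqs`, `times_ms`, `edge` (logical `freqs x times` flag matrix).
#' @export
morlet_basis <- function(fs, n_samples, window_ms, cfg = tf_config(),
                         time_step_ms = 25, time_range_ms = NULL) {
  if (any(cfg$freqs >= fs / 2))
    stop("analysis frequencies must lie below the Nyquist frequency")
  t_ms <- window_ms[1L] + 1000 / fs * (0:(n_samples - 1L))
  if (is.null(time_range_ms)) time_range_ms <- c(t_ms[1L], t_ms[n_samples])
  times_ms <- seq(time_range_ms[1L], time_range_ms[2L], by = time_step_ms)
  centers <- round((times_ms - window_ms[1L]) * fs / 1000) + 1L
  stopifnot(all(centers >= 1L), all(centers <= n_samples))
  nf <- length(cfg$freqs); nt <- length(times_ms)
  W <- matrix(0 + 0i, n_samples, nf * nt)
  edge <- matrix(FALSE, nf, nt)
  for (fi in seq_len(nf)) {
    f <- cfg$freqs[fi]
    sd_samp <- cfg$morlet_factor / (2 * pi * f) * fs
    half <- ceiling(3 * sd_samp)
    off <- (-half):half
    w <- exp(-off^2 / (2 * sd_samp^2)) *
      exp(-2i * pi * f * off / fs)          # conjugate wavelet
    for (ti in seq_len(nt)) {
      c0 <- centers[ti]
      lo <- max(1L, c0 - half); hi <- min(n_samples, c0 + half)
      seg <- w[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
      seg <- seg / sqrt(sum(Mod(seg)^2))    # unit energy
      W[lo:hi, (fi - 1L) * nt + ti] <- seg
      edge[fi, ti] <- (c0 - half < 1L) || (c0 + half > n_samples)
    }
  }
  # real/imaginary parts kept separately: power needs two real matrix
  # products instead of one complex one (half the floating-point work)
  structure(list(Wr = Re(W), Wi = Im(W), freqs = cfg$freqs,
                 times_ms = times_ms, edge = edge, fs = fs,
                 n_samples = n_samples, window_ms = window_ms),
            class = "morlet_basis")
}

#' Single-trial Morlet wavelet power
#'
#' Convolves every trial with complex Morlet wavelets and returns the squared
#' magnitude: an instantaneous power estimate per trial, frequency and output
#' time point. Edge bins within half the (truncated) wavelet support of the
#' epoch boundary are flagged and excluded from downstream cluster statistics.
#'
#' @param epochs An [epochs_container()] (single channel, or pick `channel`).
#' @param cfg A [tf_config()].
#' @param channel Channel index to decompose (default 1).
#' @param basis Optional precomputed [morlet_basis()] (must match geometry);
#'   built on the fly otherwise.
#' @param time_step_ms,time_range_ms Passed to [morlet_basis()] when `basis`
#'   is NULL.
#' @return An object of class `tf_power`: `power`
#'   (`trials x freqs x times`, nonnegative), `freqs`, `times_ms`, `edge`
#'   flag matrix, `trial_ids`.
#' @export
morlet_power <- function(epochs, cfg = tf_config(), channel = 1L,
                         basis = NULL, time_step_ms = 25,
                         time_range_ms = NULL) {
  stopifnot(inherits(epochs, "epochs"))
  n_samples <- dim(epochs$data)[3L]
  if (is.null(basis))
    basis <- morlet_basis(epochs$fs, n_samples, epochs$window_ms, cfg,
                          time_step_ms, time_range_ms)
  stopifnot(inherits(basis, "morlet_basis"), basis$n_samples == n_samples)
  X <- matrix(epochs$data[, channel, ], dim(epochs$data)[1L], n_samples)
  P <- (X %*% basis$Wr)^2 + (X %*% basis$Wi)^2  # trials x (freqs*times)
  nf <- length(basis$freqs); nt <- length(basis$times_ms)
  # columns of W run time-fastest within frequency; reorder to
  # trials x freqs x times
  P3 <- aperm(array(P, c(nrow(P), nt, nf)), c(1L, 3L, 2L))
  structure(list(power = P3, freqs = basis$freqs, times_ms = basis$times_ms,
                 edge = basis$edge, trial_ids = epochs$trial_ids),
            class = "tf_power")
}

#' Build a trial-wise regression design matrix
#'
#' Assembles the named single-trial models: a constant, standardized value
#' regressor(s), and a +-1 categorical choice regressor.
#'
#' Models (value columns in order):
#' * `"option1"` - value of option 1 (option-1-locked, sequential trials);
#' * `"both_options"` - value of option 1 and of option 2;
#' * `"action_space"` - value of the option contralateral, then ipsilateral,
#'   to `hemisphere` (uses the side encoded in `layout`);
#' * `"goods_space"` - value of the chosen, then unchosen, option.
#'
#' The choice column is +1 when the chosen option is the one carried by the
#' model's first value column frame (option 1; contralateral; for
#' `goods_space`, option 1 by label).
#'
#' @param trials Trial table with recorded choices.
#' @param model Model name (see above).
#' @param params Optional [prospect_params()]: when given, value regressors
#'   are subjective expected values; otherwise objective `p * m`.
#' @param hemisphere `"left"` or `"right"`, required for `"action_space"`.
#' @param subset `"all"`, `"harder"` or `"nobrainer"` trial selection.
#' @param trial_type Optional trial-type filter (`"comparison"`,
#'   `"sequential"`).
#' @param weight_form Probability-weighting form when `params` is given.
#' @return An object of class `tf_design`: `X` (matrix with constant first),
#'   `names`, `roles`, `trial_index` (rows of `trials` used).
#' @export
build_design <- function(trials, model = c("option1", "both_options",
                                           "action_space", "goods_space"),
                         params = NULL, hemisphere = NULL,
                         subset = c("all", "harder", "nobrainer"),
                         trial_type = NULL, weight_form = "tk1992") {
  model <- match.arg(model)
  subset <- match.arg(subset)
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(trial_type)) keep <- keep & trials$trial_type == trial_type
  if (subset == "harder") keep <- keep & !trials$nobrainer
  if (subset == "nobrainer") keep <- keep & trials$nobrainer
  idx <- which(keep)
  d <- trials[idx, , drop = FALSE]
  if (nrow(d) == 0L) stop("trial selection is empty")
  if (any(is.na(d$choice))) stop("every selected trial needs a choice")
  v <- if (is.null(params)) cbind(d$p1 * d$m1, d$p2 * d$m2)
       else trial_values(d, params, weight_form)
  side1 <- ifelse(grepl("left$", d$layout), "left", "right")
  chose1 <- d$choice == 1L
  if (model == "option1") {
    vals <- cbind(v_opt1 = v[, 1L])
    cho <- ifelse(chose1, 1, -1)
  } else if (model == "both_options") {
    vals <- cbind(v_opt1 = v[, 1L], v_opt2 = v[, 2L])
    cho <- ifelse(chose1, 1, -1)
  } else if (model == "action_space") {
    if (is.null(hemisphere) || !hemisphere %in% c("left", "right"))
      stop('action_space needs hemisphere = "left" or "right"')
    contra_side <- if (hemisphere == "left") "right" else "left"
    o1_contra <- side1 == contra_side
    vals <- cbind(v_contra = ifelse(o1_contra, v[, 1L], v[, 2L]),
                  v_ipsi   = ifelse(o1_contra, v[, 2L], v[, 1L]))
    chosen_side <- ifelse(chose1, side1,
                          ifelse(side1 == "left", "right", "left"))
    cho <- ifelse(chosen_side == contra_side, 1, -1)
  } else { # goods_space
    vals <- cbind(v_chosen   = ifelse(chose1, v[, 1L], v[, 2L]),
                  v_unchosen = ifelse(chose1, v[, 2L], v[, 1L]))
    cho <- ifelse(chose1, 1, -1)
  }
  zvals <- apply(vals, 2L, function(x) {
    if (sd(x) == 0) stop("constant value regressor: cannot standardize")
    (x - mean(x)) / sd(x)
  })
  X <- cbind(constant = 1, zvals, choice = cho)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  structure(list(X = X, names = colnames(X),
                 roles = c("constant", rep("value", ncol(zvals)), "choice"),
                 trial_index = idx,
                 trial_ids = if ("trial_id" %in% names(trials))
                   trials$trial_id[idx] else idx,
                 model = model),
            class = "tf_design")
}

#' Trial-wise OLS regression of power on a design, per time-frequency bin
#'
#' Ordinary least squares independently at every (frequency, time) bin:
#' `power ~ X`. Each regressor's map of variance-normalized effects
#' (`beta / SE`, a per-subject t-value) is returned, along with the
#' ingredients needed for contrasts of parameter estimates.
#'
#' @param power A [morlet_power()] result.
#' @param design A [build_design()] result; `trial_index` selects the rows of
#'   `power` (matched through `trial_ids`).
#' @param exclude_trials Optional logical mask (per selected trial) of
#'   additionally excluded trials (e.g. artifact rejection).
#' @param log_power Regress `log(power + eps)` instead of raw power.
#' @return An object of class `tf_fit`: `effects` (named list of
#'   [effect_map()]s), plus `beta`, `sigma2`, `xtx_inv`, `df` for
#'   [contrast_effects()].
#' @export
regress_power <- function(power, design, exclude_trials = NULL,
                          log_power = FALSE) {
  stopifnot(inherits(power, "tf_power"), inherits(design, "tf_design"))
  rows <- match(design$trial_ids, power$trial_ids)
  if (anyNA(rows)) stop("design selects trials absent from the power array")
  X <- design$X
  if (!is.null(exclude_trials)) {
    X <- X[!exclude_trials, , drop = FALSE]
    rows <- rows[!exclude_trials]
  }
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2L) stop("need at least regressors + 2 trials")
  nf <- length(power$freqs); nt <- length(power$times_ms)
  Y <- matrix(power$power[rows, , ], n, nf * nt)
  if (log_power) Y <- log(Y + 1e-12)
  qx <- qr(X)
  beta <- qr.coef(qx, Y)                       # k x B
  res <- Y - X %*% beta
  df <- n - k
  sigma2 <- colSums(res^2) / df
  # bins fit exactly (zero residual variance up to roundoff) carry no
  # normalizable effect; report 0 rather than roundoff ratios
  degenerate <- sigma2 <= 1e-24 * pmax(colMeans(Y^2), .Machine$double.xmin)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  se <- sqrt(outer(diag(xtx_inv), sigma2))     # k x B
  effects <- lapply(seq_len(k), function(j) {
    v <- beta[j, ] / se[j, ]
    v[degenerate] <- 0
    effect_map(matrix(v, nf, nt), power$freqs,
               power$times_ms, df = df, edge = power$edge,
               name = design$names[j])
  })
  names(effects) <- design$names
  structure(list(effects = effects, beta = beta, sigma2 = sigma2,
                 degenerate = degenerate,
                 xtx_inv = xtx_inv, df = df, freqs = power$freqs,
                 times_ms = power$times_ms, edge = power$edge,
                 design_names = design$names),
            class = "tf_fit")
}

#' Per-subject time-frequency effect map
#'
#' A `frequencies x times` map of a variance-normalized regression effect
#' (or contrast) for one subject.
#'
#' @param values `freqs x times` matrix.
#' @param freqs,times_ms Axes.
#' @param df Residual degrees of freedom of the subject-level fit.
#' @param edge Logical `freqs x times` matrix flagging unreliable edge bins.
#' @param name Effect name.
#' @return An object of class `effect_map`.
#' @export
effect_map <- function(values, freqs, times_ms, df = NA_integer_,
                       edge = NULL, name = "effect") {
  stopifnot(nrow(values) == length(freqs), ncol(values) == length(times_ms))
  if (is.null(edge)) edge <- matrix(FALSE, nrow(values), ncol(values))
  structure(list(values = values, freqs = freqs, times_ms = times_ms,
                 df = df, edge = edge, name = name), class = "effect_map")
}

#' Contrast of parameter estimates from one time-frequency fit
#'
#' Computes `w' beta / sqrt(sigma2 * w' (X'X)^-1 w)` per bin: the
#' variance-normalized contrast, e.g. `(+1, -1)` on the two value columns for
#' a contralateral-minus-ipsilateral or chosen-minus-unchosen value
#' difference.
#'
#' @param fit A [regress_power()] result.
#' @param weights Named or positional contrast weights; names must match
#'   regressor names, unnamed vectors must have length `k`.
#' @param name Name for the resulting map.
#' @return An [effect_map()].
#' @export
contrast_effects <- function(fit, weights, name = "contrast") {
  stopifnot(inherits(fit, "tf_fit"))
  k <- nrow(fit$beta)
  w <- numeric(k)
  if (!is.null(names(weights))) {
    pos <- match(names(weights), fit$design_names)
    if (anyNA(pos)) stop("unknown regressor in contrast weights")
    w[pos] <- weights
  } else {
    if (length(weights) != k) stop("contrast weights must have length ", k)
    w <- weights
  }
  est <- drop(crossprod(w, fit$beta))
  se <- sqrt(drop(crossprod(w, fit$xtx_inv %*% w)) * fit$sigma2)
  vals <- ifelse(se > 0 & !fit$degenerate, est / se, 0)
  effect_map(matrix(vals, length(fit$freqs), length(fit$times_ms)),
             fit$freqs, fit$times_ms, df = fit$df, edge = fit$edge,
             name = name)
}

#' Hemispheric difference of effect maps
#'
#' Subject-wise difference of two effect maps computed with mirrored designs
#' (e.g. contralateral-minus-ipsilateral value effects per hemisphere),
#' used as that subject's summary for group statistics.
#'
#' @param map_a,map_b [effect_map()]s on identical frequency/time grids.
#' @return An [effect_map()] `map_a - map_b` (edges OR-ed).
#' @export
hemispheric_difference <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "effect_map"), inherits(map_b, "effect_map"))
  if (!isTRUE(all.equal(map_a$freqs, map_b$freqs)) ||
      !isTRUE(all.equal(map_a$times_ms, map_b$times_ms)))
    stop("effect maps are on different grids")
  effect_map(map_a$values - map_b$values, map_a$freqs, map_a$times_ms,
             df = min(map_a$df, map_b$df), edge = map_a$edge | map_b$edge,
             name = paste0(map_a$name, "-minus-", map_b$name))
}
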