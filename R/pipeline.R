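#' Draw heterogeneous subject-level prospect-theory parameters
#'
#' Group distributions chosen to mimic typical risky-choice cohorts: alpha
#' normal (mean 0.8, SD 0.4, truncated to 0.1-2), gamma normal (mean 0.7,
#' SD 0.12, truncated to 0.2-1.5), beta lognormal (median 2, sdlog 0.65,
#' truncated to 0.2-20). The wide alpha/beta and narrow gamma spreads match
#' the much larger between-subject coefficients of variation reported for
#' curvature and temperature than for probability weighting.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param alpha_mean,alpha_sd,gamma_mean,gamma_sd,beta_meanlog,beta_sdlog
#'   Group distribution parameters.
#' @return List of [prospect_params()], length `n`.
#' @export
draw_subject_params <- function(n, seed = NULL, alpha_mean = 0.8,
                                alpha_sd = 0.4, gamma_mean = 0.7,
                                gamma_sd = 0.12, beta_meanlog = log(2),
                                beta_sdlog = 0.65) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      prospect_params(
        alpha = min(max(rnorm(1L, alpha_mean, alpha_sd), 0.1), 2),
        gamma = min(max(rnorm(1L, gamma_mean, gamma_sd), 0.2), 1.5),
        beta = min(max(rlnorm(1L, beta_meanlog, beta_sdlog), 0.2), 20))
    })
  })
}

#' Simulate one subject's behavioural session
#'
#' Stimuli for both trial types plus choices from a prospect-theory softmax
#' agent.
#'
#' @param params A [prospect_params()] agent.
#' @param n_per_type Trials per trial type (default 324).
#' @param order_bias Sequential-trial second-option bias (softmax units).
#' @param seed Integer seed.
#' @param ... Passed to [generate_stimulus_set()].
#' @return Trial table with choices and response times.
#' @export
simulate_session <- function(params, n_per_type = 324, order_bias = 0,
                             seed = NULL, ...) {
  with_seed(seed, {
    trials <- generate_stimulus_set(n_per_type = n_per_type, ...)
    simulate_choices(trials, params, order_bias = order_bias)
  })
}

# One subject's value/choice effect maps: sequential trials, option-1-locked
# model (constant + standardized option-1 value + signed choice), with the
# same regressors injected into the synthetic epochs. Used by the null,
# latency and crossover studies. `basis` must match window/fs geometry.
subject_option1_maps <- function(params, truth, basis, n_per_type = 324,
                                 fs = 200, window_ms = c(-1000, 2000)) {
  trials <- generate_stimulus_set(n_per_type = n_per_type)
  trials <- simulate_choices(trials, params)
  seq_trials <- trials[trials$trial_type == "sequential", , drop = FALSE]
  ep <- simulate_epochs(seq_trials, truth, fs = fs, window_ms = window_ms,
                        value = seq_trials$p1 * seq_trials$m1)
  pw <- morlet_power(ep, basis = basis)
  des <- build_design(seq_trials, model = "option1")
  fit <- regress_power(pw, des)
  list(value = fit$effects[["v_opt1"]], choice = fit$effects[["choice"]])
}

#' Family-wise error rate of the full null pipeline
#'
#' Repeatedly runs synthetic sessions with no injected effects through the
#' complete pipeline (stimuli, softmax choices, oscillatory epochs, Morlet
#' power, trial-wise regression, group sign-flip cluster test) and reports
#' the fraction of datasets yielding any cluster-corrected p below `alpha` -
#' the pipeline's central statistical guarantee (it should not exceed the
#' nominal level).
#'
#' @param n_datasets Independent null datasets.
#' @param n_subjects Subjects per dataset.
#' @param n_per_type Trials per trial type (the sequential half is analysed).
#' @param n_perm Sign-flip permutations per dataset.
#' @param threshold Cluster-forming t threshold.
#' @param alpha Nominal significance level.
#' @param freqs Analysis frequencies (Hz).
#' @param time_step_ms,time_range_ms Output time grid.
#' @param fs,window_ms Epoch geometry.
#' @param seed Master seed (single source of randomness).
#' @return List: `fwe_rate`, `any_significant` (logical per dataset),
#'   `n_datasets`, grid sizes.
#' @export
fwe_null_experiment <- function(n_datasets = 200, n_subjects = 12,
                                n_per_type = 324, n_perm = 500,
                                threshold = 2, alpha = 0.05,
                                freqs = seq(2, 40, by = 2),
                                time_step_ms = 25,
                                time_range_ms = c(0, 1475),
                                fs = 200, window_ms = c(-1000, 2000),
                                seed = NULL) {
  n_samples <- round(fs * diff(window_ms) / 1000)
  basis <- morlet_basis(fs, n_samples, window_ms, tf_config(freqs = freqs),
                        time_step_ms, time_range_ms)
  truth <- ground_truth(g_value = 0, g_choice = 0)
  with_seed(seed, {
    hits <- vapply(seq_len(n_datasets), function(d) {
      maps <- lapply(draw_subject_params(n_subjects), function(pp) {
        subject_option1_maps(pp, truth, basis, n_per_type = n_per_type,
                             fs = fs, window_ms = window_ms)$value
      })
      res <- cluster_test(group_stack(maps), threshold = threshold,
                          n_perm = n_perm, alpha = alpha)
      any(vapply(res$clusters, `[[`, logical(1L), "significant"))
    }, logical(1L))
    list(fwe_rate = mean(hits), any_significant = hits,
         n_datasets = n_datasets, n_subjects = n_subjects,
         n_bins = length(freqs) * length(basis$times_ms))
  })
}

#' Recovery of injected effect latencies and of their ordering
#'
#' Injects a value-locked and a (later) choice-locked beta-band
#' desynchronization, runs the full single-subject pipeline for a group of
#' subjects, extracts per-subject peak latencies of both effects, and tests
#' the value-before-choice ordering with a paired one-sided t-test. Repeated
#' over `n_reps` replicate groups.
#'
#' @param n_reps Replicate groups.
#' @param n_subjects Subjects per group.
#' @param tau_value_ms,tau_choice_ms Group-mean injected latencies.
#' @param tau_sd_ms Between-subject latency SD.
#' @param g_value,g_choice Group-mean effect gains (negative =
#'   desynchronization).
#' @param g_sd Between-subject gain SD.
#' @param n_per_type Trials per trial type.
#' @param freqs Analysis frequencies (beta band).
#' @param search_window_ms Peak search window.
#' @param alpha Significance level for the ordering test.
#' @param seed Master seed.
#' @return List: `value_latency_median_ms`, `choice_latency_median_ms`
#'   (medians over replicates of the group-median latencies), `detection_rate`
#'   (fraction of replicates with significant value-before-choice ordering),
#'   and the per-replicate tables.
#' @export
latency_recovery_experiment <- function(n_reps = 50, n_subjects = 18,
                                        tau_value_ms = 500,
                                        tau_choice_ms = 700,
                                        tau_sd_ms = 50,
                                        g_value = -0.3, g_choice = -0.3,
                                        g_sd = 0.1, n_per_type = 324,
                                        freqs = seq(14, 30, by = 2),
                                        search_window_ms = c(0, 1000),
                                        alpha = 0.05, seed = NULL) {
  fs <- 200; window_ms <- c(-1000, 2000)
  n_samples <- round(fs * diff(window_ms) / 1000)
  basis <- morlet_basis(fs, n_samples, window_ms, tf_config(freqs = freqs),
                        time_step_ms = 25, time_range_ms = search_window_ms)
  with_seed(seed, {
    reps <- lapply(seq_len(n_reps), function(r) {
      lat <- t(vapply(draw_subject_params(n_subjects), function(pp) {
        truth <- ground_truth(
          g_value = min(rnorm(1L, g_value, g_sd), -0.05),
          g_choice = min(rnorm(1L, g_choice, g_sd), -0.05),
          tau_value_ms = rnorm(1L, tau_value_ms, tau_sd_ms),
          tau_choice_ms = rnorm(1L, tau_choice_ms, tau_sd_ms))
        maps <- subject_option1_maps(pp, truth, basis,
                                     n_per_type = n_per_type)
        c(value = peak_latency(maps$value, window_ms = search_window_ms,
                               sign = "neg")$latency_ms,
          choice = peak_latency(maps$choice, window_ms = search_window_ms,
                                sign = "neg")$latency_ms)
      }, c(value = 0, choice = 0)))
      ord <- paired_latency_test(lat[, "value"], lat[, "choice"],
                                 alternative = "less")
      list(median_value = median(lat[, "value"]),
           median_choice = median(lat[, "choice"]),
           detected = is.finite(ord$p) && ord$p < alpha)
    })
    list(value_latency_median_ms = median(vapply(reps, `[[`, 0, "median_value")),
         choice_latency_median_ms = median(vapply(reps, `[[`, 0, "median_choice")),
         detection_rate = mean(vapply(reps, `[[`, TRUE, "detected")),
         replicates = reps)
  })
}

# Peak effect size of a value-difference contrast in one simulated
# region/condition cell. `frame` picks the design and regressor geometry;
# `g` is the injected gain on the standardized value-difference regressor
# (0 = off cell). Positive `expected_sign` regions report +peak, negative
# report -peak, so a present effect is always a large positive number.
simulate_cell_peak <- function(trials, frame = c("goods", "action"), g,
                               tau_ms, basis, window_ms, search_window_ms,
                               expected_sign, fs = 200) {
  frame <- match.arg(frame)
  chose1 <- trials$choice == 1L
  v <- cbind(trials$p1 * trials$m1, trials$p2 * trials$m2)
  if (frame == "goods") {
    vdiff <- ifelse(chose1, v[, 1L] - v[, 2L], v[, 2L] - v[, 1L])
    model <- "goods_space"; hemi <- NULL
  } else {
    o1_contra <- grepl("right$", trials$layout)   # left hemisphere
    vdiff <- ifelse(o1_contra, v[, 1L] - v[, 2L], v[, 2L] - v[, 1L])
    model <- "action_space"; hemi <- "left"
  }
  truth <- ground_truth(g_value = g * expected_sign, g_choice = 0,
                        tau_value_ms = tau_ms,
                        tau_choice_ms = tau_ms)
  ep <- simulate_epochs(trials, truth, fs = fs, window_ms = window_ms,
                        value = vdiff,
                        choice = ifelse(chose1, 1, -1))
  pw <- morlet_power(ep, basis = basis)
  des <- build_design(trials, model = model, hemisphere = hemi)
  fit <- regress_power(pw, des)
  cmap <- contrast_effects(fit, setNames(c(1, -1), fit$design_names[2:3]),
                           name = "value_difference")
  pk <- peak_latency(cmap, window_ms = search_window_ms,
                     sign = if (expected_sign > 0) "pos" else "neg")
  expected_sign * pk$peak_value
}

#' Crossover interaction recovery: region-by-trial-type on peak value effects
#'
#' Simulates the 2x2 design in which a goods-frame value signal (positive,
#' VMPFC-like) exists only on comparison trials and an action-frame value
#' signal (negative, motor-like) only on sequential trials. Per subject the
#' four cells' peak beta-band value-difference effects (each in its region's
#' expected direction) enter the within-subject interaction test; the
#' detection rate over replicates is returned.
#'
#' @param n_reps Replicate groups.
#' @param n_subjects Subjects per group.
#' @param g Effect gain magnitude in "on" cells.
#' @param n_per_type Trials per trial type.
#' @param freqs Analysis frequencies (beta band).
#' @param alpha Significance level for the interaction F.
#' @param seed Master seed.
#' @return List: `detection_rate`, `F_values` per replicate.
#' @export
interaction_crossover_experiment <- function(n_reps = 50, n_subjects = 18,
                                             g = 0.3, n_per_type = 324,
                                             freqs = seq(14, 30, by = 2),
                                             alpha = 0.05, seed = NULL) {
  fs <- 200
  stim_win <- c(-1000, 2000); resp_win <- c(-2000, 1000)
  cfg <- tf_config(freqs = freqs)
  basis_resp <- morlet_basis(fs, round(fs * diff(resp_win) / 1000), resp_win,
                             cfg, 25, c(-1000, 0))
  basis_stim <- morlet_basis(fs, round(fs * diff(stim_win) / 1000), stim_win,
                             cfg, 25, c(0, 1000))
  with_seed(seed, {
    Fs <- vapply(seq_len(n_reps), function(r) {
      cells <- t(vapply(draw_subject_params(n_subjects), function(pp) {
        trials <- simulate_session(pp)
        comp <- trials[trials$trial_type == "comparison", , drop = FALSE]
        seqt <- trials[trials$trial_type == "sequential", , drop = FALSE]
        # region A: goods frame, response-locked, positive effect, on in
        # comparison (condition 1) only
        a1 <- simulate_cell_peak(comp, "goods", g, -750, basis_resp,
                                 resp_win, c(-1000, 0), +1)
        a2 <- simulate_cell_peak(seqt, "goods", 0, -750, basis_resp,
                                 resp_win, c(-1000, 0), +1)
        # region B: action frame, stimulus-locked, negative effect, on in
        # sequential (condition 2) only
        b1 <- simulate_cell_peak(comp, "action", 0, 400, basis_stim,
                                 stim_win, c(0, 1000), -1)
        b2 <- simulate_cell_peak(seqt, "action", g, 400, basis_stim,
                                 stim_win, c(0, 1000), -1)
        c(A1 = a1, A2 = a2, B1 = b1, B2 = b2)
      }, c(A1 = 0, A2 = 0, B1 = 0, B2 = 0)))
      it <- interaction_2x2(cells)
      if (it$p < alpha) it$F else -it$F
    }, 0)
    list(detection_rate = mean(Fs > 0), F_values = abs(Fs))
  })
}

#' Behavioural parameter recovery study
#'
#' Draws heterogeneous subjects, simulates full sessions, refits the
#' prospect-theory model per subject, and summarises how well the generating
#' parameters are recovered.
#'
#' @param n_subjects Synthetic subjects.
#' @param n_per_type Trials per trial type (the fit pools both types).
#' @param n_restarts Optimiser restarts per fit.
#' @param seed Master seed.
#' @return List: `table` (true and recovered parameters per subject),
#'   `alpha_correlation`, `alpha_mae` (median absolute error),
#'   `beta_relative_error_median`.
#' @export
parameter_recovery_experiment <- function(n_subjects = 50, n_per_type = 324,
                                          n_restarts = 10, seed = NULL) {
  with_seed(seed, {
    pars <- draw_subject_params(n_subjects)
    rows <- lapply(seq_len(n_subjects), function(s) {
      trials <- simulate_session(pars[[s]], n_per_type = n_per_type)
      fit <- fit_prospect(trials, n_restarts = n_restarts,
                          seed = sample.int(2^31 - 1L, 1L))
      data.frame(subject = s,
                 alpha_true = pars[[s]]$alpha, alpha_fit = fit$params$alpha,
                 gamma_true = pars[[s]]$gamma, gamma_fit = fit$params$gamma,
                 beta_true = pars[[s]]$beta, beta_fit = fit$params$beta,
                 nll = fit$nll, convergence = fit$convergence)
    })
    tab <- do.call(rbind, rows)
    list(table = tab,
         alpha_correlation = cor(tab$alpha_true, tab$alpha_fit),
         alpha_mae = median(abs(tab$alpha_fit - tab$alpha_true)),
         beta_relative_error_median =
           median(abs(tab$beta_fit - tab$beta_true) / tab$beta_true))
  })
}

#' BIC model-selection sanity study
#'
#' Half the simulated subjects choose by a prospect-theory agent
#' (`alpha = 0.5`), half by an objective expected-value agent; each dataset
#' is fit with both models and BIC picks one. Returns the fraction of
#' datasets where BIC selects the generating model.
#'
#' @param n_sims Total simulated datasets (half per generator).
#' @param n_per_type Trials per trial type.
#' @param alpha_gen,gamma_gen,beta_gen Prospect generator parameters.
#' @param beta_ev Objective-EV generator inverse temperature (EV units).
#' @param n_restarts Optimiser restarts per fit.
#' @param seed Master seed.
#' @return List: `correct_rate`, `detail` data frame.
#' @export
bic_selection_experiment <- function(n_sims = 50, n_per_type = 324,
                                     alpha_gen = 0.5, gamma_gen = 0.7,
                                     beta_gen = 3, beta_ev = 0.1,
                                     n_restarts = 8, seed = NULL) {
  with_seed(seed, {
    gen <- rep(c("prospect", "objective_ev"), length.out = n_sims)
    rows <- lapply(seq_len(n_sims), function(i) {
      params <- if (gen[i] == "prospect")
        prospect_params(alpha_gen, gamma_gen, beta_gen)
      else prospect_params(1, 1, beta_ev)
      trials <- simulate_session(params, n_per_type = n_per_type)
      cmp <- compare_bic(trials, n_restarts = n_restarts,
                         seed = sample.int(2^31 - 1L, 1L))
      data.frame(generator = gen[i], preferred = cmp$preferred,
                 delta_bic = cmp$delta_bic)
    })
    detail <- do.call(rbind, rows)
    list(correct_rate = mean(detail$generator == detail$preferred),
         detail = detail)
  })
}
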