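#' Prospect-theory parameter set
#'
#' Container for the three-parameter descriptive choice model used throughout:
#' `alpha` curves subjective reward magnitude (`u(r) = r^alpha`), `gamma`
#' distorts probability weighting, and `beta` is the softmax inverse
#' temperature (1/tau). `alpha = gamma = 1` reduces the subjective expected
#' value to the objective expected value.
#'
#' @param alpha Magnitude-curvature exponent, > 0.
#' @param gamma Probability-weighting parameter, > 0.
#' @param beta Softmax inverse temperature, >= 0.
#' @return An object of class `prospect_params`.
#' @export
prospect_params <- function(alpha = 1, gamma = 1, beta = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0)
  structure(list(alpha = alpha, gamma = gamma, beta = beta),
            class = "prospect_params")
}

#' @export
print.prospect_params <- function(x, ...) {
  cat(sprintf("prospect_params: alpha = %.4g, gamma = %.4g, beta = %.4g\n",
              x$alpha, x$gamma, x$beta))
  invisible(x)
}

#' Probability weighting function
#'
#' Two canonical one-parameter forms: the Tversky-Kahneman (1992) inverse-S
#' weighting `p^g / (p^g + (1-p)^g)^(1/g)` (default) and the simple power
#' form `p^g`.
#'
#' @param p Probabilities in (0, 1).
#' @param gamma Weighting parameter, > 0.
#' @param form `"tk1992"` or `"power"`.
#' @return Weighted probabilities, same length as `p`.
#' @export
prob_weight <- function(p, gamma, form = c("tk1992", "power")) {
  form <- match.arg(form)
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  if (form == "power") return(p^gamma)
  pg <- p^gamma
  pg / (pg + (1 - p)^gamma)^(1 / gamma)
}

#' Subjective expected value of a risky prospect
#'
#' `w(p; gamma) * u(r; alpha)` with `u(r) = r^alpha` and `w` the configured
#' probability weighting function.
#'
#' @param p Reward probability in (0, 1); vectorized.
#' @param r Reward magnitude, > 0; vectorized.
#' @param params A [prospect_params()] object.
#' @param weight_form Passed to [prob_weight()].
#' @return Subjective expected values.
#' @export
subjective_value <- function(p, r, params, weight_form = c("tk1992", "power")) {
  if (any(r <= 0)) stop("reward magnitudes must be positive")
  prob_weight(p, params$gamma, match.arg(weight_form)) * r^params$alpha
}

#' Softmax choice probabilities for an option pair
#'
#' `P_i = exp(beta v_i) / sum_j exp(beta v_j)`, computed through the logistic
#' of the scaled value difference so it is overflow-safe for any `beta`.
#'
#' @param v1,v2 Subjective values of options 1 and 2 (vectorized).
#' @param beta Inverse temperature, >= 0.
#' @return A two-column matrix `p1`, `p2`; rows sum to 1.
#' @export
choice_probability <- function(v1, v2, beta) {
  stopifnot(beta >= 0)
  p1 <- plogis(beta * (v1 - v2))
  cbind(p1 = p1, p2 = 1 - p1)
}

# Subjective values of both options of a trial table.
trial_values <- function(trials, params, weight_form = "tk1992") {
  cbind(subjective_value(trials$p1, trials$m1, params, weight_form),
        subjective_value(trials$p2, trials$m2, params, weight_form))
}

#' Negative log-likelihood of recorded choices
#'
#' Sum of `-log P(chosen option)` under the prospect-theory softmax model.
#' Probabilities are floored at 1e-10 inside the log so the result is finite.
#'
#' @param trials Trial table with columns `p1`, `m1`, `p2`, `m2`, `choice`
#'   (1 or 2); see [generate_stimulus_set()].
#' @param params A [prospect_params()] object.
#' @param weight_form Probability-weighting form, see [prob_weight()].
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(trials, params, weight_form = "tk1992") {
  if (nrow(trials) == 0L) stop("empty trial list")
  if (any(is.na(trials$choice))) stop("every trial needs a recorded choice")
  v <- trial_values(trials, params, weight_form)
  pr <- choice_probability(v[, 1L], v[, 2L], params$beta)
  chosen <- pr[cbind(seq_len(nrow(pr)), trials$choice)]
  -sum(log(pmax(chosen, 1e-10)))
}

nll_objective <- function(theta, trials, weight_form, fix_identity = FALSE) {
  params <- if (fix_identity) {
    prospect_params(alpha = 1, gamma = 1, beta = theta[1L])
  } else {
    prospect_params(alpha = theta[1L], gamma = theta[2L], beta = theta[3L])
  }
  negative_log_likelihood(trials, params, weight_form)
}

#' Fit the three-parameter prospect-theory choice model by maximum likelihood
#'
#' Box-bounded quasi-Newton minimisation of the negative log-likelihood with
#' multiple random restarts (the likelihood surface is multimodal in
#' gamma/beta). Deterministic given `seed`.
#'
#' @param trials Trial table with recorded choices.
#' @param n_restarts Number of optimiser starts (first start is always
#'   `alpha = gamma = beta = 1`).
#' @param seed Integer seed for the random restarts.
#' @param bounds Named list of `c(lower, upper)` for `alpha`, `gamma`, `beta`.
#' @param weight_form Probability-weighting form, see [prob_weight()].
#' @return A `prospect_fit`: `params`, `nll`, `bic`, `convergence` (0 is
#'   clean), `n_trials`, `k`, `restarts` (per-start table).
#' @export
fit_prospect <- function(trials, n_restarts = 10, seed = NULL,
                         bounds = list(alpha = c(0.05, 3), gamma = c(0.05, 3),
                                       beta = c(0, 50)),
                         weight_form = "tk1992") {
  lower <- c(bounds$alpha[1L], bounds$gamma[1L], bounds$beta[1L])
  upper <- c(bounds$alpha[2L], bounds$gamma[2L], bounds$beta[2L])
  starts <- with_seed(seed, {
    s <- matrix(runif(3L * n_restarts, lower, upper), ncol = 3L, byrow = TRUE)
    s[1L, ] <- pmin(pmax(c(1, 1, 1), lower), upper)
    # spread restart temperatures over orders of magnitude
    s[, 3L] <- exp(runif(n_restarts, log(0.05), log(min(upper[3L], 20))))
    s
  })
  fits <- apply(starts, 1L, function(th) {
    res <- tryCatch(
      optim(th, nll_objective, trials = trials, weight_form = weight_form,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    res
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all optimiser restarts failed")
  nlls <- vapply(fits, `[[`, numeric(1L), "value")
  best <- fits[[which.min(nlls)]]
  n <- nrow(trials)
  k <- 3L
  structure(list(
    params = prospect_params(best$par[1L], best$par[2L], best$par[3L]),
    nll = best$value,
    bic = k * log(n) + 2 * best$value,
    convergence = best$convergence,
    n_trials = n, k = k,
    restarts = data.frame(nll = nlls,
                          convergence = vapply(fits, `[[`, numeric(1L),
                                               "convergence"))
  ), class = "prospect_fit")
}

#' Fit the one-parameter objective expected-value baseline model
#'
#' Softmax on objective expected value `p * r`; only the inverse temperature
#' is free.
#'
#' @inheritParams fit_prospect
#' @return A `prospect_fit` with `k = 1` and `alpha = gamma = 1` fixed.
#' @export
fit_ev_model <- function(trials, n_restarts = 10, seed = NULL,
                         beta_bounds = c(0, 50)) {
  starts <- with_seed(seed,
                      exp(runif(n_restarts, log(0.01),
                                log(max(beta_bounds[2L] / 2, 0.02)))))
  starts[1L] <- 1
  fits <- lapply(starts, function(b0) {
    tryCatch(
      optim(b0, nll_objective, trials = trials, weight_form = "tk1992",
            fix_identity = TRUE, method = "L-BFGS-B",
            lower = beta_bounds[1L], upper = beta_bounds[2L],
            control = list(maxit = 500L)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all optimiser restarts failed")
  nlls <- vapply(fits, `[[`, numeric(1L), "value")
  best <- fits[[which.min(nlls)]]
  n <- nrow(trials)
  structure(list(
    params = prospect_params(1, 1, best$par[1L]),
    nll = best$value,
    bic = 1L * log(n) + 2 * best$value,
    convergence = best$convergence,
    n_trials = n, k = 1L,
    restarts = data.frame(nll = nlls,
                          convergence = vapply(fits, `[[`, numeric(1L),
                                               "convergence"))
  ), class = "prospect_fit")
}

#' Compare prospect-theory and objective-EV models by BIC
#'
#' Both models are fit on the same trials; `BIC = k log(n) + 2 NLL`.
#' Negative `delta_bic` (prospect minus objective) favours prospect theory.
#'
#' @inheritParams fit_prospect
#' @return List with both fits, the two BICs, `delta_bic`, and `preferred`
#'   (`"prospect"` or `"objective_ev"`).
#' @export
compare_bic <- function(trials, n_restarts = 10, seed = NULL,
                        weight_form = "tk1992") {
  fp <- fit_prospect(trials, n_restarts = n_restarts, seed = seed,
                     weight_form = weight_form)
  fe <- fit_ev_model(trials, n_restarts = n_restarts,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  list(prospect = fp, objective_ev = fe,
       bic_prospect = fp$bic, bic_objective = fe$bic,
       delta_bic = fp$bic - fe$bic,
       preferred = if (fp$bic < fe$bic) "prospect" else "objective_ev")
}

#' Logistic-regression analysis of choice determinants
#'
#' Per subject and per trial type, regresses the choice of option 1 on the
#' standardized probability difference `p1 - p2`, magnitude difference
#' `r1 - r2` and objective expected-value difference `EV1 - EV2`, with a
#' constant to capture side/order bias. Group-level one-sample t-tests per
#' coefficient per trial type and paired t-tests between trial types.
#'
#' @param sessions List of per-subject trial tables (each with both trial
#'   types and recorded choices).
#' @param separation How to treat (near-)perfect separation: `"cap"` clips the
#'   affected coefficient at `+-cap`, `"exclude"` drops the subject from the
#'   group tests for that trial type.
#' @param cap Cap value used when `separation = "cap"`.
#' @return List with `coefficients` (subject x coefficient x trial-type
#'   array), `group_tests` and `paired_tests` data frames, and a logical
#'   `flagged` matrix marking separation.
#' @export
logistic_choice_analysis <- function(sessions, separation = c("cap", "exclude"),
                                     cap = 10) {
  separation <- match.arg(separation)
  types <- c("comparison", "sequential")
  cn <- c("constant", "dp", "dr", "dev")
  ns <- length(sessions)
  coefs <- array(NA_real_, c(ns, 4L, 2L),
                 dimnames = list(NULL, cn, types))
  flagged <- matrix(FALSE, ns, 2L, dimnames = list(NULL, types))
  for (s in seq_len(ns)) {
    tr <- sessions[[s]]
    for (ti in seq_along(types)) {
      d <- tr[tr$trial_type == types[ti], , drop = FALSE]
      if (nrow(d) < 8L) next
      X <- data.frame(
        y = as.integer(d$choice == 1L),
        dp = as.numeric(scale(d$p1 - d$p2)),
        dr = as.numeric(scale(d$m1 - d$m2)),
        dev = as.numeric(scale(d$p1 * d$m1 - d$p2 * d$m2)))
      fit <- suppressWarnings(glm(y ~ dp + dr + dev, data = X,
                                  family = binomial()))
      b <- coef(fit)
      if (any(abs(b) > cap) || !fit$converged) {
        flagged[s, ti] <- TRUE
        if (separation == "exclude") next
        b <- pmin(pmax(b, -cap), cap)
      }
      coefs[s, , ti] <- b
    }
  }
  one_sample <- do.call(rbind, lapply(types, function(ty) {
    do.call(rbind, lapply(cn, function(co) {
      x <- coefs[, co, ty]
      x <- x[is.finite(x)]
      if (length(x) < 2L || sd(x) == 0) {
        return(data.frame(trial_type = ty, coefficient = co,
                          mean = if (length(x)) mean(x) else NA_real_,
                          t = NA_real_, df = NA_real_, p = NA_real_))
      }
      tt <- t.test(x)
      data.frame(trial_type = ty, coefficient = co, mean = mean(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }))
  paired <- do.call(rbind, lapply(cn, function(co) {
    a <- coefs[, co, "comparison"]
    b <- coefs[, co, "sequential"]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2L || sd(a[ok] - b[ok]) == 0) {
      return(data.frame(coefficient = co,
                        mean_diff = if (any(ok)) mean(a[ok] - b[ok])
                                    else NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- t.test(a[ok], b[ok], paired = TRUE)
    data.frame(coefficient = co, mean_diff = mean(a[ok] - b[ok]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  list(coefficients = coefs, group_tests = one_sample, paired_tests = paired,
       flagged = flagged)
}
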