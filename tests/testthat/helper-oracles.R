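# Independent oracles, deliberately written with different numerics than the
# package implementation.

# Logistic regression by hand-rolled iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(b_new - b)) < tol) return(drop(b_new))
    b <- drop(b_new)
  }
  drop(b)
}

# OLS beta and beta/SE by explicit normal equations, one response at a time.
normal_equations_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * diag(xtx_inv))
  list(beta = unname(beta), tval = unname(beta / se))
}

# Wrap a plain freqs x times matrix as a single-channel tf_power so the
# regression path can be driven with hand-built power values.
fake_tf_power <- function(power_3d, freqs, times_ms, trial_ids = NULL) {
  structure(list(power = power_3d, freqs = freqs, times_ms = times_ms,
                 edge = matrix(FALSE, length(freqs), length(times_ms)),
                 trial_ids = if (is.null(trial_ids)) seq_len(dim(power_3d)[1])
                             else trial_ids),
            class = "tf_power")
}

# A small simulated session shared by several tests.
demo_session <- function(seed = 42, n_per_type = 120,
                         params = prospect_params(0.8, 0.7, 3)) {
  simulate_session(params, n_per_type = n_per_type, seed = seed)
}
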