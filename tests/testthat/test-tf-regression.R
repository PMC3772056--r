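make_epochs <- function(x_by_trial, fs = 200, window_ms = c(-1000, 2000)) {
  n <- length(x_by_trial[[1]])
  arr <- array(0, c(length(x_by_trial), 1, n))
  for (i in seq_along(x_by_trial)) arr[i, 1, ] <- x_by_trial[[i]]
  epochs_container(arr, fs = fs, window_ms = window_ms)
}

test_that("wavelet power localizes a pure sinusoid and scales quadratically", {
  fs <- 200
  t <- seq(-1, 2 - 1 / fs, by = 1 / fs)
  ep <- make_epochs(list(sin(2 * pi * 20 * t), 2 * sin(2 * pi * 20 * t)))
  pw <- morlet_power(ep, tf_config(freqs = seq(4, 40, 2)),
                     time_range_ms = c(0, 1000))
  mid <- which(pw$times_ms == 500)
  spec1 <- pw$power[1, , mid]
  expect_equal(pw$freqs[which.max(spec1)], 20)
  # doubling the amplitude quadruples power
  expect_equal(pw$power[2, , mid] / spec1,
               rep(4, length(pw$freqs)), tolerance = 1e-8)
  # zero input gives zero power everywhere
  ep0 <- make_epochs(list(numeric(600)))
  pw0 <- morlet_power(ep0, tf_config(freqs = seq(4, 40, 2)))
  expect_true(all(pw0$power == 0))
  expect_error(morlet_power(ep, tf_config(freqs = c(10, 120))), "Nyquist")
})

test_that("white-noise spectra are smooth across wavelet frequencies", {
  set.seed(100)
  fs <- 200
  ep <- make_epochs(lapply(1:80, function(i) rnorm(600)))
  pw <- morlet_power(ep, tf_config(freqs = seq(6, 40, 2)),
                     time_range_ms = c(200, 800))
  avg <- apply(pw$power, 2, mean)         # time- and trial-averaged
  ratio <- avg[2:(length(avg) - 1)] /
    ((avg[1:(length(avg) - 2)] + avg[3:length(avg)]) / 2)
  expect_true(all(ratio < 3 & ratio > 1 / 3))
})

test_that("edge bins are flagged where the wavelet leaves the epoch", {
  b <- morlet_basis(200, 600, c(-1000, 2000), tf_config(freqs = c(2, 20)),
                    time_step_ms = 100)
  # at 2 Hz the truncated support is ~1.2 s: early/late bins are edges
  expect_true(b$edge[1, b$times_ms == -900])
  expect_false(b$edge[1, b$times_ms == 500])
  expect_false(b$edge[2, b$times_ms == 0])
})

test_that("design matrices standardize, subset and code choice as +-1", {
  tr <- demo_session(seed = 110, n_per_type = 160)
  d <- build_design(tr, "goods_space", subset = "harder",
                    trial_type = "comparison")
  expect_equal(ncol(d$X), 4)
  expect_equal(nrow(d$X),
               sum(tr$trial_type == "comparison" & !tr$nobrainer))
  expect_equal(colnames(d$X), c("constant", "v_chosen", "v_unchosen", "choice"))
  for (j in 2:3) {
    expect_lt(abs(mean(d$X[, j])), 1e-10)
    expect_lt(abs(sd(d$X[, j]) - 1), 1e-10)
  }
  expect_true(all(d$X[, "choice"] %in% c(-1, 1)))
  expect_true(all(d$X[, "constant"] == 1))
  # subjective values enter when parameters are supplied
  ds <- build_design(tr, "option1", params = prospect_params(0.7, 0.8, 2))
  expect_false(isTRUE(all.equal(ds$X[, "v_opt1"],
                                build_design(tr, "option1")$X[, "v_opt1"])))
  # a constant choice column is collinear with the intercept
  tr2 <- tr
  tr2$choice <- 1L
  expect_error(build_design(tr2, "option1"), "rank deficient")
  expect_error(build_design(tr, "action_space"), "hemisphere")
})

test_that("per-bin OLS matches explicit normal equations to 1e-8", {
  for (seed in c(120, 121, 122)) {
    set.seed(seed)
    tr20 <- demo_session(seed = seed, n_per_type = 20)
    st <- tr20[tr20$trial_type == "sequential", ]      # 20 trials
    des <- build_design(st, "option1")                 # 3 regressors
    nf <- 3; nt <- 4
    P <- array(abs(rnorm(nrow(st) * nf * nt, 5)), c(nrow(st), nf, nt))
    pw <- fake_tf_power(P, freqs = c(10, 20, 30), times_ms = c(0, 100, 200, 300),
                        trial_ids = st$trial_id)
    fit <- regress_power(pw, des)
    for (f in 1:nf) for (ti in 1:nt) {
      oracle <- normal_equations_ols(des$X, P[, f, ti])
      for (j in 1:3)
        expect_equal(fit$effects[[j]]$values[f, ti], oracle$tval[j],
                     tolerance = 1e-8)
    }
  }
})

test_that("a known per-bin generator is recovered within sampling error", {
  set.seed(130)
  tr <- demo_session(seed = 131, n_per_type = 324)
  st <- tr[tr$trial_type == "sequential", ]
  des <- build_design(st, "option1")
  z <- des$X[, "v_opt1"]
  P <- array(rnorm(nrow(st) * 1 * 1, sd = 1), c(nrow(st), 1, 1))
  P[, 1, 1] <- P[, 1, 1] + 2 * z + 10
  pw <- fake_tf_power(P, 20, 0, trial_ids = st$trial_id)
  fit <- regress_power(pw, des)
  o <- normal_equations_ols(des$X, P[, 1, 1])
  beta_hat <- o$beta[2]
  se_hat <- beta_hat / o$tval[2]
  expect_lt(abs(beta_hat - 2), 2 * se_hat)
  # the module's variance-normalized effect equals beta/SE
  expect_equal(fit$effects$v_opt1$values[1, 1], o$tval[2], tolerance = 1e-10)
})

test_that("null effects follow the nominal Student-t calibration", {
  set.seed(140)
  tr <- demo_session(seed = 141, n_per_type = 100)
  st <- tr[tr$trial_type == "sequential", ]
  des <- build_design(st, "option1")
  nb <- 400
  P <- array(rnorm(nrow(st) * nb), c(nrow(st), 20, 20))
  pw <- fake_tf_power(P, seq_len(20), seq(0, 475, 25), trial_ids = st$trial_id)
  fit <- regress_power(pw, des)
  tv <- as.vector(fit$effects$v_opt1$values)
  df <- fit$df
  expect_lt(abs(mean(tv)), 3 / sqrt(nb))
  expect_lt(abs(var(tv) - df / (df - 2)), 0.15)
  qq <- quantile(tv, c(0.1, 0.9))
  expect_lt(max(abs(qq - qt(c(0.1, 0.9), df))), 0.15)
})

test_that("adding a multiple of the constant shifts only the intercept", {
  tr <- demo_session(seed = 150, n_per_type = 50)
  st <- tr[tr$trial_type == "sequential", ]
  des <- build_design(st, "option1")
  set.seed(151)
  P <- array(abs(rnorm(nrow(st) * 2 * 3, 4)), c(nrow(st), 2, 3))
  pw <- fake_tf_power(P, c(10, 20), c(0, 50, 100), trial_ids = st$trial_id)
  f1 <- regress_power(pw, des)
  pw$power <- pw$power + 11
  f2 <- regress_power(pw, des)
  expect_equal(f1$effects$v_opt1$values, f2$effects$v_opt1$values,
               tolerance = 1e-9)
  expect_equal(f1$effects$choice$values, f2$effects$choice$values,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$effects$constant$values,
                                f2$effects$constant$values)))
})

test_that("constant power produces exactly zero non-constant effects", {
  tr <- demo_session(seed = 160, n_per_type = 30)
  st <- tr[tr$trial_type == "sequential", ]
  des <- build_design(st, "option1")
  P <- array(3.7, c(nrow(st), 2, 2))
  pw <- fake_tf_power(P, c(10, 20), c(0, 50), trial_ids = st$trial_id)
  fit <- regress_power(pw, des)
  expect_true(all(fit$effects$v_opt1$values == 0))
  expect_true(all(fit$effects$choice$values == 0))
})

test_that("contrasts propagate the design covariance correctly", {
  tr <- demo_session(seed = 170, n_per_type = 120)
  ct <- tr[tr$trial_type == "comparison", ]
  des <- build_design(ct, "goods_space")
  set.seed(171)
  P <- array(abs(rnorm(nrow(ct) * 4, 5)), c(nrow(ct), 2, 2))
  pw <- fake_tf_power(P, c(15, 25), c(0, 100), trial_ids = ct$trial_id)
  fit <- regress_power(pw, des)
  # identity weight reproduces the component map
  m1 <- contrast_effects(fit, c(v_chosen = 1))
  expect_equal(m1$values, fit$effects$v_chosen$values, tolerance = 1e-12)
  # hand-computed (1,-1) contrast at one bin
  cm <- contrast_effects(fit, c(v_chosen = 1, v_unchosen = -1))
  y <- P[, 1, 1]
  o <- normal_equations_ols(des$X, y)
  w <- c(0, 1, -1, 0)
  xtx_inv <- solve(t(des$X) %*% des$X)
  s2 <- sum((y - des$X %*% o$beta)^2) / (nrow(des$X) - 4)
  expect_equal(cm$values[1, 1],
               sum(w * o$beta) / sqrt(s2 * drop(t(w) %*% xtx_inv %*% w)),
               tolerance = 1e-8)
  expect_error(contrast_effects(fit, c(nonsense = 1)), "unknown regressor")
})

test_that("hemispheric differences subtract maps and double mirrored effects", {
  e <- effect_map(matrix(rnorm(12), 3), c(10, 20, 30), c(0, 100, 200, 300))
  zero <- hemispheric_difference(e, e)
  expect_true(all(zero$values == 0))
  neg <- effect_map(-e$values, e$freqs, e$times_ms)
  expect_equal(hemispheric_difference(e, neg)$values, 2 * e$values)
  other <- effect_map(matrix(0, 2, 2), c(1, 2), c(0, 100))
  expect_error(hemispheric_difference(e, other), "different grids")
})

test_that("excluding trials equals fitting on the reduced trial set", {
  tr <- demo_session(seed = 190, n_per_type = 60)
  st <- tr[tr$trial_type == "sequential", ]
  des <- build_design(st, "option1")
  set.seed(191)
  P <- array(abs(rnorm(nrow(st) * 4, 4)), c(nrow(st), 2, 2))
  pw <- fake_tf_power(P, c(10, 20), c(0, 100), trial_ids = st$trial_id)
  drop_mask <- seq_len(nrow(st)) %in% sample(nrow(st), 12)
  f1 <- regress_power(pw, des, exclude_trials = drop_mask)
  st2 <- st[!drop_mask, ]
  pw2 <- fake_tf_power(P[!drop_mask, , , drop = FALSE], c(10, 20), c(0, 100),
                       trial_ids = st2$trial_id)
  # same trials, but regressors restandardized on the subset: compare to a
  # design built on the subset with identical columns
  des2 <- des
  des2$X <- des$X[!drop_mask, , drop = FALSE]
  des2$trial_ids <- des$trial_ids[!drop_mask]
  des2$trial_index <- des$trial_index[!drop_mask]
  f2 <- regress_power(pw2, des2)
  expect_equal(f1$effects$v_opt1$values, f2$effects$v_opt1$values,
               tolerance = 1e-10)
  expect_equal(f1$df, f2$df)
})

test_that("a lateralized generator doubles in the hemispheric difference", {
  # contralateral-minus-ipsilateral value effect injected with opposite sign
  # in the two hemispheres; their difference should be ~twice either one
  tr <- demo_session(seed = 192, n_per_type = 324)
  st <- tr[tr$trial_type == "sequential", ]
  vdiff <- st$p1 * st$m1 - st$p2 * st$m2
  basis <- morlet_basis(200, 600, c(-1000, 2000),
                        tf_config(freqs = seq(14, 30, 4)),
                        time_step_ms = 50, time_range_ms = c(200, 800))
  one_hemi <- function(g, seed) {
    ep <- simulate_epochs(st, ground_truth(g_value = g, g_choice = 0,
                                           tau_value_ms = 500),
                          seed = seed, value = vdiff)
    regress_power(morlet_power(ep, basis = basis),
                  build_design(st, "option1"))$effects$v_opt1
  }
  left <- one_hemi(-0.25, 193)
  right <- one_hemi(0.25, 194)
  d <- hemispheric_difference(left, right)
  band <- abs(left$freqs - 20) <= 4      # near the 20 Hz carrier
  win <- left$times_ms >= 400 & left$times_ms <= 600
  m_left <- mean(left$values[band, win])
  m_diff <- mean(d$values[band, win])
  expect_lt(m_left, -2)
  expect_lt(abs(m_diff - 2 * m_left) / abs(2 * m_left), 0.35)
})
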