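test_that("subjective value reduces to objective EV at identity parameters", {
  p0 <- prospect_params(1, 1, 1)
  expect_equal(subjective_value(0.6, 50, p0), 30)
  expect_equal(subjective_value(c(0.2, 0.8), c(10, 40), p0), c(2, 32))
})

test_that("magnitude curvature and probability weighting act separately", {
  # curvature only: near-certain reward of 100 at alpha = 0.5 is about 10
  v <- subjective_value(1 - 1e-9, 100, prospect_params(0.5, 1, 1))
  expect_equal(v, 10, tolerance = 1e-6)
  # hand-evaluation of the two closed forms at alpha=0.8, gamma=0.7
  p <- 0.4; r <- 60
  w_hand <- p^0.7 / (p^0.7 + (1 - p)^0.7)^(1 / 0.7)
  u_hand <- r^0.8
  expect_equal(subjective_value(p, r, prospect_params(0.8, 0.7, 2)),
               w_hand * u_hand, tolerance = 1e-12)
  # power-form switch
  expect_equal(subjective_value(p, r, prospect_params(0.8, 0.7, 2),
                                weight_form = "power"),
               p^0.7 * u_hand, tolerance = 1e-12)
  expect_error(subjective_value(1.2, 10, prospect_params()), "probabilit")
})

test_that("softmax probabilities are symmetric, normalized and monotone", {
  expect_equal(choice_probability(1.3, 1.3, 5)[1, ], c(p1 = 0.5, p2 = 0.5))
  expect_equal(choice_probability(2, 7, 0)[1, ], c(p1 = 0.5, p2 = 0.5))
  pr <- choice_probability(2, 1, 1)
  expect_equal(unname(pr[1, 1]), exp(2) / (exp(2) + exp(1)), tolerance = 1e-12)
  v1 <- seq(-5, 5, 0.5)
  pr <- choice_probability(v1, 0, 1.7)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_true(all(diff(pr[, 1]) > 0))
  # no overflow at extreme scaled values
  expect_equal(unname(choice_probability(1e6, 0, 50)[1, 1]), 1)
})

test_that("negative log-likelihood is additive, finite and shift-invariant", {
  tr <- demo_session(seed = 1, n_per_type = 30)
  p <- prospect_params(0.9, 0.8, 2)
  nll <- negative_log_likelihood(tr, p)
  one_at_a_time <- sum(vapply(seq_len(nrow(tr)), function(i)
    negative_log_likelihood(tr[i, ], p), 0))
  expect_equal(nll, one_at_a_time, tolerance = 1e-9)
  # single trial with equal values: -log(1/2)
  t1 <- tr[1, ]
  t1$p1 <- t1$p2 <- 0.5; t1$m1 <- 50; t1$m2 <- 50
  expect_equal(negative_log_likelihood(t1, p), log(2), tolerance = 1e-12)
  # beta = 0 makes every choice probability 1/2
  expect_equal(negative_log_likelihood(tr, prospect_params(1, 1, 0)),
               nrow(tr) * log(2), tolerance = 1e-9)
  expect_error(negative_log_likelihood(tr[0, ], p), "empty")
})

test_that("simulated-choice frequencies match the analytic softmax", {
  p <- prospect_params(0.8, 0.7, 3)
  tr <- generate_stimulus_set(n_per_type = 5000, seed = 7)
  tr <- simulate_choices(tr, p, seed = 8)
  v1 <- subjective_value(tr$p1, tr$m1, p)
  v2 <- subjective_value(tr$p2, tr$m2, p)
  pr1 <- choice_probability(v1, v2, p$beta)[, 1]
  # aggregate binomial check: total option-1 count within 4 SD of expectation
  expect_lt(abs(sum(tr$choice == 1) - sum(pr1)),
            4 * sqrt(sum(pr1 * (1 - pr1))))
  # calibration within probability strata
  strata <- cut(pr1, c(0, 0.25, 0.5, 0.75, 1))
  emp <- tapply(tr$choice == 1, strata, mean)
  thr <- tapply(pr1, strata, mean)
  expect_true(all(abs(emp - thr) < 0.04))
})

test_that("greedy and indifferent agents behave as limits demand", {
  tr <- generate_stimulus_set(n_per_type = 1500, seed = 3)
  greedy <- simulate_choices(tr, prospect_params(1, 1, 50), seed = 4)
  ev1 <- tr$p1 * tr$m1; ev2 <- tr$p2 * tr$m2
  big <- abs(ev1 - ev2) > 2
  expect_gt(mean(((greedy$choice == 1) == (ev1 > ev2))[big]), 0.99)
  coin <- simulate_choices(tr, prospect_params(1, 1, 0), seed = 5)
  expect_lt(abs(mean(coin$choice == 1) - 0.5), 0.03)
})

test_that("maximum-likelihood fitting is deterministic and recovers truth", {
  truth <- prospect_params(0.8, 0.7, 3)
  tr <- simulate_session(truth, n_per_type = 324, seed = 11)
  f1 <- fit_prospect(tr, seed = 12)
  f2 <- fit_prospect(tr, seed = 12)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  expect_lt(abs(f1$params$alpha - truth$alpha), 0.15)
  expect_lt(abs(f1$params$beta - truth$beta) / truth$beta, 0.5)
  expect_equal(f1$bic, 3 * log(nrow(tr)) + 2 * f1$nll)
})

test_that("a no-signal agent yields a near-zero fitted temperature", {
  tr <- simulate_session(prospect_params(1, 1, 0), n_per_type = 324, seed = 13)
  f <- fit_prospect(tr, seed = 14)
  expect_lt(f$params$beta * max(subjective_value(tr$p1, tr$m1, f$params)), 0.5)
})

test_that("BIC bookkeeping penalizes the larger model by (3-1) log n", {
  tr <- simulate_session(prospect_params(0.5, 0.7, 3), n_per_type = 324,
                         seed = 15)
  cmp <- compare_bic(tr, seed = 16)
  expect_equal(cmp$delta_bic,
               (cmp$prospect$bic - 2 * cmp$prospect$nll) -
                 (cmp$objective_ev$bic - 2 * cmp$objective_ev$nll) +
                 2 * (cmp$prospect$nll - cmp$objective_ev$nll))
  expect_equal(cmp$prospect$bic - 2 * cmp$prospect$nll, 3 * log(nrow(tr)))
  expect_equal(cmp$objective_ev$bic - 2 * cmp$objective_ev$nll, log(nrow(tr)))
  # strongly curved generator: prospect must win at this n
  expect_equal(cmp$preferred, "prospect")
})

test_that("logistic coefficients match an independent IRLS reimplementation", {
  for (seed in c(101, 102, 103)) {
    # a stochastic agent keeps coefficients away from separation
    tr <- demo_session(seed = seed, n_per_type = 150,
                       params = prospect_params(0.8, 0.7, 0.4))
    res <- logistic_choice_analysis(list(tr))
    expect_false(any(res$flagged))
    for (ty in c("comparison", "sequential")) {
      d <- tr[tr$trial_type == ty, ]
      X <- cbind(1, scale(d$p1 - d$p2), scale(d$m1 - d$m2),
                 scale(d$p1 * d$m1 - d$p2 * d$m2))
      b <- irls_logistic(X, as.integer(d$choice == 1))
      expect_equal(unname(res$coefficients[1, , ty]), unname(b),
                   tolerance = 1e-6)
    }
  }
})

test_that("logistic group tests recover the generating choice rule", {
  # choices driven solely by the sign of p1 - p2, with noise
  sessions <- lapply(1:12, function(s) {
    tr <- generate_stimulus_set(n_per_type = 150, seed = 200 + s)
    set.seed(300 + s)
    pr <- plogis(3 * sign(tr$p1 - tr$p2))
    tr$choice <- ifelse(runif(nrow(tr)) < pr, 1L, 2L)
    tr
  })
  res <- logistic_choice_analysis(sessions)
  gt <- res$group_tests
  dp <- gt[gt$coefficient == "dp", ]
  dr <- gt[gt$coefficient == "dr", ]
  expect_true(all(dp$t > 4 | dp$p < 1e-3))
  # magnitude has no group-level influence of its own
  expect_true(all(dr$p > 0.01))
  # second-option bias on sequential trials shows up in the constant
  sessions2 <- lapply(1:12, function(s)
    simulate_session(prospect_params(0.8, 0.7, 2), n_per_type = 150,
                     order_bias = 3, seed = 400 + s))
  res2 <- logistic_choice_analysis(sessions2)
  const_seq <- res2$group_tests[res2$group_tests$coefficient == "constant" &
                                res2$group_tests$trial_type == "sequential", ]
  # bias is toward option 2, i.e. against choosing option 1
  expect_lt(const_seq$mean, 0)
  expect_lt(const_seq$p, 0.05)
})
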