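#' Generate a session's option pairs for both trial types
#'
#' Builds `2 * n_per_type` two-option risky prospects (reward magnitude +
#' reward probability per option), pseudorandomly interleaving `comparison`
#' trials (options shown simultaneously, left/right) and `sequential` trials
#' (options shown one after the other). Probability and magnitude are never
#' identical across the two options of a trial. A configurable proportion of
#' trials are "nobrainers" (one option dominates on both attributes); the
#' rest are "harder" trials where probability and magnitude favour opposite
#' options. Option sides are counterbalanced; on sequential trials option 1
#' is the first-presented option.
#'
#' @param n_per_type Trials per trial type (default 324).
#' @param magnitude_range Range magnitudes are drawn uniformly from.
#' @param probability_set Finite grid probabilities are drawn from (>= 2
#'   distinct values, all in (0,1)).
#' @param prop_nobrainer Target proportion of dominated ("nobrainer") trials.
#' @param seed Integer seed.
#' @return Data frame with columns `trial_id`, `trial_type`, `p1`, `m1`,
#'   `p2`, `m2`, `layout`, `nobrainer`, `choice` (NA), `rt_ms` (NA).
#' @export
generate_stimulus_set <- function(n_per_type = 324,
                                  magnitude_range = c(10, 100),
                                  probability_set = seq(0.2, 0.8, by = 0.1),
                                  prop_nobrainer = 1 / 3,
                                  seed = NULL) {
  stopifnot(n_per_type > 0, prop_nobrainer >= 0, prop_nobrainer <= 1)
  probability_set <- unique(probability_set)
  if (length(probability_set) < 2L)
    stop("probability_set needs >= 2 distinct values: options can never differ")
  if (any(probability_set <= 0 | probability_set >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  if (diff(range(magnitude_range)) <= 0)
    stop("magnitude_range must be nondegenerate")
  n <- 2L * n_per_type
  with_seed(seed, {
    p <- t(replicate(n, sample(probability_set, 2L)))
    m <- matrix(runif(2L * n, magnitude_range[1L], magnitude_range[2L]),
                ncol = 2L)
    while (any(dup <- m[, 1L] == m[, 2L]))  # a.s. never; guards exact ties
      m[dup, 2L] <- runif(sum(dup), magnitude_range[1L], magnitude_range[2L])
    # dominance is imposed by pairing the larger magnitude with the larger
    # (nobrainer) or smaller (harder) probability
    nb <- runif(n) < prop_nobrainer
    m_hi <- pmax(m[, 1L], m[, 2L])
    m_lo <- pmin(m[, 1L], m[, 2L])
    p_hi_first <- p[, 1L] > p[, 2L]
    m1 <- ifelse(nb == p_hi_first, m_hi, m_lo)
    m2 <- ifelse(nb == p_hi_first, m_lo, m_hi)
    trial_type <- sample(rep(c("comparison", "sequential"), n_per_type))
    layout <- character(n)
    for (ty in c("comparison", "sequential")) {
      i <- which(trial_type == ty)
      sides <- sample(rep(c("left", "right"), length.out = length(i)))
      layout[i] <- if (ty == "comparison") paste0("o1-", sides)
                   else paste0("o1-first-", sides)
    }
    data.frame(trial_id = seq_len(n), trial_type = trial_type,
               p1 = p[, 1L], m1 = m1, p2 = p[, 2L], m2 = m2,
               layout = layout, nobrainer = nb,
               choice = NA_integer_, rt_ms = NA_real_)
  })
}

#' Simulate choices (and response times) from a prospect-theory softmax agent
#'
#' Each choice is a Bernoulli draw with the softmax probability implied by
#' the agent's subjective values; on sequential trials an optional additive
#' bias (`order_bias`, in softmax utility units) favours the second-presented
#' option. Response times on comparison trials follow a shifted lognormal
#' whose location decreases with the absolute subjective value difference;
#' sequential response times (from the go cue) are value-independent.
#'
#' @param trials Trial table from [generate_stimulus_set()].
#' @param params A [prospect_params()] agent.
#' @param order_bias Additive utility bias toward the second-presented option
#'   on sequential trials (0 = none).
#' @param seed Integer seed.
#' @param weight_form Probability-weighting form, see [prob_weight()].
#' @param rt_shift_ms,rt_meanlog,rt_sdlog,rt_value_slope Shifted-lognormal
#'   response-time parameters; the comparison-trial location is
#'   `rt_meanlog - rt_value_slope * |z(v1 - v2)|`.
#' @return The trial table with `choice` (1 or 2) and `rt_ms` filled in.
#' @export
simulate_choices <- function(trials, params, order_bias = 0, seed = NULL,
                             weight_form = "tk1992",
                             rt_shift_ms = 300, rt_meanlog = log(600),
                             rt_sdlog = 0.35, rt_value_slope = 0.3) {
  v <- trial_values(trials, params, weight_form)
  u1 <- params$beta * v[, 1L]
  u2 <- params$beta * v[, 2L] +
    order_bias * (trials$trial_type == "sequential")
  p1 <- plogis(u1 - u2)
  with_seed(seed, {
    trials$choice <- ifelse(runif(nrow(trials)) < p1, 1L, 2L)
    dv <- abs(v[, 1L] - v[, 2L])
    zdv <- if (sd(dv) > 0) (dv - mean(dv)) / sd(dv) else dv * 0
    comp <- trials$trial_type == "comparison"
    trials$rt_ms <- rt_shift_ms +
      rlnorm(nrow(trials),
             meanlog = ifelse(comp, rt_meanlog - rt_value_slope * zdv,
                              log(350)),
             sdlog = ifelse(comp, rt_sdlog, 0.3))
    trials
  })
}

#' Write / read a trial table as tab-separated text
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `write_trials_tsv` returns `path` invisibly; `read_trials_tsv`
#'   returns the trial table.
#' @export
write_trials_tsv <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
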