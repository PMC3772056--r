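#' Per-subject peak latency of a named effect
#'
#' Extremum of the signed statistic over a frequency band and time window
#' (flagged edge bins excluded). With `sign = "neg"` (e.g. beta
#' desynchronization) the minimum is taken; with `"pos"` the maximum. Ties
#' are broken deterministically: earliest time, then lowest frequency.
#'
#' @param map An [effect_map()] (or group T-map list from [group_tmap()]).
#' @param band Frequency band (Hz), inclusive.
#' @param window_ms Time window (ms), inclusive.
#' @param sign Expected effect direction, `"neg"` or `"pos"`.
#' @return List (class `peak_record`): `latency_ms`, `freq_hz`, `peak_value`,
#'   `sign`, `band`, `window_ms`.
#' @export
peak_latency <- function(map, band = c(13, 30), window_ms, sign = c("neg", "pos")) {
  sign <- match.arg(sign)
  if (is.list(map) && !inherits(map, "effect_map"))
    map <- effect_map(map$tmap, map$freqs, map$times_ms, edge = map$exclude)
  fi <- which(map$freqs >= band[1L] & map$freqs <= band[2L])
  ti <- which(map$times_ms >= window_ms[1L] & map$times_ms <= window_ms[2L])
  if (length(fi) == 0L || length(ti) == 0L) stop("empty search region")
  sub <- map$values[fi, ti, drop = FALSE]
  sub[map$edge[fi, ti, drop = FALSE]] <- NA
  if (all(is.na(sub))) stop("search region entirely edge-flagged")
  sg <- if (sign == "neg") -1 else 1
  ext <- max(sg * sub, na.rm = TRUE)
  # column-major order of (freq x time) runs freq-fastest within each time:
  # the first match is the earliest time, then the lowest frequency
  hit <- which(sg * sub == ext)[1L]
  f_at <- fi[(hit - 1L) %% length(fi) + 1L]
  t_at <- ti[(hit - 1L) %/% length(fi) + 1L]
  structure(list(latency_ms = map$times_ms[t_at], freq_hz = map$freqs[f_at],
                 peak_value = sg * ext, sign = sign, band = band,
                 window_ms = window_ms), class = "peak_record")
}

#' Paired test on peak latencies (or peak sizes) between two effects
#'
#' Paired t-test on per-subject differences `a - b` with `df = n - 1`; the
#' median difference is reported alongside. A zero-variance difference
#' vector is flagged degenerate (t undefined).
#'
#' @param peaks_a,peaks_b Numeric vectors (e.g. latencies in ms), same
#'   subjects in the same order; lists of `peak_record`s are unwrapped.
#' @param alternative Test sidedness for `mean(a - b)`, as in
#'   [stats::t.test()].
#' @return List (class `paired_test`): `t`, `df`, `p`, `mean_diff`,
#'   `median_diff`, `differences`, `degenerate`.
#' @export
paired_latency_test <- function(peaks_a, peaks_b,
                                alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  unwrap <- function(x) {
    if (is.list(x) && all(vapply(x, inherits, logical(1L), "peak_record")))
      vapply(x, `[[`, numeric(1L), "latency_ms") else as.numeric(x)
  }
  a <- unwrap(peaks_a); b <- unwrap(peaks_b)
  if (length(a) != length(b)) stop("mismatched subject sets")
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    # all differences identical: t is 0 for a zero difference, undefined
    # otherwise; flagged either way so callers notice
    return(structure(list(t = if (mean(d) == 0) 0 else NA_real_,
                          df = n - 1L, p = NA_real_,
                          mean_diff = mean(d), median_diff = median(d),
                          differences = d, degenerate = TRUE),
                     class = "paired_test"))
  }
  tt <- t.test(d, alternative = alternative)
  structure(list(t = unname(tt$statistic), df = n - 1L, p = tt$p.value,
                 mean_diff = mean(d), median_diff = median(d),
                 differences = d, degenerate = FALSE),
            class = "paired_test")
}

#' 2x2 within-subject (region x condition) interaction on peak effects
#'
#' Repeated-measures interaction computed from the per-subject
#' double-difference `d = (A1 - A2) - (B1 - B2)`; its paired t against zero
#' squared is the interaction F with df (1, n-1). Post-hoc paired t-tests
#' compare the two conditions within each region.
#'
#' @param cells `n x 4` matrix or data frame with columns
#'   `A1, A2, B1, B2` (region A/B, condition 1/2 peak effect sizes).
#' @param posthoc_alternative Sidedness for the post-hoc tests (recycled to
#'   length 2, one per region).
#' @return List (class `interaction_test`): `F`, `df`, `p`,
#'   `double_difference`, `posthoc` (per-region paired tests).
#' @export
interaction_2x2 <- function(cells, posthoc_alternative = "two.sided") {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4L) stop("need exactly the four A1, A2, B1, B2 cells")
  if (anyNA(cells)) stop("missing cells in the 2x2 table")
  colnames(cells) <- c("A1", "A2", "B1", "B2")
  n <- nrow(cells)
  d <- (cells[, "A1"] - cells[, "A2"]) - (cells[, "B1"] - cells[, "B2"])
  tt <- if (sd(d) > 0) t.test(d) else NULL
  Fval <- if (is.null(tt)) 0 else unname(tt$statistic)^2
  pval <- if (is.null(tt)) 1 else pf(Fval, 1, n - 1L, lower.tail = FALSE)
  alt <- rep(posthoc_alternative, length.out = 2L)
  posthoc <- list(
    region_a = paired_latency_test(cells[, "A1"], cells[, "A2"],
                                   alternative = alt[1L]),
    region_b = paired_latency_test(cells[, "B1"], cells[, "B2"],
                                   alternative = alt[2L]))
  structure(list(F = Fval, df = c(1L, n - 1L), p = pval,
                 double_difference = d, posthoc = posthoc),
            class = "interaction_test")
}
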