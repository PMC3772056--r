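#' Stack per-subject effect maps for group inference
#'
#' @param maps List of [effect_map()]s on identical grids, one per subject.
#' @return An object of class `group_stack`: `values`
#'   (`subjects x freqs x times`), `freqs`, `times_ms`, `exclude` (union of
#'   the subjects' edge flags), `name`.
#' @export
group_stack <- function(maps) {
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, logical(1L), "effect_map")))
  f <- maps[[1L]]$freqs; t <- maps[[1L]]$times_ms
  for (m in maps)
    if (!isTRUE(all.equal(m$freqs, f)) || !isTRUE(all.equal(m$times_ms, t)))
      stop("effect maps are on different grids")
  vals <- aperm(vapply(maps, function(m) m$values,
                       matrix(0, length(f), length(t))), c(3L, 1L, 2L))
  excl <- Reduce(`|`, lapply(maps, `[[`, "edge"))
  flat <- matrix(vals, dim(vals)[1L], length(f) * length(t))
  if (any(!is.finite(flat[, !as.vector(excl), drop = FALSE])))
    stop("non-finite effect values outside flagged edge bins")
  structure(list(values = vals, freqs = f, times_ms = t, exclude = excl,
                 name = maps[[1L]]$name), class = "group_stack")
}

#' Group-level one-sample T-map
#'
#' One-sample t statistic against zero per time-frequency bin across
#' subjects, `df = n - 1`. Bins with zero between-subject variance give
#' (sign-preserving) infinite t and are flagged.
#'
#' @param stack A [group_stack()].
#' @return List with `tmap` (`freqs x times`), `df`, `n`, `degenerate`
#'   (logical matrix of zero-variance bins), and the stack's `exclude` mask.
#' @export
group_tmap <- function(stack) {
  stopifnot(inherits(stack, "group_stack"))
  n <- dim(stack$values)[1L]
  m <- apply(stack$values, c(2L, 3L), mean)
  s <- apply(stack$values, c(2L, 3L), sd)
  tmap <- ifelse(s > 0, m / (s / sqrt(n)), sign(m) * Inf)
  list(tmap = tmap, df = n - 1L, n = n, degenerate = s == 0 & m != 0,
       exclude = stack$exclude, freqs = stack$freqs,
       times_ms = stack$times_ms)
}

#' Extract supra-threshold clusters from a T-map
#'
#' Connected components of bins with `t > threshold` (positive clusters) and
#' `t < -threshold` (negative clusters) under 4- or 8-connectivity on the
#' time-frequency grid; excluded (edge) bins never join a cluster.
#'
#' @param tmap `freqs x times` t matrix (or a [group_tmap()] result).
#' @param threshold Cluster-forming threshold (on t, default 2.0).
#' @param connectivity 4 (edge-sharing neighbours) or 8 (plus diagonals).
#' @param tail `"both"`, `"pos"` or `"neg"`: which signed families to form.
#' @param exclude Optional logical `freqs x times` exclusion mask.
#' @return List of clusters, each with `members` (two-column bin index
#'   matrix), `extent`, `sign`, `peak_t`, `peak_freq`, `peak_time_ms`.
#' @export
extract_clusters <- function(tmap, threshold = 2, connectivity = 4,
                             tail = c("both", "pos", "neg"), exclude = NULL) {
  tail <- match.arg(tail)
  if (is.list(tmap)) {
    if (is.null(exclude)) exclude <- tmap$exclude
    freqs <- tmap$freqs; times <- tmap$times_ms
    tmap <- tmap$tmap
  } else {
    freqs <- seq_len(nrow(tmap)); times <- seq_len(ncol(tmap))
  }
  if (is.null(exclude)) exclude <- matrix(FALSE, nrow(tmap), ncol(tmap))
  stopifnot(connectivity %in% c(4L, 8L))
  out <- list()
  signs <- switch(tail, both = c(1, -1), pos = 1, neg = -1)
  for (sg in signs) {
    mask <- !exclude & (sg * tmap > threshold)
    mask[is.na(mask)] <- FALSE
    labels <- label_components(mask, as.integer(connectivity))
    k <- max(labels)
    if (k == 0L) next
    for (lab in seq_len(k)) {
      members <- which(labels == lab, arr.ind = TRUE)
      tv <- tmap[members]
      pk <- which.max(sg * tv)
      out[[length(out) + 1L]] <- list(
        members = members, extent = nrow(members), sign = sg,
        peak_t = tv[pk], peak_freq = freqs[members[pk, 1L]],
        peak_time_ms = times[members[pk, 2L]])
    }
  }
  out[order(-vapply(out, `[[`, numeric(1L), "extent"))]
}

#' Sign-flip null distribution of the maximum cluster extent
#'
#' Under the one-sample null of zero group mean, every subject's whole effect
#' map is multiplied by an independent fair +-1, the group T-map is
#' recomputed, and the maximum supra-threshold cluster extent is recorded.
#' Deterministic given `seed`. For `n <= 12` subjects an exhaustive mode
#' enumerates all `2^n` sign assignments.
#'
#' @param stack A [group_stack()].
#' @param threshold Cluster-forming threshold on t.
#' @param n_perm Number of random sign flips (ignored when `exhaustive`).
#' @param connectivity 4 or 8.
#' @param tail `"both"`: record the maximum extent over positive and negative
#'   clusters jointly (a single null controlling the whole plane across both
#'   signs); `"pos"`/`"neg"`: one signed family; `"both_separate"`: record
#'   the two signed maxima separately (each cluster is then compared with its
#'   own signed null).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all sign assignments (requires `n <= 12`).
#' @return List with `max_extent` (vector, or two-column matrix for
#'   `"both_separate"`), `n_perm`, `tail`, `threshold`, `exhaustive`.
#' @export
signflip_null <- function(stack, threshold = 2, n_perm = 5000,
                          connectivity = 4,
                          tail = c("both", "pos", "neg", "both_separate"),
                          seed = NULL, exhaustive = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(stack, "group_stack"), n_perm >= 1)
  n <- dim(stack$values)[1L]
  nf <- length(stack$freqs); nt <- length(stack$times_ms)
  X <- matrix(stack$values, n, nf * nt)
  X[!is.finite(X)] <- 0       # flagged/degenerate bins are excluded anyway
  if (exhaustive) {
    if (n > 12L) stop("exhaustive enumeration limited to n <= 12 subjects")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(S)
  } else {
    S <- with_seed(seed,
                   matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                          n_perm, n))
  }
  ss <- colSums(X^2)
  M <- S %*% X / n                         # permuted means, n_perm x B
  V <- sweep(n * M^2, 2L, ss, function(a, b) (b - a) / (n - 1L))
  Tm <- M / sqrt(pmax(V, 0) / n)
  Tm[!is.finite(Tm)] <- 0
  excl <- stack$exclude
  res <- matrix(0L, n_perm, 2L)
  for (i in seq_len(n_perm)) {
    res[i, ] <- max_cluster_extents(matrix(Tm[i, ], nf, nt), threshold,
                                    as.integer(connectivity), excl)
  }
  max_extent <- switch(tail,
    both = pmax(res[, 1L], res[, 2L]),
    pos = res[, 1L],
    neg = res[, 2L],
    both_separate = res)
  list(max_extent = max_extent, n_perm = n_perm, tail = tail,
       threshold = threshold, exhaustive = exhaustive)
}

#' Permutation-corrected cluster p-values
#'
#' `p = (1 + #\{null >= observed extent\}) / (1 + n_perm)`: the observed data
#' count as one member of their own null, so p is never zero and is bounded
#' below by `1/(n_perm + 1)`. In exhaustive mode the identity flip is already
#' in the enumeration and `p = mean(null >= observed)`.
#'
#' @param clusters [extract_clusters()] output.
#' @param null A [signflip_null()] result.
#' @param alpha Significance level.
#' @return An object of class `cluster_result`: the clusters with `p` and
#'   `significant` added, plus the null summary.
#' @export
corrected_p <- function(clusters, null, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    nd <- if (is.matrix(null$max_extent)) {
      null$max_extent[, if (cl$sign > 0) 1L else 2L]
    } else null$max_extent
    p <- if (null$exhaustive) mean(nd >= cl$extent)
         else (1 + sum(nd >= cl$extent)) / (1 + null$n_perm)
    clusters[[i]]$p <- p
    clusters[[i]]$significant <- p < alpha
  }
  structure(list(clusters = clusters, alpha = alpha, null = null),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), %d permutations (%s tail)\n",
              length(x$clusters), x$null$n_perm, x$null$tail))
  for (cl in x$clusters)
    cat(sprintf("  %s extent %d, peak T = %.2f at %.3g Hz / %g ms, p = %.4g%s\n",
                if (cl$sign > 0) "positive" else "negative", cl$extent,
                cl$peak_t, cl$peak_freq, cl$peak_time_ms, cl$p,
                if (cl$significant) " *" else ""))
  invisible(x)
}

#' Group cluster-based permutation test, end to end
#'
#' Convenience wrapper: one-sample group T-map, supra-threshold cluster
#' extraction, sign-flip null of the maximum cluster extent, and corrected
#' p-values.
#'
#' @inheritParams signflip_null
#' @param alpha Significance level.
#' @return A `cluster_result` (see [corrected_p()]) with the `tmap` attached.
#' @export
cluster_test <- function(stack, threshold = 2, n_perm = 5000,
                         connectivity = 4, tail = "both", alpha = 0.05,
                         seed = NULL, exhaustive = FALSE) {
  tm <- group_tmap(stack)
  cl_tail <- if (tail %in% c("both", "both_separate")) "both" else tail
  clusters <- extract_clusters(tm, threshold = threshold,
                               connectivity = connectivity, tail = cl_tail)
  null <- signflip_null(stack, threshold = threshold, n_perm = n_perm,
                        connectivity = connectivity, tail = tail,
                        seed = seed, exhaustive = exhaustive)
  res <- corrected_p(clusters, null, alpha = alpha)
  res$tmap <- tm
  res
}
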