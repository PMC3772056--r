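random_stack <- function(n = 10, nf = 8, nt = 12, seed = 1, shift = 0) {
  set.seed(seed)
  maps <- lapply(seq_len(n), function(i)
    effect_map(matrix(rnorm(nf * nt) + shift, nf), seq_len(nf) + 10,
               seq(0, by = 50, length.out = nt)))
  group_stack(maps)
}

test_that("group T-maps are antisymmetric and flag degenerate bins", {
  st <- random_stack(n = 12, seed = 2)
  tm <- group_tmap(st)
  expect_equal(tm$df, 11)
  neg <- st
  neg$values <- -st$values
  expect_equal(group_tmap(neg)$tmap, -tm$tmap)
  # identical nonzero values across subjects: infinite t, flagged
  same <- random_stack(n = 6, seed = 3)
  same$values[, 1, 1] <- 4
  tm2 <- group_tmap(same)
  expect_true(is.infinite(tm2$tmap[1, 1]) && tm2$tmap[1, 1] > 0)
  expect_true(tm2$degenerate[1, 1])
})

test_that("bin-wise null T values follow Student-t quantiles", {
  set.seed(4)
  n <- 15
  maps <- lapply(seq_len(n), function(i)
    effect_map(matrix(rnorm(50 * 40), 50), seq_len(50),
               seq_len(40)))
  tm <- group_tmap(group_stack(maps))
  tv <- as.vector(tm$tmap)
  expect_lt(abs(var(tv) - 14 / 12), 0.12)
  expect_lt(max(abs(quantile(tv, c(0.05, 0.5, 0.95)) -
                      qt(c(0.05, 0.5, 0.95), 14))), 0.12)
})

test_that("cluster extraction respects threshold, blocks and adjacency", {
  tm <- matrix(0, 10, 12)
  expect_length(extract_clusters(tm, threshold = 2), 0)
  tm[3:7, 2:5] <- 3                       # 5 x 4 block
  cl <- extract_clusters(tm, threshold = 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$extent, 20)
  expect_equal(cl[[1]]$sign, 1)
  # diagonal touch: two clusters under 4-connectivity, one under 8
  tm2 <- matrix(0, 6, 6)
  tm2[1:2, 1:2] <- 3
  tm2[3:4, 3:4] <- 3
  expect_length(extract_clusters(tm2, 2, connectivity = 4), 2)
  expect_length(extract_clusters(tm2, 2, connectivity = 8), 1)
  # negative clusters are their own family
  tm3 <- matrix(0, 4, 4)
  tm3[1:2, 1:2] <- -5
  cl3 <- extract_clusters(tm3, 2, tail = "both")
  expect_equal(cl3[[1]]$sign, -1)
  expect_length(extract_clusters(tm3, 2, tail = "pos"), 0)
  # excluded bins never join clusters
  excl <- matrix(FALSE, 10, 12)
  excl[3, ] <- TRUE
  cl4 <- extract_clusters(tm, 2, exclude = excl)
  expect_equal(max(vapply(cl4, `[[`, 0, "extent")), 16)
})

test_that("corrected p-values follow the counting convention", {
  null <- list(max_extent = 1:100, n_perm = 100, tail = "both",
               threshold = 2, exhaustive = FALSE)
  cl <- list(list(members = cbind(1, 1:90), extent = 90, sign = 1,
                  peak_t = 3, peak_freq = 1, peak_time_ms = 0))
  res <- corrected_p(cl, null)
  expect_equal(res$clusters[[1]]$p, (1 + 11) / 101)
  # larger than every null draw: the lower bound 1/(n_perm + 1)
  cl[[1]]$extent <- 500
  expect_equal(corrected_p(cl, null)$clusters[[1]]$p, 1 / 101)
  # monotonicity: larger extent never has larger p
  ps <- vapply(c(5, 20, 50, 90, 101), function(e) {
    cl[[1]]$extent <- e
    corrected_p(cl, null)$clusters[[1]]$p
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("sign-flip nulls are seeded, sign-symmetric and scale-invariant", {
  st <- random_stack(n = 10, seed = 5, shift = 0.4)
  n1 <- signflip_null(st, n_perm = 300, seed = 6)
  n2 <- signflip_null(st, n_perm = 300, seed = 6)
  expect_identical(n1$max_extent, n2$max_extent)
  # global sign flip of the data leaves the (both-tail) null unchanged
  neg <- st
  neg$values <- -st$values
  n3 <- signflip_null(neg, n_perm = 300, seed = 6)
  expect_identical(n1$max_extent, n3$max_extent)
  # scaling all subjects by a positive constant changes nothing anywhere
  sc <- st
  sc$values <- st$values * 3.7
  r1 <- cluster_test(st, n_perm = 200, seed = 7)
  r2 <- cluster_test(sc, n_perm = 200, seed = 7)
  expect_equal(vapply(r1$clusters, `[[`, 0, "p"),
               vapply(r2$clusters, `[[`, 0, "p"))
  expect_equal(vapply(r1$clusters, `[[`, 0L, "extent"),
               vapply(r2$clusters, `[[`, 0L, "extent"))
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  for (seed in c(8, 9)) {
    st <- random_stack(n = 10, seed = seed, shift = 0.55)
    ex <- cluster_test(st, n_perm = 1024, seed = 1, exhaustive = TRUE)
    mc <- cluster_test(st, n_perm = 2000, seed = seed + 50)
    expect_gt(length(ex$clusters), 0)
    for (i in seq_along(ex$clusters)) {
      p_ex <- ex$clusters[[i]]$p
      p_mc <- mc$clusters[[i]]$p
      tol <- 3 * sqrt(p_ex * (1 - p_ex) / 2000) + 1 / 2000
      expect_lt(abs(p_ex - p_mc), max(tol, 0.02))
    }
  }
  st <- random_stack(n = 13, seed = 10)
  expect_error(signflip_null(st, exhaustive = TRUE), "n <= 12")
})

test_that("the exhaustive null contains the identity flip, bounding p above zero", {
  st <- random_stack(n = 8, seed = 11, shift = 1)
  ex <- cluster_test(st, seed = 1, exhaustive = TRUE)
  for (cl in ex$clusters) expect_gte(cl$p, 1 / 2^8)
})

test_that("full-pipeline null effects are t-calibrated at the group level", {
  # one null dataset through stimuli -> choices -> epochs -> wavelets ->
  # regression -> group T; bin-wise variance should match Student-t(n-1)
  basis <- morlet_basis(200, 600, c(-1000, 2000),
                        tf_config(freqs = seq(6, 38, 4)),
                        time_step_ms = 25, time_range_ms = c(0, 1200))
  set.seed(20)
  n_sub <- 12
  maps <- lapply(draw_subject_params(n_sub), function(pp) {
    tr <- simulate_session(pp, n_per_type = 120)
    st <- tr[tr$trial_type == "sequential", ]
    ep <- simulate_epochs(st, ground_truth(g_value = 0, g_choice = 0),
                          value = st$p1 * st$m1)
    regress_power(morlet_power(ep, basis = basis),
                  build_design(st, "option1"))$effects$v_opt1
  })
  tm <- group_tmap(group_stack(maps))
  tv <- tm$tmap[!tm$exclude]
  df <- n_sub - 1
  expect_lt(abs(mean(tv)), 0.2)
  expect_lt(abs(var(tv) - df / (df - 2)), 0.35)
  expect_lt(mean(abs(tv) > qt(0.975, df)), 0.12)
})
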