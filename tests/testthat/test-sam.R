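# Plain-R re-implementation of the d statistic used as an oracle below.
oracle_d <- function(x, male_idx, s0) {
  apply(x, 1, function(row) {
    a <- row[male_idx]; b <- row[-male_idx]
    sa <- sum((a - mean(a))^2); sb <- sum((b - mean(b))^2)
    s <- sqrt((1 / length(a) + 1 / length(b)) * (sa + sb) /
                (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (s + s0)
  })
}

test_that("relative difference follows the pooled-scatter formula", {
  # males (3,5), females (1,3): diff 2, s = sqrt((1/2+1/2)*(2+2)/2) = sqrt(2)
  x <- matrix(c(3, 5, 1, 3), 1, 4)
  ps <- pooled_scatter(x, 1:2, 3:4)
  expect_equal(ps$s, sqrt(2))
  expect_equal(relative_difference(ps$mean_a, ps$mean_b, ps$s, 0), sqrt(2))

  # equal group means -> d = 0
  x0 <- matrix(c(1, 3, 3, 1), 1, 4)
  ps0 <- pooled_scatter(x0, 1:2, 3:4)
  expect_equal(relative_difference(ps0$mean_a, ps0$mean_b, ps0$s, 0), 0)

  # translation invariance
  set.seed(2)
  xm <- matrix(rnorm(40), 5, 8)
  p1 <- pooled_scatter(xm, 1:4, 5:8)
  p2 <- pooled_scatter(xm + 11.5, 1:4, 5:8)
  expect_equal(relative_difference(p1$mean_a, p1$mean_b, p1$s, 0.1),
               relative_difference(p2$mean_a, p2$mean_b, p2$s, 0.1))

  # zero denominator guard
  xc <- matrix(5, 1, 4)
  psc <- pooled_scatter(xc, 1:2, 3:4)
  expect_error(relative_difference(psc$mean_a, psc$mean_b, psc$s, 0),
               "zero denominator")
})

test_that("s0 selection honors fixed percentiles, ties and the cv oracle", {
  set.seed(31)
  numer <- rnorm(500)
  s <- rexp(500) + 0.05
  expect_equal(choose_s0(numer, s, list(fixed_percentile = 0)), min(s))
  expect_equal(choose_s0(numer, s, list(fixed_percentile = 1)), max(s))

  expect_warning(s0_deg <- choose_s0(numer, rep(2, 500), "cv_minimization"),
                 "degenerate")
  expect_equal(s0_deg, 2)  # tie rule: smallest candidate = 0th percentile

  # independent re-implementation of the selection loop
  cand <- unname(quantile(s, seq(0, 0.95, 0.05)))
  windows <- split(order(s), rep(1:100, each = 5))
  cv <- sapply(cand, function(alpha) {
    spreads <- sapply(windows, function(i) {
      d <- numer[i] / (s[i] + alpha)
      median(abs(d - median(d))) * 1.4826
    })
    sd(spreads) / mean(spreads)
  })
  expect_equal(choose_s0(numer, s, "cv_minimization"), cand[which.min(cv)])
})

test_that("permutation null enumerates exhaustively and matches brute force", {
  set.seed(41)
  x <- matrix(rnorm(8 * 20), 20, 8)
  male <- rep(c(TRUE, FALSE), each = 4)

  null <- permutation_null(x, male, s0 = 0.1, sam_config())
  expect_true(null$exhaustive)
  expect_equal(null$n_perm, choose(8, 4))  # 70 arrangements

  # brute-force oracle: enumerate, compute d per arrangement, average sorted
  arr <- combn(8, 4)
  d_all <- apply(arr, 2, function(ix) sort(oracle_d(x, ix, 0.1)))
  expect_equal(null$d_sorted, d_all)
  expect_equal(null$dbar, rowMeans(d_all))

  # 2 vs 2 -> C(4,2) = 6 arrangements (coarse, so it warns)
  x4 <- matrix(rnorm(4 * 15), 15, 4)
  expect_warning(
    null4 <- permutation_null(x4, c(TRUE, TRUE, FALSE, FALSE), 0.1,
                              sam_config()),
    "coarse")
  expect_equal(null4$n_perm, 6)

  # sampling path draws distinct arrangements and includes the original
  cfg <- sam_config(n_permutations = 100, seed = 5, exhaustive_cap = 10)
  nulls <- permutation_null(x, male, 0.1, cfg)
  expect_false(nulls$exhaustive)
  expect_equal(nulls$n_perm, 70)  # capped at the number of distinct ones
  expect_equal(nulls$dbar, null$dbar)  # all-distinct draw = full enumeration
})

test_that("delta thresholding reproduces a hand trace", {
  d_sorted <- c(-3, -1.5, -0.5, 0, 0.4, 0.8, 1.1, 2.5, 3.0, 4.0)
  dbar <- c(-2.0, -1.4, -0.6, 0, 0.3, 0.7, 1.0, 1.5, 2.0, 2.4)
  # gaps: -1.0 -0.1 0.1 0 0.1 0.1 0.1 1.0 1.0 1.6
  res <- call_at_delta(d_sorted, dbar, delta = 0.9)
  expect_equal(res$cut_up, 2.5)          # smallest d with gap >= 0.9
  expect_equal(res$cut_low, -3)          # largest d with gap <= -0.9
  expect_equal(which(res$called_pos), 8:10)
  expect_equal(which(res$called_neg), 1)

  # delta = 0: cutoffs collapse onto the first gap sign changes
  res0 <- call_at_delta(d_sorted, dbar, delta = 0)
  expect_equal(res0$cut_up, -0.5)   # smallest d with gap >= 0 (i = 3)
  expect_equal(res0$cut_low, 0)     # largest d with gap <= 0 (i = 4)

  # delta beyond max gap: nothing called
  res_big <- call_at_delta(d_sorted, dbar, delta = 2)
  expect_equal(res_big$cut_up, Inf)
  expect_equal(res_big$cut_low, -Inf)
  expect_false(any(res_big$called_pos | res_big$called_neg))
})

test_that("label swap negates d and exchanges the called tails", {
  sim <- simulate_dataset(sim_config(seed = 13, n_per_sex = 4,
                                     n_autosomal = 150, n_z = 80, n_w = 10,
                                     noise_log2_sd = 0.4))
  ds <- sim$dataset
  cfg <- sam_config(seed = 1, s0_strategy = list(fixed_percentile = 0.5))
  r1 <- sam_test(ds, cfg)           # 4 vs 4 -> exhaustive
  r2 <- sam_test(swap_sex_labels(ds), cfg)
  expect_true(r1$exhaustive)
  expect_equal(r2$table$d, -r1$table$d)
  expect_equal(r2$table$called_positive, r1$table$called_negative)
  expect_equal(r2$table$called_negative, r1$table$called_positive)
  expect_equal(r2$table$q_value, r1$table$q_value)
})

test_that("spiked two-fold probesets are recovered at 5% FDR", {
  # 50 true male-biased two-fold spikes among 1000 probesets, 9 vs 9
  cfg <- sim_config(seed = 17, n_autosomal = 950, n_z = 50, n_w = 0,
                    frac_z_compensated = 0, noncompensated_mf = 2,
                    noise_log2_sd = 0.25)
  sim <- simulate_dataset(cfg)
  res <- sam_test(sim$dataset,
                  sam_config(n_permutations = 300, seed = 23,
                             exhaustive_cap = 100))
  spikes <- sim$truth$probeset_id[sim$truth$true_class == "z_noncompensated"]
  called <- res$table$probeset_id[res$table$called_positive]
  expect_gte(length(intersect(called, spikes)), 45)
  # and the calls are overwhelmingly the spikes
  expect_lte(length(setdiff(called, spikes)), ceiling(0.15 * length(called)))
})

test_that("q-values decrease with the distance-from-expected rank", {
  sim <- simulate_dataset(sim_config(seed = 29, n_autosomal = 400, n_z = 200,
                                     n_w = 0, noise_log2_sd = 0.3))
  res <- sam_test(sim$dataset, sam_config(n_permutations = 200, seed = 3,
                                          exhaustive_cap = 100))
  tab <- res$table
  ord <- res$d_order
  d_sorted <- tab$d[ord]
  q_sorted <- tab$q_value[ord]
  # upper tail: q non-increasing as d grows (nested called sets)
  pos <- d_sorted > 0
  expect_true(all(diff(q_sorted[pos]) <= 1e-12))
  # lower tail: q non-decreasing as d grows towards zero
  neg <- d_sorted < 0
  expect_true(all(diff(q_sorted[neg]) >= -1e-12))
})
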