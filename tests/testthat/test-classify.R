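fake_sam <- function(ids, pos = logical(length(ids)),
                     neg = logical(length(ids))) {
  data.frame(probeset_id = ids, called_positive = pos, called_negative = neg,
             stringsAsFactors = FALSE)
}

fake_ratios <- function(ids, mf) {
  data.frame(probeset_id = ids, mean_male = mf, mean_female = 1,
             mf_ratio = mf, log2_mf = log2(mf), fm_ratio = 1 / mf,
             stringsAsFactors = FALSE)
}

test_that("bias classification applies the FDR-then-ratio funnel", {
  ids <- paste0("p", 1:5)
  # p1: sig + ratio 1.75 -> male; p2: sig but ratio 1.2 -> none;
  # p3: not sig, ratio 5 -> none; p4: sig but ratio 4 (above 3.2) -> none;
  # p5: sig negative with F:M 2 -> female
  sam <- fake_sam(ids, pos = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                  neg = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ratios <- fake_ratios(ids, c(1.75, 1.2, 5, 4, 0.5))
  bc <- classify_bias(sam, ratios)
  expect_equal(bc$direction, c("male", "none", "none", "none", "female"))
  funnel <- attr(bc, "funnel")
  expect_equal(unname(funnel$male), c(3, 1))
  expect_equal(unname(funnel$female), c(1, 1))
  # funnel monotone: ratio stage is a subset of the FDR stage
  expect_true(all(bc$passed_ratio <= bc$passed_fdr))

  # upper bound disabled: p4 (ratio 4) becomes male-biased
  bc2 <- classify_bias(sam, ratios, use_upper_bound = FALSE)
  expect_equal(bc2$direction[4], "male")
})

test_that("compensation banding is inclusive and partitions completely", {
  ids <- paste0("p", 1:6)
  # Gga.3546.1.S1_at-like 1.95 -> non-compensated; Gga.9708.2.S1_a_at-like
  # 1.23 -> compensated; band edges 0.8, 1.3, 1.5 and midpoints
  ratios <- fake_ratios(ids, c(1.95, 1.23, 1.4, 1.0, 1.3, 1.5))
  cc <- classify_compensation(ratios)
  expect_equal(cc$class, c("non_compensated", "compensated", "intermediate",
                           "compensated", "compensated", "non_compensated"))
  expect_equal(sort(table(cc$class), decreasing = TRUE)[["compensated"]], 3)
  expect_equal(nrow(cc), length(ids))  # every ratio maps to exactly one class

  # chromosome restriction via annotation
  ann <- toy_annotation(ids, c("Z", "Z", "Z", "1", "1", "Z"))
  ccz <- classify_compensation(ratios, annotation = ann, chromosome = "Z")
  expect_equal(nrow(ccz), 4)
  expect_true(all(ccz$probeset_id %in% ids[c(1, 2, 3, 6)]))
})

test_that("chromosome distribution preserves totals across strata", {
  ids <- paste0("p", 1:10)
  ann <- toy_annotation(ids[1:8], c("Z", "Z", "Z", "1", "2", "W",
                                    "Un_random", "unknown"),
                        position_bp = c(1:5 * 1e6, NA, NA, NA))
  counts <- chromosome_distribution(ids, ann)  # p9, p10 unannotated
  expect_equal(sum(counts), 10)
  expect_equal(unname(counts["Z"]), 3)
  expect_equal(unname(counts["unknown"]), 3)

  all_z <- chromosome_distribution(ids[1:3], ann)
  expect_equal(all_z, c(Z = 3L))
})

test_that("female-biased calls concentrate on W in synthetic truth", {
  sim <- simulate_dataset(sim_config(seed = 33, n_autosomal = 500, n_z = 200,
                                     n_w = 25))
  fds <- detection_filter(sim$dataset)
  r <- sex_ratios(fds)
  res <- sam_test(fds, sam_config(n_permutations = 200, seed = 2,
                                  exhaustive_cap = 100))
  bc <- classify_bias(res, r)
  female_ids <- bc$probeset_id[bc$direction == "female"]
  expect_gt(length(female_ids), 0)
  dist <- chromosome_distribution(female_ids, sim$annotation)
  expect_gte(sum(dist[names(dist) == "W"]) / sum(dist), 0.9)
})

test_that("rank-sum comparison matches exhaustive enumeration", {
  # A = {1,2}, B = {3,4}: one-sided p = 1/6, two-sided 1/3
  expect_equal(rank_sum_compare(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  expect_equal(rank_sum_compare(c(1, 2), c(3, 4))$p_value, 1 / 3)

  # identical multisets -> p = 1 under the tie-corrected approximation
  expect_equal(rank_sum_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # property: exact p equals enumeration over all C(n_a+n_b, n_a) splits
  set.seed(55)
  for (rep in 1:10) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    vals <- sample(100, n_a + n_b)  # no ties
    a <- vals[1:n_a]; b <- vals[-(1:n_a)]
    obs_u <- sum(outer(a, b, ">"))
    splits <- combn(n_a + n_b, n_a)
    u_all <- apply(splits, 2, function(ix)
      sum(outer(vals[ix], vals[-ix], ">")))
    p_greater <- mean(u_all >= obs_u)
    expect_equal(rank_sum_compare(a, b, "greater")$p_value, p_greater)
  }

  # large shifted samples are detected decisively
  set.seed(7)
  za <- rnorm(500, 0.5, 0.5)
  aut <- rnorm(500, 0, 0.5)
  expect_lt(rank_sum_compare(za, aut)$p_value, 1e-6)
})

test_that("chromosome summary recovers construction-level means", {
  # noise-free: non-compensated male-female gap is exactly 1 log2 unit
  cfg <- sim_config(seed = 61, n_autosomal = 300, n_z = 200, n_w = 0,
                    noise_log2_sd = 0, frac_z_compensated = 0.3,
                    noncompensated_mf = 2)
  sim <- simulate_dataset(cfg)
  r <- sex_ratios(sim$dataset)
  cc <- classify_compensation(r, annotation = sim$annotation, chromosome = "Z")
  cs <- chromosome_summary(r, sim$dataset, sim$annotation, cc)
  strata <- cs$strata
  expect_equal(strata$gap[strata$stratum == "non_compensated"], 1.0)
  expect_equal(strata$gap[strata$stratum == "autosomes"], 0.0)
  aut_rows <- cs$per_chromosome$chromosome != "Z"
  expect_equal(max(abs(cs$per_chromosome$mean_log2_mf[aut_rows])), 0)
  # chromosome 32, W, unplaced strata never appear in the per-chromosome table
  expect_false(any(cs$per_chromosome$chromosome %in%
                     c("32", "W", "Un_random", "unknown")))

  # noisy seeded run recovers the truth-mixture expectation
  cfg2 <- sim_config(seed = 62, n_autosomal = 0, n_z = 2000, n_w = 0,
                     frac_z_compensated = 0.3, noise_log2_sd = 0.25)
  sim2 <- simulate_dataset(cfg2)
  r2 <- sex_ratios(sim2$dataset)
  expect_warning(
    cs2 <- chromosome_summary(r2, sim2$dataset, sim2$annotation, NULL),
    "empty stratum")  # no autosomes were simulated
  z_mean <- cs2$per_chromosome$mean_log2_mf[cs2$per_chromosome$chromosome == "Z"]
  expect_equal(z_mean, truth_summary(sim2$truth)$expected_z_mean_log2_mf,
               tolerance = 0.05 / 0.7)
})
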