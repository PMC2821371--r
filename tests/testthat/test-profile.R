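test_that("running average reproduces hand-computed windows", {
  # window 3 over values (1,2,3,4) at positions (10,20,30,40)
  out <- running_average(c(10, 20, 30, 40), c(1, 2, 3, 4), window = 3)
  expect_equal(out$position_bp, c(20, 30))
  expect_equal(out$value, c(2.0, 3.0))
  expect_equal(nrow(out), 4 - 3 + 1)

  # even window: median position is the mean of the two central positions
  out2 <- running_average(c(10, 20, 40, 80), c(1, 2, 3, 4), window = 4)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$position_bp, (20 + 40) / 2)
  expect_equal(out2$value, 2.5)

  # constant values give a constant profile; window = n collapses to one point
  outc <- running_average(1:50 * 1e5, rep(0.7, 50), window = 30)
  expect_equal(outc$value, rep(0.7, 21))
  outn <- running_average(1:7, c(5, 1, 4, 2, 3, 7, 6), window = 7)
  expect_equal(outn$value, 4)
  expect_equal(outn$position_bp, 4)

  expect_error(running_average(1:5, 1:5, window = 30), "smaller window")
})

test_that("profiles are invariant to input row order", {
  set.seed(19)
  pos <- sample(1e6, 100)
  vals <- rnorm(100)
  p1 <- running_average(pos, vals, window = 10)
  perm <- sample(100)
  p2 <- running_average(pos[perm], vals[perm], window = 10)
  expect_equal(p1, p2)
})

test_that("amplitude dominates the signed ratio profile pointwise", {
  set.seed(23)
  pos <- sort(sample(1e6, 200))
  lr <- rnorm(200, 0, 0.8)
  ra <- running_average(pos, lr, window = 30)
  amp <- amplitude_profile(pos, lr, window = 30)
  expect_true(all(amp$value >= abs(ra$value) - 1e-12))

  # symmetric +a/-a ratios: amplitude constant at a, signed profile ~ 0
  lr_sym <- rep(c(0.6, -0.6), 50)
  pos_sym <- seq_len(100) * 1e4
  amp_sym <- amplitude_profile(pos_sym, lr_sym, window = 10)
  ra_sym <- running_average(pos_sym, lr_sym, window = 10)
  expect_equal(amp_sym$value, rep(0.6, 91))
  expect_equal(max(abs(ra_sym$value)), 0)

  # all-compensated region: amplitude identically zero
  expect_equal(amplitude_profile(pos_sym, rep(0, 100), window = 10)$value,
               rep(0, 91))
})

test_that("ratio distribution normalizes to percent and finds modes", {
  rd <- ratio_distribution(rep(0.61, 40), bin_width = 0.1)
  expect_equal(sum(rd$percent_per_bin), 100)
  expect_equal(sum(rd$percent_per_bin > 0), 1)

  set.seed(71)
  mix <- c(rnorm(600, 0, 0.15), rnorm(1400, 1, 0.15))
  rd2 <- ratio_distribution(mix, bin_width = 0.1)
  expect_equal(sum(rd2$percent_per_bin), 100)
  expect_gte(length(rd2$modes), 2)
  # the two dominant modes sit near the mixture components at 0 and 1
  mode_pct <- rd2$percent_per_bin[match(rd2$modes, rd2$bin_centers)]
  top2 <- sort(rd2$modes[order(-mode_pct)][1:2])
  expect_lt(abs(top2[1] - 0), 0.15)
  expect_lt(abs(top2[2] - 1), 0.15)
})

test_that("region contrast separates a compensated window from background", {
  set.seed(91)
  n_in <- 50; n_out <- 500
  pos <- c(runif(n_in, 2e6, 3e6),
           ifelse(runif(n_out) < 0.4,
                  runif(n_out, 0, 2e6 - 1),
                  runif(n_out, 3e6 + 1, 5e6)))
  vals <- c(rnorm(n_in, 0, 0.15), rnorm(n_out, 1, 0.15))
  rc <- region_contrast(vals, pos, region = c(2e6, 3e6))
  expect_lt(rc$inside_mean, 0.1)
  expect_gt(rc$outside_mean, 0.9)
  expect_lt(rc$p_value, 0.001)

  # logical indicator mode goes through the overlap permutation test
  cls <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  rc2 <- region_contrast(cls, pos, region = c(2e6, 3e6),
                         n_sims = 2000, seed = 5)
  expect_lt(rc2$p_value, 0.01)
  expect_equal(rc2$inside_mean, 1)

  # degenerate regions
  expect_error(region_contrast(vals, pos, region = c(0, 5e6)),
               "whole chromosome")
  expect_error(region_contrast(vals, pos, region = c(2e6, 2e6 + 10)),
               "need >=")
})

test_that("simulated MHM window shows an amplitude valley", {
  cfg <- sim_config(seed = 77, n_autosomal = 0, n_w = 0, n_z = 1500,
                    frac_z_compensated = 0.3, mhm_compensated_boost = 0.5)
  sim <- simulate_dataset(cfg)
  r <- sex_ratios(sim$dataset)
  ann <- sim$annotation
  pos <- ann$position_bp[match(r$probeset_id, ann$probeset_id)]
  amp <- amplitude_profile(pos, r$log2_mf, window = 30, ids = r$probeset_id)
  inside <- amp$position_bp >= cfg$mhm_window[1] &
    amp$position_bp <= cfg$mhm_window[2]
  expect_gt(sum(inside), 3)
  expect_lt(mean(amp$value[inside]), mean(amp$value[!inside]))
})
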