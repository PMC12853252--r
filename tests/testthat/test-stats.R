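test_that("bootstrap significance handles degenerate inputs correctly", {
  time_s <- seq(0, 1, by = 0.01)
  T_ <- length(time_s)
  zero <- matrix(0, 10, T_)
  set.seed(61)
  b0 <- bootstrap_difference(zero, time_s)
  expect_false(any(b0$sig_mask))
  ones <- matrix(1, 10, T_)
  b1 <- bootstrap_difference(ones, time_s)
  expect_true(all(b1$sig_mask))
  expect_true(all(b1$prop_consistent == 1))
  neg <- matrix(-2, 10, T_)
  expect_true(all(bootstrap_difference(neg, time_s)$sig_mask))
  expect_error(bootstrap_difference(matrix(1, 1, T_), time_s),
               "at least 2")
})

test_that("bootstrap is reproducible and invariant to participant order", {
  set.seed(62)
  d <- matrix(rnorm(12 * 50, 0.3), 12)
  set.seed(1); a <- bootstrap_difference(d, n_iter = 500)
  set.seed(1); b <- bootstrap_difference(d, n_iter = 500)
  expect_identical(a$sig_mask, b$sig_mask)
  expect_identical(a$prop_consistent, b$prop_consistent)
  # permuting rows leaves the distributional result essentially unchanged
  set.seed(2); c1 <- bootstrap_difference(d, n_iter = 2000)
  set.seed(3); c2 <- bootstrap_difference(d[sample(12), ], n_iter = 2000)
  expect_lt(max(abs(c1$prop_consistent - c2$prop_consistent)), 0.06)
})

test_that("bootstrap recovers the onset of an injected late divergence", {
  set.seed(63)
  time_s <- seq(-1, 10, by = 0.02)
  T_ <- length(time_s)
  P <- 16
  onset <- 3
  ramp <- pmax(0, time_s - onset) * -1
  d <- t(replicate(P, ramp * runif(1, 0.8, 1.2) +
                     hann_smooth(rnorm(T_, 0, 1.0), 150, 50)))
  bt <- bootstrap_difference(d, time_s)
  got <- first_sig_time(bt, min_s = 0, min_run_s = 0.3)
  expect_lt(abs(got - onset), 0.5)
})

test_that("surrogate-split noise floor separates null from injected effects", {
  set.seed(64)
  time_s <- seq(0, 2.5, by = 0.02)
  T_ <- length(time_s)
  P <- 10
  mk_controls <- function() lapply(seq_len(P), function(i)
    t(replicate(8, hann_smooth(rnorm(T_), 150, 50))))
  ctl <- mk_controls()
  fl <- noise_floor(ctl, time_s, n_iter = 40, n_boot = 400)
  expect_gte(fl$threshold_s, 0)
  expect_lt(fl$threshold_s, 1.5)
  # an injected 1 s consistent effect outlasts the floor
  eff <- t(replicate(P, as.numeric(time_s >= 1 & time_s < 2) * 1.5 +
                       hann_smooth(rnorm(T_, 0, 0.5), 150, 50)))
  bt <- bootstrap_difference(eff, time_s, n_iter = 400)
  expect_gt(longest_sig_run_s(bt), fl$threshold_s)
  # deterministic identical trials: surrogate halves tie, floor collapses
  ident <- lapply(seq_len(P), function(i)
    matrix(rep(sin(time_s), each = 8), nrow = 8, byrow = FALSE))
  fl0 <- noise_floor(ident, time_s, n_iter = 10, n_boot = 100)
  expect_equal(fl0$threshold_s, 0)
  # halving trials preserves detection of a strong effect
  ctl_half <- lapply(ctl, function(m) m[1:4, , drop = FALSE])
  fl_half <- noise_floor(ctl_half, time_s, n_iter = 40, n_boot = 400)
  expect_gt(longest_sig_run_s(bt), fl_half$threshold_s)
})

test_that("divergence-latency resampling recovers injected onsets in order", {
  set.seed(65)
  time_s <- seq(-0.5, 2.5, by = 0.02)
  T_ <- length(time_s)
  P <- 16
  mk <- function(onset, slope = 2) t(replicate(P,
    pmax(0, time_s - onset) * slope * runif(1, 0.85, 1.15) +
      hann_smooth(rnorm(T_, 0, 0.25), 150, 50)))
  nc <- t(replicate(P, hann_smooth(rnorm(T_, 0, 0.25), 150, 50)))
  lat_ca <- divergence_latency(mk(0.45), nc, time_s, n_iter = 120,
                               n_boot = 400, min_s = 0, min_run_s = 0.3)
  lat_cd <- divergence_latency(mk(1.0), nc, time_s, n_iter = 120,
                               n_boot = 400, min_s = 0, min_run_s = 0.3)
  expect_lt(abs(lat_ca$mean_s - 0.45), 0.1)
  expect_lt(abs(lat_cd$mean_s - 1.0), 0.1)
  expect_lt(lat_ca$mean_s, lat_cd$mean_s)
  # huge immediate effect: every latency lands on the first admissible sample
  huge <- matrix(5, P, T_) + rnorm(P * T_, 0, 0.01)
  lat0 <- divergence_latency(huge, nc * 0, time_s, n_iter = 40,
                             n_boot = 200, min_s = 0)
  expect_true(all(lat0$latencies_s == time_s[time_s >= 0][1]))
  expect_equal(lat0$missing_rate, 0)
  # no effect: latencies are mostly missing
  lat_null <- divergence_latency(nc, nc + 0 * rnorm(1), time_s, n_iter = 40,
                                 n_boot = 200, min_s = 0, min_run_s = 0.3)
  expect_gt(lat_null$missing_rate, 0.8)
})

test_that("monotonicity: larger injected amplitudes never delay the latency", {
  set.seed(66)
  time_s <- seq(-0.5, 2.5, by = 0.05)
  P <- 14
  nc0 <- matrix(0, P, length(time_s))
  means <- vapply(c(0.5, 1.5, 5), function(a) {
    eff <- t(replicate(P, pmax(0, time_s - 0.8) * a +
                         hann_smooth(rnorm(length(time_s), 0, 0.3), 100, 20)))
    divergence_latency(eff, nc0, time_s, n_iter = 60, n_boot = 300,
                       min_s = 0, min_run_s = 0.3)$mean_s
  }, numeric(1))
  expect_true(all(diff(means) <= 0.1))
})

test_that("Wilcoxon effect size matches closed-form benchmarks", {
  # perfectly ordered positive differences at N = 32: maximal r
  a <- 1:32 + 100; b <- rep(100, 32)
  es <- wilcoxon_effect_size(a, b)
  v_max <- 32 * 33 / 2
  z_max <- (v_max - 32 * 33 / 4) / sqrt(32 * 33 * 65 / 24)
  expect_equal(es$v, v_max)
  expect_equal(es$r, z_max / sqrt(32), tolerance = 1e-9)
  # identical samples: r = 0
  expect_equal(wilcoxon_effect_size(a, a)$r, 0)
  # sign flip leaves r unchanged
  set.seed(67)
  x <- rnorm(32); y <- rnorm(32)
  expect_equal(wilcoxon_effect_size(x, y)$r,
               wilcoxon_effect_size(y, x)$r, tolerance = 1e-12)
  # small-sample exact branch agrees with wilcox.test
  x2 <- c(1.1, 2.3, 0.2, -0.4, 1.8, 2.2, 0.9, -1.2)
  y2 <- rep(0, 8)
  es2 <- wilcoxon_effect_size(x2, y2)
  p_ref <- stats::wilcox.test(x2, y2, paired = TRUE, exact = TRUE)$p.value
  expect_equal(es2$p, p_ref, tolerance = 1e-12)
})

test_that("behavior scoring applies the 2 s hit rule strictly", {
  trials <- build_session(70, n_blocks = 1)$trials
  gap_trial <- trials[trials$decoy, ][1, ]
  g <- gap_trial$gap_start_s
  presses <- data.frame(block = gap_trial$block, trial = gap_trial$trial,
                        press_s = g + 1.9)
  bs <- score_behavior(trials, presses)
  expect_true(bs$hits[trials$block == gap_trial$block &
                        trials$trial == gap_trial$trial])
  expect_equal(bs$n_false_alarms, 0)
  expect_equal(bs$rts[trials$block == gap_trial$block &
                        trials$trial == gap_trial$trial], 1.9)
  # 2.1 s after the gap: not a hit, counted as false alarm
  presses2 <- presses; presses2$press_s <- g + 2.1
  bs2 <- score_behavior(trials, presses2)
  expect_false(any(bs2$hits))
  expect_equal(bs2$n_false_alarms, 1)
  # no presses at all
  bs3 <- score_behavior(trials, presses[0, ])
  expect_equal(bs3$n_false_alarms, 0)
  expect_true(all(!bs3$hits))
  expect_equal(bs3$by_condition$hit_rate, c(0, 0))
})

test_that("uniform false-alarm times produce a flat within-trial histogram", {
  p <- synth_params(hit_prob = 0, fa_rate_per_trial = 3)
  trials <- build_session(71, n_blocks = 2)$trials
  set.seed(72)
  presses <- simulate_presses(trials, p)
  bs <- score_behavior(trials, presses)
  expect_gt(length(bs$fa_times_s), 120)
  ks <- stats::ks.test(bs$fa_times_s, "punif", 0, 10)
  expect_gt(ks$p.value, 1e-3)
})

test_that("RT-pupil correlation behaves at the proportional and null poles", {
  set.seed(73)
  P <- 32
  time_s <- seq(-1, 10, by = 0.05)
  rt <- rnorm(P)
  series <- outer(rt, rep(1, length(time_s)))   # proportional at every t
  rc <- rt_pd_correlation(rt, series, time_s)
  expect_true(all(abs(rc$r - 1) < 1e-9))
  expect_equal(rc$windowed$r, 1, tolerance = 1e-9)
  # windowed correlation equals pointwise correlation of time-averaged series
  noisy <- series + matrix(rnorm(P * length(time_s)), P)
  rc2 <- rt_pd_correlation(rt, noisy, time_s, window_s = c(6, 10))
  win <- time_s >= 6 & time_s <= 10
  expect_equal(rc2$windowed$r,
               unname(stats::cor(rt, rowMeans(noisy[, win]))),
               tolerance = 1e-9)
  # null calibration: |r| rarely exceeds the alpha = 0.05 critical value
  null_series <- matrix(rnorm(P * length(time_s)), P)
  rc3 <- rt_pd_correlation(rnorm(P), null_series, time_s)
  crit <- sqrt(stats::qf(0.95, 1, P - 2) / (P - 2 +
                                              stats::qf(0.95, 1, P - 2)))
  rate <- mean(abs(rc3$r) > crit)
  expect_lt(rate, 0.12)
  expect_gt(rate, 0.005)
  expect_error(rt_pd_correlation(rnorm(2), null_series[1:2, ], time_s),
               "at least 3")
})
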