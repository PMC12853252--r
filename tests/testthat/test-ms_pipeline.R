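test_that("5-point velocity estimator is exact on linear motion", {
  n <- 100
  v0 <- gaze_velocity(rep(3, n), rep(7, n))
  expect_true(all(v0$vx[3:(n - 2)] == 0))
  # linear motion at 100 px/s sampled at 1 kHz
  x <- 0.1 * seq_len(n)
  v1 <- gaze_velocity(x, x * 2)
  expect_equal(v1$vx[3:(n - 2)], rep(100, n - 4), tolerance = 1e-9)
  expect_equal(v1$vy[3:(n - 2)], rep(200, n - 4), tolerance = 1e-9)
  expect_true(all(is.na(v1$vx[c(1, 2, n - 1, n)])))
  # sample-alternating noise is annihilated (unlike 2-point differencing)
  alt <- rep(c(1, -1), 50)
  va <- gaze_velocity(alt, alt)
  expect_true(all(abs(va$vx[3:(n - 2)]) < 1e-12))
})

test_that("median-based SD estimates the Gaussian robust scale", {
  set.seed(41)
  sigma <- 35
  v <- list(vx = rnorm(1e5, 0, sigma), vy = rnorm(1e5, 0, sigma))
  thr <- velocity_threshold(v, lambda = 6)
  # median-based SD of a centered Gaussian converges to qnorm(0.75)*sigma
  expected <- sigma * sqrt(stats::qchisq(0.5, 1))
  expect_lt(abs(thr$sigma_x - expected) / expected, 0.05)
  expect_equal(thr$eta_x, 6 * thr$sigma_x)
  # scale equivariance: doubling velocities doubles sigma and eta
  v2 <- list(vx = 2 * v$vx, vy = 2 * v$vy)
  thr2 <- velocity_threshold(v2)
  expect_equal(thr2$eta_x, 2 * thr$eta_x, tolerance = 1e-12)
  expect_identical(above_threshold(v, thr),
                   above_threshold(v2, thr2))
  # flat trace errors
  expect_error(velocity_threshold(list(vx = rep(0, 100), vy = rep(0, 100))),
               "degenerate")
})

test_that("the elliptic criterion is strict at the threshold", {
  thr <- list(eta_x = 100, eta_y = 100)
  v <- list(vx = c(100, 100.1, 0, 71, 90), vy = c(0, 0, 100, 71, 90))
  expect_identical(above_threshold(v, thr),
                   c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("monocular run durations are bounded inclusively at 5 and 100 ms", {
  thr <- list(eta_x = 10, eta_y = 10, lambda = 6)
  mk <- function(len, at = 500, n = 1000) {
    vx <- rep(0.1, n); vx[at:(at + len - 1)] <- 50
    list(vx = vx, vy = rep(0.1, n))
  }
  expect_equal(nrow(detect_monocular(mk(4), thr)), 0)   # 4 ms: too short
  d5 <- detect_monocular(mk(5), thr)
  expect_equal(nrow(d5), 1)                              # 5 ms: kept
  expect_equal(d5$onset, 500)
  expect_equal(nrow(detect_monocular(mk(100), thr)), 1)  # 100 ms: kept
  expect_equal(nrow(detect_monocular(mk(120), thr)), 0)  # 120 ms: too long
  # runs touching missing data are dropped
  miss <- rep(FALSE, 1000); miss[499] <- TRUE
  expect_equal(nrow(detect_monocular(mk(10), thr, miss)), 0)
})

test_that("binocular pairing matches the exhaustive oracle on small lists", {
  mk <- function(onsets) data.frame(onset = onsets, offset = onsets + 10,
                                    peak_vel = rep(1, length(onsets)),
                                    amp_px = rep(1, length(onsets)))
  # identical lists pair fully at zero disparity
  p0 <- pair_binocular(mk(c(100, 300, 500)), mk(c(100, 300, 500)))
  expect_equal(nrow(p0), 3)
  expect_true(all(p0$disparity_ms == 0))
  # onsets 12 ms apart do not pair
  expect_equal(nrow(pair_binocular(mk(100), mk(112))), 0)
  # random interleavings against brute force
  set.seed(44)
  for (i in 1:200) {
    nl <- sample(0:5, 1); nr <- sample(0:5, 1)
    l_on <- sort(sample(1:120, nl)); r_on <- sort(sample(1:120, nr))
    got <- pair_binocular(mk(l_on), mk(r_on), max_disparity_ms = 10)
    best <- oracle_pairing(l_on, r_on, max_disp = 10)
    expect_equal(nrow(got), max(0, best$n))
    if (nrow(got) > 0)
      expect_equal(sum(got$disparity_ms), best$cost, tolerance = 1e-9)
  }
})

test_that("refractory sweep keeps only onsets more than 50 ms apart", {
  mk <- function(onsets) data.frame(onset = onsets, onset_l = onsets,
                                    onset_r = onsets, offset = onsets + 10,
                                    dur_ms = 10, amp_px = 1, peak_vel = 1,
                                    disparity_ms = 0)
  expect_equal(nrow(enforce_refractory(mk(100))), 1)
  # onsets at 0, 30, 90 ms -> keep {0, 90}
  kept <- enforce_refractory(mk(c(1, 31, 91)))
  expect_equal(kept$onset, c(1, 91))
  # exactly 50 ms apart: second dropped (strictly "longer than")
  expect_equal(enforce_refractory(mk(c(1, 51)))$onset, 1)
  expect_equal(enforce_refractory(mk(c(1, 52)))$onset, c(1, 52))
})

test_that("the full detection chain equals brute-force enumeration", {
  set.seed(47)
  for (i in 1:60) {
    g <- random_ms_trace(2000, n_steps = sample(1:4, 1))
    vl <- gaze_velocity(g$xl, g$yl)
    vr <- gaze_velocity(g$xr, g$yr)
    thr_l <- velocity_threshold(vl)
    thr_r <- velocity_threshold(vr)
    cl <- detect_monocular(vl, thr_l)
    cr <- detect_monocular(vr, thr_r)
    ev <- enforce_refractory(pair_binocular(cl, cr))
    # oracle: literal loops for every stage
    ol <- oracle_monocular(vl, thr_l, NULL)
    or_ <- oracle_monocular(vr, thr_r, NULL)
    expect_equal(cl$onset, ol$onset)
    expect_equal(cr$onset, or_$onset)
    if (nrow(ol) && nrow(or_)) {
      bestp <- oracle_pairing(ol$onset, or_$onset, max_disp = 10)
      expect_equal(nrow(pair_binocular(cl, cr)), bestp$n)
      pair_on <- sort(pmin(ol$onset[bestp$pairs[, 1]],
                           or_$onset[bestp$pairs[, 2]]))
      expect_equal(sort(ev$onset), oracle_refractory(pair_on, 50))
    }
  }
})

test_that("detection is invariant to gaze offset and 90-degree rotation", {
  set.seed(48)
  g <- random_ms_trace(2000, 3)
  base <- detect_ms(make_trace(rep(1200, 2000), xl = g$xl, yl = g$yl))
  tr_off <- make_trace(rep(1200, 2000), xl = g$xl + 500, yl = g$yl - 200)
  expect_equal(detect_ms(tr_off)$onset, base$onset)
  tr_rot <- make_trace(rep(1200, 2000), xl = -g$yl, yl = g$xl)
  expect_equal(detect_ms(tr_rot)$onset, base$onset)
})

test_that("injected microsaccades are recovered with accurate onsets", {
  p <- synth_params(scene_dur_s = 9, pre_s = 0.5, post_s = 0.5,
                    blink_rate_hz = 0)
  set.seed(50)
  tr <- simulate_block(rbind(one_trial(), one_trial(), one_trial()), p,
                       blinks = FALSE)
  ev <- detect_ms(tr)
  gt <- tr$ground_truth$ms
  hit <- vapply(gt$block_ms, function(t) any(abs(ev$onset_ms - t) < 10),
                logical(1))
  expect_gt(mean(hit), 0.9)
  err <- vapply(gt$block_ms[hit], function(t)
    min(abs(ev$onset_ms - t)), numeric(1))
  expect_lt(stats::median(err), 3)
  expect_true(all(ev$dur_ms >= 5 & ev$dur_ms <= 100))
})

test_that("microsaccade rate series reflect the generating Poisson rate", {
  k <- causal_kernel()
  # no events -> zero rate minus zero baseline
  r0 <- event_rate(list(numeric(0), numeric(0)), c(-0.15, 2.5), k,
                   c(-0.15, 0))
  expect_true(all(r0$rate_hz == 0))
  # homogeneous 1.5 Hz pulse trains -> plateau near 1.5 events/s
  set.seed(52)
  trains <- replicate(600, sort(runif(rpois(1, 1.5 * 5), -2, 3)),
                      simplify = FALSE)
  r <- event_rate(trains, c(0, 3), k, NULL)
  mid <- r$time_s > 0.5 & r$time_s < 2.5
  expect_equal(mean(r$rate_hz[mid]), 1.5, tolerance = 0.1)
})
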