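test_that("missing-data mask applies the fixation radius strictly", {
  n <- 1000
  tr <- make_trace(rep(1200, n))
  expect_false(any(mask_missing(tr)))
  # gaze exactly at 100 px is kept; 100.5 px is missing
  tr2 <- make_trace(rep(1200, n), xl = rep(960 + 100, n))
  expect_false(any(mask_missing(tr2)))
  tr3 <- make_trace(rep(1200, n), xl = rep(960 + 100.5, n))
  expect_true(all(mask_missing(tr3)))
  # masking is idempotent: re-masking a masked trace changes nothing
  m <- mask_missing(tr3)
  expect_identical(m, mask_missing(tr3))
})

test_that("closure intervals are padded by exactly 250 ms on both sides", {
  n <- 4000
  vl <- rep(TRUE, n)
  vl[2001:2100] <- FALSE                       # 100 ms closure at t = 2.0 s
  tr <- make_trace(rep(1200, n), vl = vl)
  m <- mask_missing(tr)
  expect_identical(which(m), 1751:2350)        # [1.75, 2.35) s
})

test_that("shape-preserving interpolation fills gaps without overshoot", {
  y <- sin(seq(0, 2 * pi, length.out = 200))
  expect_identical(interpolate_missing(y, rep(FALSE, 200)), y)
  # linear data: exact linear fill
  y2 <- seq(0, 10, length.out = 101)
  m2 <- rep(FALSE, 101); m2[40:60] <- TRUE
  out2 <- interpolate_missing(y2, m2)
  expect_equal(out2, y2, tolerance = 1e-12)
  # monotone data stays monotone over the gap
  y3 <- cumsum(runif(100, 0, 1))
  m3 <- rep(FALSE, 100); m3[30:70] <- TRUE
  out3 <- interpolate_missing(y3, m3)
  expect_true(all(diff(out3[25:75]) >= -1e-12))
  # no overshoot beyond neighboring extrema, even with noisy gap edges
  set.seed(8)
  y4 <- 1200 + rnorm(2000)
  m4 <- rep(FALSE, 2000); m4[500:1200] <- TRUE
  out4 <- interpolate_missing(y4, m4)
  expect_lte(max(out4[500:1200]), max(y4[!m4]))
  expect_gte(min(out4[500:1200]), min(y4[!m4]))
  # leading/trailing gaps hold the nearest valid value
  m5 <- rep(FALSE, 100); m5[1:10] <- TRUE; m5[95:100] <- TRUE
  y5 <- seq_len(100) / 10
  out5 <- interpolate_missing(y5, m5)
  expect_true(all(out5[1:10] == y5[11]))
  expect_true(all(out5[95:100] == y5[94]))
})

test_that("Hann smoothing has unit gain, known kernel, and variance factor", {
  expect_equal(hann_smooth(rep(5, 500)), rep(5, 500))
  # impulse response: symmetric Hann summing to 1
  x <- numeric(501); x[251] <- 1
  h <- hann_smooth(x)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(h, rev(h))
  expect_equal(which.max(h), 251)
  # white-noise variance shrinks by the kernel sum-of-squares factor
  L <- 151
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1))); w <- w / sum(w)
  set.seed(4)
  z <- rnorm(2e5)
  vr <- stats::var(hann_smooth(z)[1000:199000])
  expect_equal(vr, sum(w^2), tolerance = 0.05)
})

test_that("epoch rejection applies the >50% missing and outlier rules", {
  n_ep <- 16; T_ <- 200
  data <- matrix(rnorm(n_ep * T_), n_ep)
  ep <- list(data = data, missing_frac = rep(0, n_ep),
             time_s = seq(-0.5, by = 0.01, length.out = T_),
             events = data.frame(block = rep(1L, n_ep)))
  es <- epoch_and_reject(ep, "X", baseline_window_s = c(-0.5, 0))
  expect_equal(es$n_rejected, 0)
  # strictly more than 50% missing rejects; exactly below keeps
  ep$missing_frac <- c(0.51, 0.49, rep(0, n_ep - 2))
  es2 <- epoch_and_reject(ep, "X", baseline_window_s = c(-0.5, 0))
  expect_equal(nrow(es2$data), n_ep - 1)
  # an epoch deviating >3 SD on >=10% of samples is discarded
  data3 <- matrix(rnorm(n_ep * T_), n_ep)
  data3[1, 1:30] <- 50
  ep3 <- list(data = data3, missing_frac = rep(0, n_ep),
              time_s = ep$time_s, events = ep$events)
  es3 <- epoch_and_reject(ep3, "X", baseline_window_s = c(-0.5, 0))
  expect_equal(es3$n_rejected, 1)
})

test_that("z-normalization pools block baselines and is affine-invariant", {
  set.seed(6)
  T_ <- 300
  time_s <- seq(-1, 2, length.out = T_)
  mk <- function(scale = 1, shift = 0) {
    data <- matrix(rnorm(8 * T_, 10, 2) * scale + shift, 8)
    structure(list(data = data, time_s = time_s, condition = "X",
                   baseline_window_s = c(-1, 0), n_rejected = 0L,
                   block = rep(1:2, each = 4)), class = "epoch_set")
  }
  e <- mk()
  z <- znormalize(e)
  bl <- time_s >= -1 & time_s < 0
  for (b in 1:2) {
    base <- z$data[z$block == b, bl]
    expect_equal(mean(base), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.numeric(base)), 1, tolerance = 1e-10)
  }
  # affine transform of the input leaves the output unchanged
  e2 <- e; e2$data <- 3.7 * e$data - 42
  expect_equal(znormalize(e2)$data, z$data, tolerance = 1e-9)
  # zero baseline SD drops the block with a warning
  e3 <- e; e3$data[e3$block == 1, bl] <- 5
  expect_warning(z3 <- znormalize(e3), "zero baseline SD")
  expect_equal(nrow(z3$data), 4)
})

test_that("condition averaging reduces to the obvious cases", {
  T_ <- 50
  time_s <- seq(0, 1, length.out = T_)
  mk <- function(data) structure(
    list(data = data, time_s = time_s, condition = "X",
         baseline_window_s = c(-1, 0), n_rejected = 0L,
         block = rep(1L, nrow(data))), class = "epoch_set")
  x <- rnorm(T_)
  one <- average_condition(mk(matrix(x, 1)))
  expect_equal(one$mean, x)
  sym <- average_condition(mk(rbind(x, -x)))
  expect_equal(sym$mean, rep(0, T_))
  expect_equal(sym$n, 2)
})

test_that("participant-level epochs recover the generator tonic template", {
  p <- synth_params(blink_rate_hz = 0)
  set.seed(30)
  design <- build_session(30, n_blocks = 1)
  blocks <- list(simulate_block(design$trials[design$trials$block == 1, ], p,
                                blinks = FALSE))
  eps <- participant_pupil_epochs(blocks, NULL, "sequence", p)
  expect_named(eps, c("REG", "RND"), ignore.order = TRUE)
  expect_equal(ncol(eps$REG$data), 11001)
  avg <- average_condition(eps$REG)
  # late sustained phase: z-scored mean tracks the declining template
  late <- avg$time_s >= 6 & avg$time_s <= 9
  early <- avg$time_s >= 0.5 & avg$time_s <= 1
  expect_lt(mean(avg$mean[late]), mean(avg$mean[early]))
})
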