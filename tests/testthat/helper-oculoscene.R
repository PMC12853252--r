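# Shared test utilities: hand-built traces, brute-force oracles, and tiny
# trial tables.

# a minimal sample_trace with constant gaze at fixation and given pupil
make_trace <- function(pl, xl = NULL, yl = NULL, vl = NULL, fs = 1000,
                       fix = c(960, 540)) {
  n <- length(pl)
  structure(list(
    fs_hz = fs, time_ms = seq_len(n) - 1L,
    xl = if (is.null(xl)) rep(fix[1], n) else xl,
    yl = if (is.null(yl)) rep(fix[2], n) else yl,
    pl = pl, vl = if (is.null(vl)) rep(TRUE, n) else vl,
    xr = if (is.null(xl)) rep(fix[1], n) else xl,
    yr = if (is.null(yl)) rep(fix[2], n) else yl,
    pr = pl, vr = if (is.null(vl)) rep(TRUE, n) else vl,
    events = NULL, ground_truth = NULL), class = "sample_trace")
}

# one-trial data frame as used by the generator
one_trial <- function(regularity = "RND", change_type = "NC",
                      change_time_s = NA_real_) {
  data.frame(block = 1L, trial = 1L,
             condition = paste(regularity, change_type, sep = "-"),
             regularity = regularity, change_type = change_type,
             change_time_s = change_time_s, gap_start_s = NA_real_,
             decoy = FALSE)
}

# literal brute-force dilation-event scan: strict local minimum over
# distinct-value neighbors (plateau -> first sample), then non-decreasing
# for the next `need` samples
oracle_dilation <- function(y, need = 100) {
  n <- length(y)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    j <- i - 1
    while (j >= 1 && y[j] == y[i]) j <- j - 1
    if (j < 1 || y[j] <= y[i]) next
    if (y[i - 1] == y[i]) next                      # plateau: not first sample
    k <- i + 1
    while (k <= n && y[k] == y[i]) k <- k + 1
    if (k > n || y[k] <= y[i]) next
    if (i + need > n) next
    ok <- TRUE
    for (t in i:(i + need - 1)) if (y[t + 1] < y[t]) { ok <- FALSE; break }
    if (ok) out <- c(out, i)
  }
  out
}

# literal brute-force monocular run detector
oracle_monocular <- function(vel, thr, missing, fs = 1000,
                             dur_ms = c(5, 100)) {
  n <- length(vel$vx)
  bad <- !is.finite(vel$vx) | !is.finite(vel$vy)
  if (!is.null(missing)) bad <- bad | missing
  ab <- (vel$vx / thr$eta_x)^2 + (vel$vy / thr$eta_y)^2 > 1
  ab[bad] <- FALSE
  res <- NULL
  i <- 1
  while (i <= n) {
    if (!ab[i]) { i <- i + 1; next }
    j <- i
    while (j < n && ab[j + 1]) j <- j + 1
    len_ms <- (j - i + 1) * 1000 / fs
    touches_bad <- (i > 1 && bad[i - 1]) || (j < n && bad[j + 1])
    if (len_ms >= dur_ms[1] && len_ms <= dur_ms[2] && !touches_bad)
      res <- rbind(res, c(i, j))
    i <- j + 1
  }
  if (is.null(res)) data.frame(onset = integer(0), offset = integer(0))
  else data.frame(onset = res[, 1], offset = res[, 2])
}

# exhaustive binocular matching oracle for small candidate lists:
# enumerate all pairings with |donset| < max_disp, maximize count then
# minimize total disparity
oracle_pairing <- function(l_on, r_on, max_disp) {
  best <- list(n = -1L, cost = Inf, pairs = matrix(integer(0), 0, 2))
  recurse <- function(i, used_r, pairs, cost) {
    if (i > length(l_on)) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used_r, pairs, cost)            # skip left i
    for (j in seq_along(r_on)) {
      if (used_r[j]) next
      d <- abs(l_on[i] - r_on[j])
      if (d < max_disp) {
        used_r[j] <- TRUE
        recurse(i + 1L, used_r, rbind(pairs, c(i, j)), cost + d)
        used_r[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(r_on)), matrix(integer(0), 0, 2), 0)
  best
}

# refractory sweep oracle (strict "longer than")
oracle_refractory <- function(onsets, min_gap) {
  if (!length(onsets)) return(onsets)
  onsets <- sort(onsets)
  kept <- onsets[1]
  for (o in onsets[-1]) if (o - kept[length(kept)] > min_gap)
    kept <- c(kept, o)
  kept
}

# random small gaze trace with planted binocular steps, for chain oracles
random_ms_trace <- function(n = 2000, n_steps = 3, fs = 1000) {
  t <- seq_len(n)
  mk <- function() cumsum(rnorm(n, 0, 0.02)) + rnorm(n, 0, 0.15)
  xl <- mk(); yl <- mk(); xr <- mk(); yr <- mk()
  onsets <- sort(sample(seq(100, n - 100), n_steps))
  if (length(onsets) > 1) onsets <- onsets[c(TRUE, diff(onsets) > 120)]
  for (o in onsets) {
    d <- sample(8:20, 1)
    amp <- runif(1, 6, 20); ang <- runif(1, 0, 2 * pi)
    prof <- amp * 0.5 * (1 - cos(pi * seq_len(d) / d))
    disp <- sample(0:4, 1)
    for (eye in c("l", "r")) {
      o_e <- if (eye == "l") o else o + disp
      idx <- o_e:(o_e + d - 1L)
      step <- c(prof, rep(amp, n - max(idx)))
      full <- numeric(n)
      full[o_e:n] <- step[seq_len(n - o_e + 1L)]
      if (eye == "l") { xl <- xl + cos(ang) * full; yl <- yl + sin(ang) * full }
      else { xr <- xr + cos(ang) * full; yr <- yr + sin(ang) * full }
    }
  }
  list(xl = xl, yl = yl, xr = xr, yr = yr, true_onsets = onsets)
}
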