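# Pupil dilation rate (PDR): discrete dilation-onset events extracted from
# the smoothed pupil trace, converted to a rate time series with a causal
# alpha-function kernel.  The same kernel machinery serves the microsaccade
# rate.

#' Detect pupil dilation events
#'
#' An event is a strict local minimum of the (smoothed, gap-free) pupil
#' series that is followed by continuous (non-decreasing) dilation for at
#' least `min_dilation_ms`.  Plateau minima take their first sample.
#'
#' @param y smoothed, gap-free pupil series.
#' @param fs_hz sampling rate.
#' @param min_dilation_ms required non-decreasing run after the minimum (ms).
#' @return integer vector of event sample indices (1-based).
#' @export
detect_dilation_events <- function(y, fs_hz = 1000, min_dilation_ms = 100) {
  n <- length(y)
  need <- round(min_dilation_ms / 1000 * fs_hz)
  if (n < need + 2L) return(integer(0))
  # collapse plateaus: strict local minima over distinct values,
  # mapped back to the first sample of the plateau
  r <- rle(y)
  v <- r$values
  first <- cumsum(r$lengths) - r$lengths + 1L
  k <- length(v)
  if (k < 3L) return(integer(0))
  is_min <- c(FALSE, v[2:(k - 1)] < v[1:(k - 2)] & v[2:(k - 1)] < v[3:k],
              FALSE)
  cand <- first[is_min]
  if (!length(cand)) return(integer(0))
  # non-decreasing run length ahead of each sample
  nd <- diff(y) >= 0
  run_ahead <- rev(cumsum_reset(rev(nd)))          # at i: run length of nd
  cand <- cand[cand + need <= n]
  cand[run_ahead[cand] >= need]
}

# length of the TRUE run starting at each position (0 where FALSE)
cumsum_reset <- function(x) {
  # reversed cumulative run length: classic cumsum trick
  cs <- cumsum(x)
  cs - cummax(cs * (!x))
}

#' Causal rate-estimation kernel
#'
#' The alpha-function kernel \eqn{\omega(\tau) = \alpha^2 \tau e^{-\alpha\tau}}
#' for \eqn{\tau \ge 0} with time constant `alpha_inv_ms` (so
#' \eqn{\alpha = 1/}`alpha_inv_ms`), discretized at `fs_hz`, truncated where
#' \eqn{\omega < 10^{-6}} of its maximum, and renormalized to unit area.  The
#' kernel is causal (zero at the origin) and peaks at `alpha_inv_ms`.
#'
#' @param alpha_inv_ms kernel time constant (ms); also the peak latency.
#' @param fs_hz sampling rate.
#' @param cutoff relative truncation threshold.
#' @return a `causal_kernel`: list with `weights` (1/s units, sum *
#'   `1/fs_hz` = 1), `fs_hz`, `peak_latency_s`, `support_s`.
#' @export
causal_kernel <- function(alpha_inv_ms = 150, fs_hz = 1000, cutoff = 1e-6) {
  alpha <- 1000 / alpha_inv_ms                      # 1/s
  dt <- 1 / fs_hz
  peak <- alpha * exp(-1)                           # omega at tau = 1/alpha
  # support: largest tau with omega >= cutoff * peak (solve numerically)
  f <- function(tau) alpha^2 * tau * exp(-alpha * tau) - cutoff * peak
  hi <- 1 / alpha
  while (f(hi) > 0) hi <- hi * 2
  support <- stats::uniroot(f, c(1 / alpha, hi))$root
  tau <- seq(0, support, by = dt)
  w <- alpha^2 * tau * exp(-alpha * tau)
  w <- w / (sum(w) * dt)
  structure(list(weights = w, fs_hz = fs_hz,
                 peak_latency_s = 1 / alpha, support_s = support),
            class = "causal_kernel")
}

#' Event rate from point-event trains
#'
#' Per-trial event trains (Dirac pulses) are summed, normalized by the number
#' of trials and the sampling rate, causally convolved with the kernel,
#' baseline corrected, and reported on a time axis shifted left by the
#' kernel's peak latency (to undo the kernel-induced delay).
#'
#' @param trains list of numeric vectors: per-trial event times (s), relative
#'   to the alignment point.  Events earlier than `window_s[1]` are used to
#'   warm up the causal convolution.
#' @param window_s reported window, e.g. `c(-0.15, 2.5)` (s).
#' @param kernel a `causal_kernel`.
#' @param baseline_window_s interval whose mean rate is subtracted (on the
#'   shifted axis), or `NULL` for no correction.
#' @param condition,participant labels carried through.
#' @return a `rate_series`: list with `time_s`, `rate_hz`, `n_trials`,
#'   `baseline_window_s`, `condition`, `participant`.
#' @export
event_rate <- function(trains, window_s, kernel = causal_kernel(),
                       baseline_window_s = NULL, condition = NA_character_,
                       participant = NA_character_) {
  n_trials <- length(trains)
  if (n_trials == 0) stop("event_rate needs at least one trial")
  fs <- kernel$fs_hz
  pad_s <- kernel$support_s
  t0 <- window_s[1] - pad_s
  grid0 <- round(t0 * fs)
  grid1 <- round(window_s[2] * fs)
  n <- grid1 - grid0 + 1L
  pulses <- numeric(n)
  for (tr in trains) {
    tr <- tr[tr >= t0 & tr <= window_s[2]]
    if (length(tr)) {
      idx <- round(tr * fs) - grid0 + 1L
      for (i in idx) pulses[i] <- pulses[i] + 1
    }
  }
  m <- pulses / n_trials
  w <- kernel$weights
  rate <- stats::filter(c(numeric(length(w) - 1L), m), w, sides = 1)
  rate <- as.numeric(rate[length(w):(length(w) - 1L + n)])
  # crop to the reported window and undo the kernel delay
  keep <- (round(window_s[1] * fs) - grid0 + 1L):n
  time_s <- (seq(round(window_s[1] * fs), grid1)) / fs - kernel$peak_latency_s
  rate <- rate[keep]
  if (!is.null(baseline_window_s)) {
    bl <- time_s >= baseline_window_s[1] & time_s < baseline_window_s[2]
    if (any(bl)) rate <- rate - mean(rate[bl])
  }
  structure(list(time_s = time_s, rate_hz = rate, n_trials = n_trials,
                 baseline_window_s = baseline_window_s,
                 condition = condition, participant = participant),
            class = "rate_series")
}

#' Participant-level pupil-dilation-rate series per condition
#'
#' Detects dilation events on each block's continuous preprocessed pupil
#' trace, collects event times per analyzable trial relative to the change
#' time (NC trials: nominal 6 s), and converts them to baseline-corrected
#' rate series per condition.
#'
#' @inheritParams participant_pupil_epochs
#' @param window_s reported change-locked window.
#' @param baseline_window_s baseline interval (the short PDR baseline).
#' @param kernel a `causal_kernel`.
#' @return named list of `rate_series` per condition label.
#' @export
participant_pdr <- function(blocks, presses = NULL,
                            window_s = c(-0.15, 2.5),
                            baseline_window_s = c(-0.15, 0),
                            kernel = causal_kernel(),
                            params = synth_params()) {
  fixation <- c(params$fix_x, params$fix_y)
  trains <- list()
  for (tr in blocks) {
    pp <- preprocess_pupil(tr, fixation)
    ev_idx <- detect_dilation_events(pp$y, tr$fs_hz)
    ev_s <- (ev_idx - 1) / tr$fs_hz * 1000          # block time, ms
    ev <- analyzable_trials(tr$events, presses)
    chg <- ifelse(is.finite(ev$change_time_s), ev$change_time_s, 6)
    anchor_ms <- ev$onset_ms + chg * 1000
    for (i in seq_len(nrow(ev))) {
      rel <- (ev_s - anchor_ms[i]) / 1000
      rel <- rel[rel >= window_s[1] - kernel$support_s - 0.5 &
                   rel <= window_s[2]]
      lab <- ev$condition[i]
      trains[[lab]] <- c(trains[[lab]], list(rel))
    }
  }
  out <- list()
  for (lab in names(trains))
    out[[lab]] <- event_rate(trains[[lab]], window_s, kernel,
                             baseline_window_s, condition = lab)
  out
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> %s: [%g, %g] s, %d trials, mean %.3g events/s\n",
    x$condition, min(x$time_s), max(x$time_s), x$n_trials, mean(x$rate_hz)))
  invisible(x)
}

#' @export
plot.rate_series <- function(x, ...) {
  graphics::plot(x$time_s, x$rate_hz, type = "l",
                 xlab = "time (s)", ylab = "rate (events/s)",
                 main = x$condition, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
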