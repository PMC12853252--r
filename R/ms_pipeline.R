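# Binocular microsaccade detection from gaze velocity.
#
# Criteria: (1) velocity exceeds 6x the median-based SD per axis (elliptic
# combination) computed per block; (2) above-threshold runs last 5-100 ms;
# (3) events occur in both eyes with onset disparity < 10 ms; (4) successive
# events are more than 50 ms apart.  Eye-closure intervals are treated as
# missing and never interpolated; runs touching missing data are dropped.

#' Gaze velocity (5-point moving difference)
#'
#' \eqn{v_t = (x_{t+2} + x_{t+1} - x_{t-1} - x_{t-2}) / (6 \Delta t)}, per
#' axis.  The first and last two samples are `NA`.
#'
#' @param x,y gaze coordinates (px).
#' @param fs_hz sampling rate.
#' @return list with `vx`, `vy` (px/s).
#' @export
gaze_velocity <- function(x, y, fs_hz = 1000) {
  v5 <- function(z) {
    n <- length(z)
    v <- rep(NA_real_, n)
    if (n >= 5)
      v[3:(n - 2)] <- (z[5:n] + z[4:(n - 1)] - z[2:(n - 3)] - z[1:(n - 4)]) *
        fs_hz / 6
    v
  }
  list(vx = v5(x), vy = v5(y))
}

#' Median-based velocity thresholds
#'
#' Per axis, the robust SD \eqn{\sigma = \sqrt{\mathrm{median}(v^2) -
#' \mathrm{median}(v)^2}} over the whole block (missing samples excluded) and
#' the threshold \eqn{\eta = \lambda \sigma}.  A sample is above threshold
#' when \eqn{(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1} (elliptic criterion,
#' strict).
#'
#' @param vel list with `vx`, `vy` (a block's velocity series).
#' @param lambda threshold multiplier.
#' @return list with `eta_x`, `eta_y`, `sigma_x`, `sigma_y`, `lambda`.
#' @export
velocity_threshold <- function(vel, lambda = 6) {
  sig <- function(v) {
    v <- v[is.finite(v)]
    s2 <- stats::median(v^2) - stats::median(v)^2
    sqrt(max(0, s2))
  }
  sx <- sig(vel$vx)
  sy <- sig(vel$vy)
  if (sx == 0 || sy == 0)
    stop("degenerate velocity distribution (zero median-based SD)")
  list(eta_x = lambda * sx, eta_y = lambda * sy,
       sigma_x = sx, sigma_y = sy, lambda = lambda)
}

#' @rdname velocity_threshold
#' @param thr thresholds as returned by [velocity_threshold].
#' @return `above_threshold`: logical vector (strict elliptic criterion).
#' @export
above_threshold <- function(vel, thr) {
  (vel$vx / thr$eta_x)^2 + (vel$vy / thr$eta_y)^2 > 1
}

#' Monocular candidate events
#'
#' Maximal runs of above-threshold samples lasting between `dur_ms[1]` and
#' `dur_ms[2]` (inclusive).  Runs containing or adjacent to missing samples
#' are discarded.
#'
#' @param vel list with `vx`, `vy`.
#' @param thr output of [velocity_threshold].
#' @param missing logical mask of missing samples (closures), or `NULL`.
#' @param fs_hz sampling rate.
#' @param dur_ms admissible run-duration range (ms).
#' @return data frame with `onset` and `offset` (sample indices, inclusive),
#'   `peak_vel` (px/s), `amp_px` (net displacement over the run estimated by
#'   velocity integration).
#' @export
detect_monocular <- function(vel, thr, missing = NULL, fs_hz = 1000,
                             dur_ms = c(5, 100)) {
  bad <- !is.finite(vel$vx) | !is.finite(vel$vy)
  if (!is.null(missing)) bad <- bad | missing
  ab <- above_threshold(vel, thr)
  ab[bad] <- FALSE
  rr <- runs_of(ab)
  out <- list()
  n <- length(ab)
  lo <- round(dur_ms[1] / 1000 * fs_hz)
  hi <- round(dur_ms[2] / 1000 * fs_hz)
  for (i in seq_len(nrow(rr))) {
    s <- rr[i, 1]; e <- rr[i, 2]
    len <- e - s + 1L
    if (len < lo || len > hi) next
    # drop runs abutting missing data (conservative)
    if ((s > 1 && bad[s - 1L]) || (e < n && bad[e + 1L])) next
    idx <- s:e
    speed <- sqrt(vel$vx[idx]^2 + vel$vy[idx]^2)
    out[[length(out) + 1L]] <- data.frame(
      onset = s, offset = e, peak_vel = max(speed),
      amp_px = sqrt(sum(vel$vx[idx] / fs_hz)^2 + sum(vel$vy[idx] / fs_hz)^2))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(onset = integer(0), offset = integer(0),
               peak_vel = numeric(0), amp_px = numeric(0))
}

#' Pair monocular events across eyes
#'
#' Optimal non-crossing matching of left- and right-eye candidates with onset
#' disparity strictly below `max_disparity_ms` (maximizes the number of
#' pairs, then minimizes total disparity); unmatched candidates are dropped.
#' The binocular onset is the earlier eye's onset; amplitude and duration are
#' averaged across eyes.
#'
#' @param left,right monocular candidate tables ([detect_monocular]).
#' @param max_disparity_ms pairing bound (ms, strict).
#' @param fs_hz sampling rate.
#' @return data frame of binocular events: `onset` (samples), `onset_l`,
#'   `onset_r`, `offset`, `dur_ms`, `amp_px`, `peak_vel`, `disparity_ms`.
#' @export
pair_binocular <- function(left, right, max_disparity_ms = 10,
                           fs_hz = 1000) {
  empty <- data.frame(onset = integer(0), onset_l = integer(0),
                      onset_r = integer(0), offset = integer(0),
                      dur_ms = numeric(0), amp_px = numeric(0),
                      peak_vel = numeric(0), disparity_ms = numeric(0))
  nl <- nrow(left); nr <- nrow(right)
  if (nl == 0 || nr == 0) return(empty)
  left <- left[order(left$onset), , drop = FALSE]
  right <- right[order(right$onset), , drop = FALSE]
  max_disp <- max_disparity_ms / 1000 * fs_hz
  # no pair can cross a gap >= max_disp in the merged onset sequence, so
  # split into disparity-connected components and solve each by DP
  all_on <- c(left$onset, right$onset)
  eye <- rep(c(1L, 2L), c(nl, nr))
  pos <- c(seq_len(nl), seq_len(nr))
  ord <- order(all_on)
  comp <- cumsum(c(1, diff(all_on[ord]) >= max_disp))
  li <- integer(0); rj <- integer(0)
  for (cid in unique(comp)) {
    sel <- ord[comp == cid]
    is_ <- sort(pos[sel][eye[sel] == 1L])
    js_ <- sort(pos[sel][eye[sel] == 2L])
    if (!length(is_) || !length(js_)) next
    m <- match_component(left$onset[is_], right$onset[js_], max_disp)
    li <- c(li, is_[m[, 1]])
    rj <- c(rj, js_[m[, 2]])
  }
  if (!length(li)) return(empty)
  L <- left[li, , drop = FALSE]
  R <- right[rj, , drop = FALSE]
  data.frame(
    onset = pmin(L$onset, R$onset),
    onset_l = L$onset, onset_r = R$onset,
    offset = pmax(L$offset, R$offset),
    dur_ms = ((L$offset - L$onset + 1L) + (R$offset - R$onset + 1L)) / 2 *
      1000 / fs_hz,
    amp_px = (L$amp_px + R$amp_px) / 2,
    peak_vel = pmax(L$peak_vel, R$peak_vel),
    disparity_ms = abs(L$onset - R$onset) * 1000 / fs_hz)
}

# Non-crossing DP matching of two sorted onset lists under a disparity cap:
# maximize pairs, then minimize total disparity.  Returns a 2-column matrix
# of (left index, right index) pairs.
match_component <- function(a, b, max_disp) {
  na <- length(a); nb <- length(b)
  pairs_tab <- matrix(0L, na + 1L, nb + 1L)
  cost_tab <- matrix(0, na + 1L, nb + 1L)
  take <- matrix(FALSE, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d <- abs(a[i] - b[j])
    best_p <- pairs_tab[i, j + 1L]; best_c <- cost_tab[i, j + 1L]; tk <- FALSE
    if (pairs_tab[i + 1L, j] > best_p ||
        (pairs_tab[i + 1L, j] == best_p && cost_tab[i + 1L, j] < best_c)) {
      best_p <- pairs_tab[i + 1L, j]; best_c <- cost_tab[i + 1L, j]
    }
    if (d < max_disp) {
      p <- pairs_tab[i, j] + 1L
      cc <- cost_tab[i, j] + d
      if (p > best_p || (p == best_p && cc < best_c)) {
        best_p <- p; best_c <- cc; tk <- TRUE
      }
    }
    pairs_tab[i + 1L, j + 1L] <- best_p
    cost_tab[i + 1L, j + 1L] <- best_c
    take[i + 1L, j + 1L] <- tk
  }
  i <- na; j <- nb
  out <- NULL
  while (i > 0 && j > 0) {
    if (take[i + 1L, j + 1L]) {
      out <- rbind(c(i, j), out); i <- i - 1L; j <- j - 1L
    } else if (pairs_tab[i, j + 1L] == pairs_tab[i + 1L, j + 1L] &&
               cost_tab[i, j + 1L] == cost_tab[i + 1L, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

#' Enforce the inter-saccade refractory interval
#'
#' Sweeps events in onset order, keeping an event only if its onset is
#' strictly more than `min_interval_ms` after the last kept onset (the first
#' event is always kept).
#'
#' @param events binocular event table (sorted or not).
#' @param min_interval_ms refractory interval (ms).
#' @param fs_hz sampling rate.
#' @return filtered event table.
#' @export
enforce_refractory <- function(events, min_interval_ms = 50, fs_hz = 1000) {
  if (nrow(events) <= 1) return(events)
  events <- events[order(events$onset), , drop = FALSE]
  min_gap <- min_interval_ms / 1000 * fs_hz
  keep <- logical(nrow(events))
  keep[1] <- TRUE
  last <- events$onset[1]
  for (i in 2:nrow(events)) {
    if (events$onset[i] - last > min_gap) {
      keep[i] <- TRUE
      last <- events$onset[i]
    }
  }
  events[keep, , drop = FALSE]
}

#' Detect binocular microsaccades in a block
#'
#' Runs the full chain (velocity, block thresholds, monocular runs, binocular
#' pairing, refractory sweep) on one block's gaze traces.  Closure intervals
#' (validity flags false) are treated as missing and not interpolated.
#'
#' @param trace a `sample_trace`.
#' @param lambda velocity-threshold multiplier.
#' @param dur_ms monocular run-duration bounds (ms).
#' @param max_disparity_ms binocular pairing bound (ms).
#' @param min_interval_ms refractory interval (ms).
#' @return data frame of events with block-time `onset_ms` plus the
#'   [pair_binocular] columns, with the thresholds as attributes.
#' @export
detect_ms <- function(trace, lambda = 6, dur_ms = c(5, 100),
                      max_disparity_ms = 10, min_interval_ms = 50) {
  fs <- trace$fs_hz
  vl <- gaze_velocity(trace$xl, trace$yl, fs)
  vr <- gaze_velocity(trace$xr, trace$yr, fs)
  miss_l <- !trace$vl
  miss_r <- !trace$vr
  thr_l <- velocity_threshold(
    list(vx = ifelse(miss_l, NA, vl$vx), vy = ifelse(miss_l, NA, vl$vy)),
    lambda)
  thr_r <- velocity_threshold(
    list(vx = ifelse(miss_r, NA, vr$vx), vy = ifelse(miss_r, NA, vr$vy)),
    lambda)
  cl <- detect_monocular(vl, thr_l, miss_l, fs, dur_ms)
  cr <- detect_monocular(vr, thr_r, miss_r, fs, dur_ms)
  ev <- pair_binocular(cl, cr, max_disparity_ms, fs)
  ev <- enforce_refractory(ev, min_interval_ms, fs)
  ev$onset_ms <- (ev$onset - 1L) * 1000 / fs
  attr(ev, "thresholds") <- list(left = thr_l, right = thr_r)
  ev
}

#' Participant-level microsaccade rate series per condition
#'
#' Detects events per block, assigns them to analyzable trials, discards
#' epochs with more than 50% missing gaze data, and converts the pulse trains
#' to baseline-corrected rate series with the shared causal kernel.
#'
#' @inheritParams participant_pupil_epochs
#' @param analysis `"sequence"` (window (-0.5, 10) s, baseline 0.5 s
#'   pre-onset) or `"change"` (window (-0.15, 2.5) s, baseline 0.15 s
#'   pre-change).
#' @param kernel a `causal_kernel`.
#' @param lambda velocity-threshold multiplier.
#' @return named list of `rate_series` per condition label (sequence analysis
#'   labels by regularity over NC trials, change analysis by full condition).
#' @export
participant_ms_rate <- function(blocks, presses = NULL,
                                analysis = c("change", "sequence"),
                                kernel = causal_kernel(), lambda = 6,
                                params = synth_params()) {
  analysis <- match.arg(analysis)
  window_s <- if (analysis == "sequence") c(-0.5, 10) else c(-0.15, 2.5)
  baseline <- if (analysis == "sequence") c(-0.5, 0) else c(-0.15, 0)
  trains <- list()
  for (tr in blocks) {
    ev_ms <- detect_ms(tr, lambda)
    miss <- !tr$vl | !tr$vr
    evts <- analyzable_trials(tr$events, presses)
    if (analysis == "sequence") {
      evts <- evts[evts$change_type == "NC", , drop = FALSE]
      evts$label <- evts$regularity
      anchor_ms <- evts$onset_ms
    } else {
      evts$label <- evts$condition
      chg <- ifelse(is.finite(evts$change_time_s), evts$change_time_s, 6)
      anchor_ms <- evts$onset_ms + chg * 1000
    }
    for (i in seq_len(nrow(evts))) {
      idx <- round(anchor_ms[i] + window_s[1] * 1000):
        round(anchor_ms[i] + window_s[2] * 1000) + 1L
      idx <- idx[idx >= 1 & idx <= length(miss)]
      if (mean(miss[idx]) > 0.5) next
      rel <- (ev_ms$onset_ms - anchor_ms[i]) / 1000
      rel <- rel[rel >= window_s[1] - kernel$support_s - 0.5 &
                   rel <= window_s[2]]
      lab <- evts$label[i]
      trains[[lab]] <- c(trains[[lab]], list(rel))
    }
  }
  out <- list()
  for (lab in names(trains))
    out[[lab]] <- event_rate(trains[[lab]], window_s, kernel, baseline,
                             condition = lab)
  out
}

#' Export a microsaccade event table as TSV
#'
#' @param events event table from [detect_ms] (optionally with participant /
#'   block columns added).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ms_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
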