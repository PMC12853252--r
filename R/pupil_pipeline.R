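# Pupil preprocessing: missing-data masking, shape-preserving interpolation,
# Hann smoothing, epoching with rejection, per-block z-normalization, and
# condition averaging.

# start/end (inclusive, sample indices) of runs of TRUE
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# expand TRUE runs by pad samples on both sides
expand_mask <- function(mask, pad) {
  if (!any(mask) || pad <= 0) return(mask)
  out <- logical(length(mask))
  rr <- runs_of(mask)
  for (i in seq_len(nrow(rr)))
    out[max(1L, rr[i, 1] - pad):min(length(mask), rr[i, 2] + pad)] <- TRUE
  out
}

#' Mark missing pupil samples
#'
#' A sample is missing when (a) gaze is strictly outside a 100 px radius
#' around the fixation center, or (b) it falls inside an eye-closure interval
#' extended by 250 ms on both sides (blink-edge artifacts).
#'
#' @param trace a `sample_trace`.
#' @param eye `"left"` or `"right"`.
#' @param fixation fixation-cross center, `c(x, y)` in px.
#' @param radius_px fixation radius; distances strictly greater are missing.
#' @param pad_ms symmetric padding around closure intervals (ms).
#' @return logical vector, `TRUE` where missing.
#' @export
mask_missing <- function(trace, eye = c("left", "right"),
                         fixation = c(960, 540), radius_px = 100,
                         pad_ms = 250) {
  eye <- match.arg(eye)
  gx <- if (eye == "left") trace$xl else trace$xr
  gy <- if (eye == "left") trace$yl else trace$yr
  valid <- if (eye == "left") trace$vl else trace$vr
  away <- sqrt((gx - fixation[1])^2 + (gy - fixation[2])^2) > radius_px
  pad <- round(pad_ms / 1000 * trace$fs_hz)
  closed <- expand_mask(!valid, pad)
  away | closed
}

# Prefer the left eye; fall back to the right when the left is mostly lost.
choose_eye <- function(trace, fixation = c(960, 540), max_missing = 0.5) {
  ml <- mean(mask_missing(trace, "left", fixation))
  if (ml <= max_missing) return("left")
  mr <- mean(mask_missing(trace, "right", fixation))
  if (mr < ml) "right" else "left"
}

#' Interpolate missing samples (shape-preserving piecewise cubic)
#'
#' Missing spans are recovered with shape-preserving piecewise cubic Hermite
#' interpolation (pchip) through the valid samples.  The pchip tangent rule
#' (harmonic-mean slopes, zero at local extrema) keeps the interpolant free
#' of overshoot beyond neighboring data extrema even across long gaps.
#' Leading/trailing missing spans are held at the nearest valid value.
#'
#' @param y numeric series.
#' @param missing logical mask, `TRUE` where `y` is to be recovered.
#' @return gap-free numeric series.
#' @export
interpolate_missing <- function(y, missing) {
  if (!any(missing)) return(y)
  good <- which(!missing)
  if (length(good) < 2) stop("need at least 2 valid samples to interpolate")
  out <- y
  inner <- missing
  inner[seq_len(good[1])] <- FALSE
  inner[good[length(good)]:length(y)] <- FALSE
  if (any(inner)) {
    # pchip tangents are local (adjacent slopes only), so each gap can be
    # filled exactly from a few flanking valid samples
    gaps <- runs_of(inner)
    for (g in seq_len(nrow(gaps))) {
      lo <- gaps[g, 1]; hi <- gaps[g, 2]
      before <- good[good < lo]
      after <- good[good > hi]
      knots <- c(utils::tail(before, 3), utils::head(after, 3))
      out[lo:hi] <- pracma::pchip(knots, y[knots], lo:hi)
    }
  }
  if (good[1] > 1) out[seq_len(good[1] - 1L)] <- y[good[1]]
  if (good[length(good)] < length(y))
    out[(good[length(good)] + 1L):length(y)] <- y[good[length(good)]]
  out
}

#' Smooth with a Hann window
#'
#' Zero-phase convolution with a unit-area Hann window of `window_ms` length;
#' edges are handled by reflection.
#'
#' @param y gap-free numeric series.
#' @param window_ms window length in ms.
#' @param fs_hz sampling rate.
#' @return smoothed series, same length.
#' @export
hann_smooth <- function(y, window_ms = 150, fs_hz = 1000) {
  L <- round(window_ms / 1000 * fs_hz) + 1L   # odd, centered
  if (L %% 2L == 0L) L <- L + 1L
  k <- seq_len(L) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / (L - 1)))
  w <- w / sum(w)
  h <- (L - 1L) %/% 2L
  ypad <- c(y[(h + 1L):2L], y, y[(length(y) - 1L):(length(y) - h)])
  out <- stats::filter(ypad, w, sides = 2)
  as.numeric(out[(h + 1L):(h + length(y))])
}

#' Preprocess one block's pupil trace
#'
#' Eye selection (left preferred), missing-data masking, shape-preserving
#' interpolation, and Hann smoothing, in that order.  The pre-interpolation
#' mask is retained for epoch rejection.
#'
#' @param trace a `sample_trace`.
#' @param fixation fixation center (px).
#' @param eye `"auto"` (left unless mostly missing), `"left"`, or `"right"`.
#' @param window_ms Hann window (ms).
#' @return list with `y` (clean series), `missing` (pre-interpolation mask),
#'   `eye`.
#' @export
preprocess_pupil <- function(trace, fixation = c(960, 540), eye = "auto",
                             window_ms = 150) {
  if (eye == "auto") eye <- choose_eye(trace, fixation)
  missing <- mask_missing(trace, eye, fixation)
  y <- if (eye == "left") trace$pl else trace$pr
  y <- interpolate_missing(y, missing)
  y <- hann_smooth(y, window_ms, trace$fs_hz)
  list(y = y, missing = missing, eye = eye)
}

#' Cut epochs around events
#'
#' @param y numeric block series (typically preprocessed pupil).
#' @param missing pre-interpolation missing mask for the same block.
#' @param events block trial table with `onset_ms` (and `change_time_s` for
#'   change-locked alignment).
#' @param align `"onset"` (scene onset) or `"change"` (change time; NC trials
#'   use the nominal 6 s change point as control).
#' @param window_s epoch window, e.g. `c(-1, 10)`.
#' @param fs_hz sampling rate.
#' @param nominal_change_s control alignment point for NC trials.
#' @return list with `data` (trials x time), `missing_frac` per epoch,
#'   `time_s`, and the `events` rows used.
#' @export
cut_epochs <- function(y, missing, events, align = c("onset", "change"),
                       window_s, fs_hz = 1000, nominal_change_s = 6) {
  align <- match.arg(align)
  t_rel <- seq(round(window_s[1] * fs_hz), round(window_s[2] * fs_hz))
  anchor_ms <- events$onset_ms
  if (align == "change") {
    chg <- ifelse(is.finite(events$change_time_s), events$change_time_s,
                  nominal_change_s)
    anchor_ms <- anchor_ms + chg * 1000
  }
  n <- length(t_rel)
  data <- matrix(NA_real_, nrow(events), n)
  mfrac <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    idx <- round(anchor_ms[i]) + t_rel + 1L
    ok <- idx >= 1 & idx <= length(y)
    data[i, ok] <- y[idx[ok]]
    mfrac[i] <- mean(missing[idx[ok]])
  }
  list(data = data, missing_frac = mfrac, time_s = t_rel / fs_hz,
       events = events)
}

#' Epoch with rejection
#'
#' Removes decoy trials and trials containing a key press before epoching,
#' then discards epochs with more than 50% missing samples
#' (pre-interpolation) or with at least 10% of samples deviating more than
#' 3 SD from the per-time-point condition mean (single pass).
#'
#' @param epochs output of [cut_epochs] (all epochs of one condition for one
#'   participant).
#' @param condition condition label.
#' @param baseline_window_s baseline interval (s, relative to the alignment
#'   point) used later for normalization.
#' @param max_missing maximal allowed missing fraction (strictly greater
#'   rejects).
#' @param outlier_sd,outlier_frac outlier rule: reject when at least
#'   `outlier_frac` of samples deviate more than `outlier_sd` SD from the
#'   condition mean.
#' @return an `epoch_set`: list with `data`, `time_s`, `condition`,
#'   `baseline_window_s`, `n_rejected`, `block` (per surviving epoch).
#' @export
epoch_and_reject <- function(epochs, condition,
                             baseline_window_s = c(-1, 0),
                             max_missing = 0.5, outlier_sd = 3,
                             outlier_frac = 0.10) {
  keep <- epochs$missing_frac <= max_missing
  data <- epochs$data[keep, , drop = FALSE]
  ev <- epochs$events[keep, , drop = FALSE]
  if (nrow(data) > 2) {
    mu <- colMeans(data)
    sd <- apply(data, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- Inf
    frac_out <- rowMeans(abs(sweep(data, 2, mu)) >
                           outlier_sd * rep(sd, each = nrow(data)))
    ok <- frac_out < outlier_frac
    data <- data[ok, , drop = FALSE]
    ev <- ev[ok, , drop = FALSE]
  }
  structure(list(data = data, time_s = epochs$time_s, condition = condition,
                 baseline_window_s = baseline_window_s,
                 n_rejected = nrow(epochs$data) - nrow(data),
                 block = ev$block),
            class = "epoch_set")
}

#' z-normalize epochs by block/condition baseline statistics
#'
#' Pools all baseline samples of the epoch set's condition within each block,
#' computes their mean and SD, and z-scores every epoch of that block.
#'
#' @param epochset an `epoch_set` (one condition, one participant, possibly
#'   several blocks).
#' @return the z-scored `epoch_set`; epochs from blocks with zero baseline SD
#'   are dropped with a warning.
#' @export
znormalize <- function(epochset) {
  e <- epochset
  bl <- e$time_s >= e$baseline_window_s[1] & e$time_s < e$baseline_window_s[2]
  keep <- rep(TRUE, nrow(e$data))
  for (b in unique(e$block)) {
    rows <- which(e$block == b)
    base <- e$data[rows, bl, drop = FALSE]
    mu <- mean(base)
    sigma <- stats::sd(as.numeric(base))
    if (!is.finite(sigma) || sigma == 0) {
      warning("zero baseline SD in block ", b, "; epochs dropped")
      keep[rows] <- FALSE
      next
    }
    e$data[rows, ] <- (e$data[rows, ] - mu) / sigma
  }
  e$data <- e$data[keep, , drop = FALSE]
  e$block <- e$block[keep]
  e$n_rejected <- e$n_rejected + sum(!keep)
  e
}

#' Average an epoch set into a condition time course
#'
#' @param epochset an `epoch_set`.
#' @return list with `time_s`, `mean`, `sem` (across epochs), `n`,
#'   `condition`.
#' @export
average_condition <- function(epochset) {
  stopifnot(nrow(epochset$data) >= 1)
  m <- colMeans(epochset$data)
  s <- if (nrow(epochset$data) > 1)
    apply(epochset$data, 2, stats::sd) / sqrt(nrow(epochset$data))
  else rep(NA_real_, ncol(epochset$data))
  list(time_s = epochset$time_s, mean = m, sem = s,
       n = nrow(epochset$data), condition = epochset$condition)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s: %d epochs x %d samples (%d rejected), baseline [%g, %g) s\n",
    x$condition, nrow(x$data), ncol(x$data), x$n_rejected,
    x$baseline_window_s[1], x$baseline_window_s[2]))
  invisible(x)
}

# Analyzable (non-decoy, press-free) trials of one block's event table.
analyzable_trials <- function(events, presses = NULL) {
  keep <- !events$decoy
  if (!is.null(presses) && nrow(presses)) {
    pressed <- paste(presses$block, presses$trial)
    keep <- keep & !(paste(events$block, events$trial) %in% pressed)
  }
  events[keep, , drop = FALSE]
}

#' Participant-level pupil epochs per condition
#'
#' Runs the full preprocessing chain over all blocks of one participant and
#' returns z-scored epoch sets per condition, for either the sequence-evoked
#' analysis (NC trials, window \[-1, 10\] s around scene onset, conditions
#' REG/RND) or the change-locked analysis (window \[-0.5, 2.5\] s around
#' change time, six conditions, NC aligned at the nominal 6 s change point).
#'
#' @param blocks list of `sample_trace` (one per block).
#' @param presses key-press table (decides false-alarm exclusions).
#' @param analysis `"sequence"` or `"change"`.
#' @param params a `synth_params` (fixation center is read from it).
#' @return named list of `epoch_set` objects (by condition label).
#' @export
participant_pupil_epochs <- function(blocks, presses = NULL,
                                     analysis = c("sequence", "change"),
                                     params = synth_params()) {
  analysis <- match.arg(analysis)
  fixation <- c(params$fix_x, params$fix_y)
  window_s <- if (analysis == "sequence") c(-1, 10) else c(-0.5, 2.5)
  baseline <- if (analysis == "sequence") c(-1, 0) else c(-0.5, 0)
  align <- if (analysis == "sequence") "onset" else "change"
  per_cond <- list()
  for (tr in blocks) {
    pp <- preprocess_pupil(tr, fixation)
    ev <- analyzable_trials(tr$events, presses)
    if (analysis == "sequence") {
      ev <- ev[ev$change_type == "NC", , drop = FALSE]
      ev$label <- ev$regularity
    } else {
      ev$label <- ev$condition
    }
    for (lab in unique(ev$label)) {
      sub <- ev[ev$label == lab, , drop = FALSE]
      ep <- cut_epochs(pp$y, pp$missing, sub, align, window_s, tr$fs_hz)
      per_cond[[lab]] <- c(per_cond[[lab]], list(ep))
    }
  }
  out <- list()
  for (lab in names(per_cond)) {
    eps <- per_cond[[lab]]
    merged <- list(
      data = do.call(rbind, lapply(eps, `[[`, "data")),
      missing_frac = unlist(lapply(eps, `[[`, "missing_frac")),
      time_s = eps[[1]]$time_s,
      events = do.call(rbind, lapply(eps, `[[`, "events")))
    es <- epoch_and_reject(merged, lab, baseline_window_s = baseline)
    out[[lab]] <- znormalize(es)
  }
  out
}
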