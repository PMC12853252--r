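# Synthetic binocular eye-tracking generator.
#
# Produces 1 kHz binocular traces (gaze x/y in pixels, pupil in arbitrary
# units, validity flags) for whole experimental blocks, together with the
# ground truth that generated them (true microsaccades, true dilation events,
# tonic slopes, phasic amplitudes, inhibition parameters, blink intervals).
# Every downstream stage has a parameter-recovery test against this ground
# truth.  The generative model is a stand-in: no published generative model
# exists for these signals, so all distributional choices here are the
# package's own (see the methods vignette) and the analysis side never
# assumes the generator's kernel shapes.

#' Generator parameters
#'
#' Returns the default parameterization of the synthetic generator; any field
#' can be overridden by name.  Pupil values are in arbitrary units (a.u.),
#' gaze in screen pixels, times in seconds unless suffixed `_ms`.
#'
#' Key fields: tonic decline slopes `tonic_slope_reg`/`tonic_slope_rnd`
#' (a.u./s, decline from `tonic_start_s`; REG steeper); change-evoked phasic
#' dilations (`phasic_amp_ca` at delay `phasic_delay_ca_s`, and the CD
#' analogues, smaller and later); discrete dilation events at
#' `dil_event_rate_hz` whose local minima the dilation-rate pipeline detects;
#' microsaccades at `ms_base_rate_hz` with post-change inhibition of depth
#' `msi_depth` in \[0, 1\] peaking `msi_latency_s` after the change; blinks at
#' `blink_rate_hz` with partial-closure edge artifacts.
#'
#' @param ... named overrides of any default.
#' @return a classed list of generator parameters (`synth_params`).
#' @export
synth_params <- function(...) {
  p <- list(
    fs_hz = 1000, pre_s = 1.5, post_s = 1.6, scene_dur_s = 9,
    # pupil (a.u.)
    pupil_base = 1200, base_jitter_sd = 1,
    onset1_amp = 8, onset1_peak_s = 0.8, onset1_shape = 4,
    onset2_amp = 3, onset2_peak_s = 3, onset2_shape = 3,
    tonic_start_s = 3, tonic_slope_reg = 3, tonic_slope_rnd = 1.5,
    phasic_amp_ca = 8, phasic_delay_ca_s = 0.45, phasic_scale_ca_s = 0.4,
    phasic_amp_cd = 5, phasic_delay_cd_s = 1.0, phasic_scale_cd_s = 0.5,
    osc_amp = 0.3, osc_freq_hz = 0.25,
    dil_event_rate_hz = 1.3, dil_refractory_s = 0.5,
    dil_amp = 7, dil_rise_s = 0.12, dil_decay_s = 0.35,
    pdr_gain_ca = 1.0, pdr_gain_cd = 0.6,
    pupil_noise_sd = 1.5, eye_offset = 15,
    # gaze (px)
    fix_x = 960, fix_y = 540,
    drift_vel_sd = 20, drift_vel_theta = 10, drift_recenter = 0.002,
    gaze_noise_sd = 0.15,
    ms_base_rate_hz = 1.5, msi_depth = 0.8, msi_latency_s = 0.2,
    msi_width_s = 0.05, msi_onset_depth = 0.5,
    ms_amp_px = c(8, 25), ms_dur_ms = c(8, 22),
    ms_min_isi_s = 0.12, ms_disp_sd_ms = 2.5, ms_disp_max_ms = 8,
    ms_return_tau_s = 0.3,
    # blinks
    blink_rate_hz = 0.15, blink_dur_ms = c(80, 350), blink_edge_ms = c(20, 50),
    # behavior
    hit_prob = 0.97, rt_meanlog = log(0.5), rt_sdlog = 0.3,
    fa_rate_per_trial = 0.012,
    # between-participant variability (multiplicative CVs)
    between_slope_cv = 0.08, between_amp_cv = 0.10, between_msi_cv = 0.05
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  structure(p, class = "synth_params")
}

trial_len_ms <- function(p) round((p$pre_s + p$scene_dur_s + p$post_s) * 1000)

# unit-peak gamma-like bump, peak 1 at t = peak
gamma_bump <- function(t, peak, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / peak)^shape * exp(shape * (1 - t[pos] / peak))
  out
}

# dilation-event kernel, zero at origin, initial slope amp/rise
dil_kernel <- function(p, len_s = 2.5) {
  u <- seq(0, len_s, by = 1 / p$fs_hz)
  p$dil_amp * (1 - exp(-u / p$dil_rise_s)) * exp(-u / p$dil_decay_s)
}

#' Deterministic pupil template for one trial
#'
#' The noise-free tonic + phasic pupil time course: baseline, biphasic onset
#' response (peaks near 0.8 s and 3 s), sustained linear decline from
#' `tonic_start_s` (steeper for REG), and a change-locked phasic dilation for
#' CA/CD whose first departure from the NC template is at
#' `change_time + phasic_delay`.
#'
#' @param t_s time axis in seconds relative to scene onset.
#' @param regularity `"REG"` or `"RND"`.
#' @param change_type `"CA"`, `"CD"`, or `"NC"`.
#' @param change_time_s change time (s); ignored for NC.
#' @param params a `synth_params` object.
#' @return numeric vector of pupil values (a.u.).
#' @export
pupil_template <- function(t_s, regularity, change_type, change_time_s,
                           params = synth_params()) {
  p <- params
  y <- rep(p$pupil_base, length(t_s)) +
    p$onset1_amp * gamma_bump(t_s, p$onset1_peak_s, p$onset1_shape) +
    p$onset2_amp * gamma_bump(t_s, p$onset2_peak_s, p$onset2_shape)
  slope <- if (regularity == "REG") p$tonic_slope_reg else p$tonic_slope_rnd
  y <- y - slope * pmax(0, t_s - p$tonic_start_s)
  if (change_type %in% c("CA", "CD") && is.finite(change_time_s)) {
    amp <- if (change_type == "CA") p$phasic_amp_ca else p$phasic_amp_cd
    delay <- if (change_type == "CA") p$phasic_delay_ca_s else
      p$phasic_delay_cd_s
    scale <- if (change_type == "CA") p$phasic_scale_ca_s else
      p$phasic_scale_cd_s
    u <- t_s - change_time_s - delay
    pos <- u > 0
    y[pos] <- y[pos] + amp * (u[pos] / scale) * exp(1 - u[pos] / scale)
  }
  y
}

# Inhomogeneous Poisson thinning over a trial, with a refractory sweep.
# rate_fn(t_s) gives the rate in Hz over scene-relative time.
draw_point_process <- function(rate_fn, t0, t1, rate_max, refractory_s) {
  n <- stats::rpois(1, rate_max * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rate_fn(cand) / rate_max
  ev <- cand[keep]
  if (length(ev) > 1 && refractory_s > 0) {
    kept <- ev[1]
    for (e in ev[-1]) if (e - kept[length(kept)] > refractory_s)
      kept <- c(kept, e)
    ev <- kept
  }
  ev
}

#' Simulate the pupil time course for one trial
#'
#' Sum of the deterministic template ([pupil_template]), discrete dilation
#' events convolved with a smooth dilation kernel, a slow oscillation with
#' random phase, a per-trial baseline offset, and white noise.  Both eyes
#' share the physiological signal; the right eye adds an independent noise
#' draw and a constant size offset.
#'
#' @param trial one-row data frame (or list) with `regularity`, `change_type`,
#'   `change_time_s`.
#' @param params a `synth_params` object.
#' @return list with `time_s` (scene-relative), `left`, `right`, `template`,
#'   and `dil_events` (true dilation-event times, s, scene-relative).
#' @export
simulate_pupil <- function(trial, params = synth_params()) {
  p <- params
  n <- trial_len_ms(p)
  t_s <- (seq_len(n) - 1) / p$fs_hz - p$pre_s
  templ <- pupil_template(t_s, trial$regularity, trial$change_type,
                          trial$change_time_s, p)
  ev <- dil_event_times(trial, p, t0 = -p$pre_s,
                        t1 = p$scene_dur_s + p$post_s)
  dil <- dil_component(ev, t_s, p)
  osc <- if (p$osc_amp > 0)
    p$osc_amp * sin(2 * pi * p$osc_freq_hz * t_s + stats::runif(1, 0, 2 * pi))
  else 0
  jitter <- stats::rnorm(1, 0, p$base_jitter_sd)
  signal <- templ + dil + osc + jitter
  list(time_s = t_s,
       left = signal + stats::rnorm(n, 0, p$pupil_noise_sd),
       right = signal + p$eye_offset + stats::rnorm(n, 0, p$pupil_noise_sd),
       template = templ, dil_events = ev)
}

dil_event_times <- function(trial, p, t0, t1) {
  if (p$dil_event_rate_hz <= 0) return(numeric(0))
  chg <- trial$change_time_s
  gain <- switch(trial$change_type, CA = p$pdr_gain_ca, CD = p$pdr_gain_cd, 0)
  # the event-rate boost shares the condition's phasic onset delay, so each
  # condition has a single well-defined injected effect onset
  delay <- switch(trial$change_type, CA = p$phasic_delay_ca_s,
                  CD = p$phasic_delay_cd_s, 0)
  rate_fn <- function(t) {
    r <- rep(p$dil_event_rate_hz, length(t))
    if (gain > 0 && is.finite(chg)) {
      u <- t - chg - delay
      pos <- u > 0
      r[pos] <- r[pos] * (1 + gain * (u[pos] / 0.4) * exp(1 - u[pos] / 0.4))
    }
    r
  }
  draw_point_process(rate_fn, t0, t1, p$dil_event_rate_hz * (1 + max(0, gain)),
                     p$dil_refractory_s)
}

dil_component <- function(ev, t_s, p) {
  out <- numeric(length(t_s))
  if (!length(ev)) return(out)
  kern <- dil_kernel(p)
  fs <- p$fs_hz
  for (e in ev) {
    i0 <- round((e - t_s[1]) * fs) + 1L
    if (i0 > length(t_s)) next
    k <- min(length(kern), length(t_s) - i0 + 1L)
    j <- max(1L, i0)
    out[j:(i0 + k - 1L)] <- out[j:(i0 + k - 1L)] + kern[(j - i0 + 1L):k]
  }
  out
}

#' Simulate binocular gaze for one trial
#'
#' Fixational drift (mean-reverting random walk around fixation) plus
#' conjugate microsaccades from an inhomogeneous Poisson process whose rate
#' dips after scene onset, offset, and the scene change (microsaccadic
#' inhibition): `r(t) = base * (1 - depth * g(t - change - latency))` with a
#' unimodal Gaussian bump `g`.  Each microsaccade is a raised-cosine position
#' step (amplitude 8-25 px, duration 8-22 ms) executed by both eyes with an
#' inter-eye onset disparity below 10 ms, followed by a slow exponential
#' return; inter-event spacing is kept above `ms_min_isi_s`.
#'
#' @inheritParams simulate_pupil
#' @return list with `time_s`, per-eye gaze (`xl`, `yl`, `xr`, `yr`), and
#'   `ms_events` (data frame of true microsaccades: `onset_s`, `onset_r_s`,
#'   `dur_ms`, `amp_px`, `angle`, `disparity_ms`).
#' @export
simulate_gaze <- function(trial, params = synth_params()) {
  p <- params
  n <- trial_len_ms(p)
  t_s <- (seq_len(n) - 1) / p$fs_hz - p$pre_s
  drift <- ou_drift(n, p)
  ms <- draw_ms_events(trial, p, t0 = -p$pre_s, t1 = p$scene_dur_s + p$post_s)
  disp <- ms_displacement(ms, t_s, p)
  list(time_s = t_s,
       xl = p$fix_x + drift$x + disp$xl + stats::rnorm(n, 0, p$gaze_noise_sd),
       yl = p$fix_y + drift$y + disp$yl + stats::rnorm(n, 0, p$gaze_noise_sd),
       xr = p$fix_x + drift$x + disp$xr + stats::rnorm(n, 0, p$gaze_noise_sd),
       yr = p$fix_y + drift$y + disp$yr + stats::rnorm(n, 0, p$gaze_noise_sd),
       ms_events = ms)
}

# Smooth fixational drift: the drift *velocity* is a mean-reverting
# (Ornstein-Uhlenbeck) process, integrated into position with a weak
# recentering pull toward fixation.  This yields slow, smooth wander (real
# drift is slow relative to microsaccades) rather than sample-to-sample
# jitter, so the velocity-threshold detector sees a realistic noise floor.
ou_drift <- function(n, p) {
  dt <- 1 / p$fs_hz
  phi_v <- exp(-p$drift_vel_theta * dt)
  step_sd <- p$drift_vel_sd * sqrt(1 - phi_v^2)
  one <- function() {
    v <- as.numeric(stats::filter(stats::rnorm(n, 0, step_sd), phi_v,
                                  "recursive"))
    as.numeric(stats::filter(v * dt, 1 - p$drift_recenter, "recursive"))
  }
  list(x = one(), y = one())
}

draw_ms_events <- function(trial, p, t0, t1) {
  base <- p$ms_base_rate_hz
  if (base <= 0)
    return(data.frame(onset_s = numeric(0), onset_r_s = numeric(0),
                      dur_ms = numeric(0), amp_px = numeric(0),
                      angle = numeric(0), disparity_ms = numeric(0)))
  chg <- trial$change_time_s
  bump <- function(u) exp(-u^2 / (2 * p$msi_width_s^2))
  rate_fn <- function(t) {
    r <- 1 - p$msi_onset_depth * bump(t - p$msi_latency_s) -
      p$msi_onset_depth * bump(t - p$scene_dur_s - p$msi_latency_s)
    if (is.finite(chg) && trial$change_type %in% c("CA", "CD"))
      r <- r - p$msi_depth * bump(t - chg - p$msi_latency_s)
    base * pmax(0, r)
  }
  # dead-time compensation: the minimal inter-event spacing thins a Poisson
  # stream by ~ 1/(1 + r*tau); drive the generator harder so the realized
  # rate matches the nominal base rate
  k <- 1 / max(0.1, 1 - base * p$ms_min_isi_s)
  on <- draw_point_process(function(t) k * rate_fn(t), t0, t1, k * base,
                           p$ms_min_isi_s)
  k <- length(on)
  disp_ms <- pmin(p$ms_disp_max_ms - 1e-6,
                  pmax(-(p$ms_disp_max_ms - 1e-6),
                       stats::rnorm(k, 0, p$ms_disp_sd_ms)))
  data.frame(
    onset_s = on,
    onset_r_s = on + disp_ms / 1000,
    dur_ms = stats::runif(k, p$ms_dur_ms[1], p$ms_dur_ms[2]),
    amp_px = stats::runif(k, p$ms_amp_px[1], p$ms_amp_px[2]),
    angle = stats::runif(k, 0, 2 * pi),
    disparity_ms = disp_ms)
}

# raised-cosine position step per eye plus a slow exponential return
ms_displacement <- function(ms, t_s, p) {
  n <- length(t_s)
  out <- list(xl = numeric(n), yl = numeric(n),
              xr = numeric(n), yr = numeric(n))
  if (!nrow(ms)) return(out)
  fs <- p$fs_hz
  tail_n <- round(5 * p$ms_return_tau_s * fs)
  for (i in seq_len(nrow(ms))) {
    dx <- ms$amp_px[i] * cos(ms$angle[i])
    dy <- ms$amp_px[i] * sin(ms$angle[i])
    d_n <- max(2L, round(ms$dur_ms[i] / 1000 * fs))
    prof <- c(0.5 * (1 - cos(pi * seq_len(d_n) / d_n)),
              exp(-(seq_len(tail_n)) / (p$ms_return_tau_s * fs)))
    for (eye in c("l", "r")) {
      onset <- if (eye == "l") ms$onset_s[i] else ms$onset_r_s[i]
      i0 <- round((onset - t_s[1]) * fs) + 1L
      if (i0 > n) next
      k <- min(length(prof), n - i0 + 1L)
      j0 <- max(1L, i0)
      idx <- j0:(i0 + k - 1L)
      pr <- prof[(j0 - i0 + 1L):k]
      out[[paste0("x", eye)]][idx] <- out[[paste0("x", eye)]][idx] + dx * pr
      out[[paste0("y", eye)]][idx] <- out[[paste0("y", eye)]][idx] + dy * pr
    }
  }
  out
}

#' Inject eye-closure (blink) intervals into a trace
#'
#' Closure intervals occur at Poisson times.  During full closure both eyes'
#' validity flags are false and the pupil signal is lost (set to 0); each
#' closure is flanked by 20-50 ms partial-closure edges in which the pupil is
#' artifactually reduced while the validity flag stays true (the downstream
#' 250 ms padding is what removes these).  Gaze is held at the last valid
#' position during closure.
#'
#' @param trace a `sample_trace`.
#' @param params a `synth_params` object.
#' @return the trace with closures applied and `blink_intervals` recorded in
#'   its ground truth.
#' @export
inject_blinks <- function(trace, params = synth_params()) {
  p <- params
  n <- length(trace$time_ms)
  if (p$blink_rate_hz <= 0) {
    trace$ground_truth$blink_intervals <-
      data.frame(start_ms = numeric(0), end_ms = numeric(0))
    return(trace)
  }
  k <- stats::rpois(1, p$blink_rate_hz * n / p$fs_hz)
  starts <- sort(stats::runif(k, 0, n / p$fs_hz)) * 1000
  durs <- stats::runif(k, p$blink_dur_ms[1], p$blink_dur_ms[2])
  keep <- starts + durs < n - 60 & starts > 60
  starts <- starts[keep]; durs <- durs[keep]
  for (i in seq_along(starts)) {
    i0 <- round(starts[i]) + 1L
    i1 <- round(starts[i] + durs[i])
    e0 <- round(stats::runif(1, p$blink_edge_ms[1], p$blink_edge_ms[2]))
    e1 <- round(stats::runif(1, p$blink_edge_ms[1], p$blink_edge_ms[2]))
    closed <- i0:i1
    trace$vl[closed] <- FALSE
    trace$vr[closed] <- FALSE
    trace$pl[closed] <- 0
    trace$pr[closed] <- 0
    hold <- max(1L, i0 - 1L)
    for (g in c("xl", "yl", "xr", "yr"))
      trace[[g]][closed] <- trace[[g]][hold]
    pre <- max(1L, i0 - e0):(i0 - 1L)
    post <- (i1 + 1L):min(n, i1 + e1)
    ramp_pre <- seq(1, 0.35, length.out = length(pre))
    ramp_post <- seq(0.35, 1, length.out = length(post))
    trace$pl[pre] <- trace$pl[pre] * ramp_pre
    trace$pr[pre] <- trace$pr[pre] * ramp_pre
    trace$pl[post] <- trace$pl[post] * ramp_post
    trace$pr[post] <- trace$pr[post] * ramp_post
  }
  trace$ground_truth$blink_intervals <-
    data.frame(start_ms = starts, end_ms = starts + durs)
  trace
}

#' Simulate one experimental block
#'
#' Lays the given trials end to end (each trial spans `pre_s` before scene
#' onset to `post_s` after scene offset) and generates the full binocular
#' trace plus ground truth.
#'
#' @param trials data frame of trials for one block (columns `block`, `trial`,
#'   `condition`, `regularity`, `change_type`, `change_time_s`, `gap_start_s`,
#'   `decoy`), e.g. a block subset of `build_session()$trials`.
#' @param params a `synth_params` object.
#' @param blinks logical; inject eye closures?
#' @return a `sample_trace`: list with `fs_hz`, `time_ms`, per-eye gaze
#'   (`xl`, `yl`, `xr`, `yr`), pupil (`pl`, `pr`), validity (`vl`, `vr`),
#'   an `events` table (the trials with their block-time `onset_ms`), and
#'   `ground_truth` (`ms`, `dil`, `blink_intervals`, `params`).
#' @export
simulate_block <- function(trials, params = synth_params(), blinks = TRUE) {
  p <- params
  len <- trial_len_ms(p)
  n <- len * nrow(trials)
  tr <- list(fs_hz = p$fs_hz, time_ms = seq_len(n) - 1L,
             xl = numeric(n), yl = numeric(n), pl = numeric(n),
             vl = rep(TRUE, n), xr = numeric(n), yr = numeric(n),
             pr = numeric(n), vr = rep(TRUE, n))
  ms_gt <- list(); dil_gt <- list()
  trials$onset_ms <- (seq_len(nrow(trials)) - 1L) * len + p$pre_s * 1000
  for (i in seq_len(nrow(trials))) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    trial <- trials[i, ]
    pu <- simulate_pupil(trial, p)
    gz <- simulate_gaze(trial, p)
    tr$pl[idx] <- pu$left; tr$pr[idx] <- pu$right
    tr$xl[idx] <- gz$xl; tr$yl[idx] <- gz$yl
    tr$xr[idx] <- gz$xr; tr$yr[idx] <- gz$yr
    if (length(pu$dil_events))
      dil_gt[[length(dil_gt) + 1L]] <- data.frame(
        trial = trial$trial, time_s = pu$dil_events,
        block_ms = trials$onset_ms[i] + pu$dil_events * 1000)
    if (nrow(gz$ms_events)) {
      m <- gz$ms_events
      m$trial <- trial$trial
      m$block_ms <- trials$onset_ms[i] + m$onset_s * 1000
      ms_gt[[length(ms_gt) + 1L]] <- m
    }
  }
  tr$events <- trials
  tr$ground_truth <- list(
    ms = if (length(ms_gt)) do.call(rbind, ms_gt) else NULL,
    dil = if (length(dil_gt)) do.call(rbind, dil_gt) else NULL,
    params = p)
  tr <- structure(tr, class = "sample_trace")
  if (blinks) tr <- inject_blinks(tr, p) else
    tr$ground_truth$blink_intervals <-
      data.frame(start_ms = numeric(0), end_ms = numeric(0))
  tr
}

# Per-participant parameter heterogeneity (multiplicative jitter).
participant_params <- function(params, id) {
  p <- params
  jit <- function(cv) max(0.5, stats::rnorm(1, 1, cv))
  p$tonic_slope_reg <- p$tonic_slope_reg * jit(p$between_slope_cv)
  p$tonic_slope_rnd <- p$tonic_slope_rnd * jit(p$between_slope_cv)
  p$phasic_amp_ca <- p$phasic_amp_ca * jit(p$between_amp_cv)
  p$phasic_amp_cd <- p$phasic_amp_cd * jit(p$between_amp_cv)
  p$msi_depth <- min(1, p$msi_depth * jit(p$between_msi_cv))
  p
}

#' Simulate key presses for the decoy gap-detection task
#'
#' Decoy gaps are detected with probability `hit_prob` at a lognormal
#' reaction time; false alarms occur at a small per-trial rate, uniformly
#' within the trial window.
#'
#' @param trials session trial table.
#' @param params a `synth_params` object.
#' @return data frame with `block`, `trial`, `press_s` (scene-relative).
#' @export
simulate_presses <- function(trials, params = synth_params()) {
  p <- params
  out <- list()
  for (i in seq_len(nrow(trials))) {
    presses <- numeric(0)
    if (isTRUE(trials$decoy[i]) && stats::runif(1) < p$hit_prob) {
      rt <- min(1.9, stats::rlnorm(1, p$rt_meanlog, p$rt_sdlog))
      presses <- trials$gap_start_s[i] + rt
    }
    n_fa <- stats::rpois(1, p$fa_rate_per_trial)
    if (n_fa > 0)
      presses <- c(presses, stats::runif(n_fa, 0, p$scene_dur_s + 1))
    if (length(presses))
      out[[length(out) + 1L]] <- data.frame(
        block = trials$block[i], trial = trials$trial[i], press_s = presses)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(block = integer(0), trial = integer(0), press_s = numeric(0))
}

#' Simulate a full participant
#'
#' Builds a session design from `design_seed`, draws participant-level
#' parameters (mild multiplicative heterogeneity), simulates every block and
#' the decoy-task behavior.
#'
#' @param id participant identifier.
#' @param seed integer seed for this participant's data.
#' @param params a `synth_params` object (group-level).
#' @param n_blocks blocks per session.
#' @param blinks logical; inject eye closures?
#' @return list with `id`, `design`, `params` (participant-level), `blocks`
#'   (list of `sample_trace`), `presses`.
#' @export
simulate_participant <- function(id, seed, params = synth_params(),
                                 n_blocks = 8L, blinks = TRUE) {
  design <- build_session(seed, n_blocks = n_blocks)
  pp <- participant_params(params, id)
  blocks <- lapply(seq_len(n_blocks), function(b)
    simulate_block(design$trials[design$trials$block == b, , drop = FALSE],
                   pp, blinks = blinks))
  presses <- simulate_presses(design$trials, pp)
  list(id = id, design = design, params = pp, blocks = blocks,
       presses = presses)
}

#' @export
print.sample_trace <- function(x, ...) {
  cat(sprintf(
    "<sample_trace> %d samples at %g Hz (%.1f s), %d trials, %.1f%% invalid\n",
    length(x$time_ms), x$fs_hz, length(x$time_ms) / x$fs_hz,
    nrow(x$events), 100 * mean(!x$vl)))
  invisible(x)
}
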