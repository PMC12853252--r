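# Stimulus construction: multi-stream tone-cloud "scenes".
#
# A scene is 9 s of six concurrent pure-tone streams, each with a unique
# carrier frequency and its own temporal structure.  REG streams are
# isochronous (fixed tone duration and inter-tone interval); RND streams
# redraw the inter-tone interval for every gap.  Scene changes are the
# appearance (CA) or disappearance (CD) of a single stream around 6 s;
# NC scenes have no change.  Decoy trials additionally carry a 200 ms
# global silent gap that participants respond to.

#' ERB-rate ("cam") scale conversions
#'
#' Converts frequency in Hz to the ERB-rate number (unit: cam) using the
#' Glasberg & Moore formula \eqn{21.4 \log_{10}(4.37 f_{kHz} + 1)}, and back.
#'
#' @param f_hz frequency in Hz.
#' @return ERB-rate value in cam.
#' @export
erb_cam <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)

#' @rdname erb_cam
#' @param cam ERB-rate value in cam.
#' @return frequency in Hz.
#' @export
erb_cam_inv <- function(cam) (10^(cam / 21.4) - 1) / 4.37 * 1000

#' Carrier-frequency pool
#'
#' Nine fixed carrier frequencies between 500 and 3,225 Hz, equally spaced on
#' the ERB-rate (cam) scale.  Both endpoints are honored exactly; interior
#' values are placed at equal cam steps between the endpoint cam values.
#'
#' @param n number of pool frequencies.
#' @param f_lo,f_hi endpoint frequencies in Hz.
#' @return strictly increasing numeric vector of length `n` (Hz).
#' @export
make_frequency_pool <- function(n = 9L, f_lo = 500, f_hi = 3225) {
  cams <- seq(erb_cam(f_lo), erb_cam(f_hi), length.out = n)
  pool <- erb_cam_inv(cams)
  pool[1] <- f_lo
  pool[n] <- f_hi
  pool
}

# Onset schedule for one stream over [0, dur_ms).  Returns onsets plus the
# iti actually used after each tone (needed for CD change-time arithmetic).
stream_schedule <- function(tone_dur_ms, iti_ms, phase_offset_ms, dur_ms,
                            regular) {
  onsets <- numeric(0)
  itis <- numeric(0)
  t <- phase_offset_ms
  i <- 1L
  while (t < dur_ms) {
    onsets <- c(onsets, t)
    iti <- if (regular) iti_ms[1] else iti_ms[min(i, length(iti_ms))]
    itis <- c(itis, iti)
    t <- t + tone_dur_ms + iti
    i <- i + 1L
  }
  list(onsets = onsets, itis = itis)
}

#' Sample one tone-pip stream
#'
#' Tone-pip duration and inter-tone interval(s) are drawn uniformly from
#' \[10, 150\] ms.  REG streams fix one ITI for the whole scene; RND streams
#' redraw the ITI for every gap.  Streams are phase randomized: with
#' probability 1/2 the scene starts with a tone (first onset at 0), otherwise
#' with a silent interval whose duration is uniform within the first ITI.
#'
#' @param regularity `"REG"` or `"RND"`.
#' @param duration_s scene duration in seconds.
#' @param carrier_hz carrier frequency in Hz (may be `NA` until assigned).
#' @param tone_range_ms,iti_range_ms sampling ranges in ms.
#' @return a `stream_spec`: list with `regularity`, `carrier_hz`,
#'   `tone_dur_ms`, `iti_ms` (length 1 for REG, per-gap for RND),
#'   `phase_offset_ms`, `onset_times_ms`, `active_from_s`.
#' @export
sample_stream <- function(regularity = c("REG", "RND"), duration_s = 9,
                          carrier_hz = NA_real_,
                          tone_range_ms = c(10, 150),
                          iti_range_ms = c(10, 150)) {
  regularity <- match.arg(regularity)
  dur_ms <- duration_s * 1000
  tone <- stats::runif(1, tone_range_ms[1], tone_range_ms[2])
  regular <- regularity == "REG"
  n_max <- ceiling(dur_ms / (tone + iti_range_ms[1])) + 2L
  itis <- if (regular) stats::runif(1, iti_range_ms[1], iti_range_ms[2]) else
    stats::runif(n_max, iti_range_ms[1], iti_range_ms[2])
  start_with_tone <- stats::runif(1) < 0.5
  phase <- if (start_with_tone) 0 else stats::runif(1, 0, itis[1])
  sched <- stream_schedule(tone, itis, phase, dur_ms, regular)
  structure(list(
    regularity = regularity,
    carrier_hz = carrier_hz,
    tone_dur_ms = tone,
    iti_ms = if (regular) itis else sched$itis,
    phase_offset_ms = phase,
    onset_times_ms = sched$onsets,
    active_from_s = 0
  ), class = "stream_spec")
}

# Appearing stream for CA scenes: first tone onset exactly at change_s.
sample_appearing_stream <- function(regularity, duration_s, change_s,
                                    carrier_hz,
                                    tone_range_ms = c(10, 150),
                                    iti_range_ms = c(10, 150)) {
  s <- sample_stream(regularity, duration_s, carrier_hz,
                     tone_range_ms, iti_range_ms)
  dur_ms <- duration_s * 1000
  change_ms <- change_s * 1000
  regular <- s$regularity == "REG"
  sched <- stream_schedule(s$tone_dur_ms, s$iti_ms, change_ms, dur_ms, regular)
  s$phase_offset_ms <- change_ms
  s$onset_times_ms <- sched$onsets
  if (!regular) s$iti_ms <- sched$itis
  s$active_from_s <- change_s
  s
}

#' Build one scene
#'
#' Assembles six base streams with distinct pool carriers and schedules the
#' change.  CA: a seventh stream whose first tone onset is exactly 6 s after
#' scene onset.  CD-REG: one base stream is truncated so that its expected
#' next onset (last tone offset + the stream's fixed ITI) is as close to 6 s
#' as possible; that expected onset is the change time.  CD-RND: same, with
#' the mean ITI (80 ms) in place of a fixed ITI.  NC: no change.
#'
#' @param change_type `"CA"`, `"CD"`, or `"NC"`.
#' @param regularity `"REG"` or `"RND"`.
#' @param duration_s scene duration (s).
#' @param change_target_s nominal change time (s).
#' @param pool carrier-frequency pool (Hz).
#' @param n_streams number of base streams.
#' @return a `scene_spec`: list with `regularity`, `change_type`, `duration_s`,
#'   `streams` (list of `stream_spec`), `change_stream_index`, `change_time_s`,
#'   `gap` (`NULL` or `c(start_s, dur_s)`).
#' @export
build_scene <- function(change_type = c("CA", "CD", "NC"),
                        regularity = c("REG", "RND"),
                        duration_s = 9, change_target_s = 6,
                        pool = make_frequency_pool(), n_streams = 6L) {
  change_type <- match.arg(change_type)
  regularity <- match.arg(regularity)
  n_carriers <- n_streams + (change_type == "CA")
  carriers <- sample(pool, n_carriers)
  streams <- lapply(carriers[seq_len(n_streams)], function(f)
    sample_stream(regularity, duration_s, carrier_hz = f))
  change_idx <- NA_integer_
  change_time <- NA_real_
  if (change_type == "CA") {
    app <- sample_appearing_stream(regularity, duration_s, change_target_s,
                                   carriers[n_carriers])
    streams <- c(streams, list(app))
    change_idx <- n_streams + 1L
    change_time <- change_target_s
  } else if (change_type == "CD") {
    change_idx <- sample.int(n_streams, 1L)
    s <- streams[[change_idx]]
    onsets <- s$onset_times_ms
    next_iti <- if (s$regularity == "REG") rep(s$iti_ms, length(onsets)) else 80
    cand_ms <- onsets + s$tone_dur_ms + next_iti # expected next-onset times
    k <- which.min(abs(cand_ms - change_target_s * 1000))
    s$onset_times_ms <- onsets[seq_len(k)]
    if (s$regularity == "RND") s$iti_ms <- s$iti_ms[seq_len(k)]
    streams[[change_idx]] <- s
    change_time <- cand_ms[k] / 1000
    # deviations beyond half the maximal stream period cannot occur by
    # construction; guard against pathological inputs anyway
    stopifnot(abs(change_time - change_target_s) <= 0.3)
  }
  structure(list(
    regularity = regularity,
    change_type = change_type,
    duration_s = duration_s,
    streams = streams,
    change_stream_index = change_idx,
    change_time_s = change_time,
    gap = NULL
  ), class = "scene_spec")
}

#' Insert a decoy gap into a scene
#'
#' A 200 ms silent gap across all streams, starting uniformly between 1 s
#' post onset and 1 s pre offset.
#'
#' @param scene a `scene_spec` without a gap.
#' @param gap_dur_s gap duration (s).
#' @param margin_s protected margin at both ends (s).
#' @return the scene with `gap = c(start_s, dur_s)`.
#' @export
insert_gap <- function(scene, gap_dur_s = 0.2, margin_s = 1) {
  stopifnot(inherits(scene, "scene_spec"), is.null(scene$gap))
  start <- stats::runif(1, margin_s, scene$duration_s - margin_s - gap_dur_s)
  scene$gap <- c(start_s = start, dur_s = gap_dur_s)
  scene
}

#' Build a full session design
#'
#' Eight blocks of 30 trials each: four trials of each of the six main
#' conditions (REG/RND x CA/CD/NC) plus one gap-containing decoy trial per
#' condition, in randomized order within block.
#'
#' @param rng_seed integer seed; the design is fully reproducible from it.
#' @param n_blocks number of blocks.
#' @param trials_per_condition main trials per condition per block.
#' @param decoys_per_condition decoy trials per condition per block.
#' @param duration_s scene duration (s).
#' @return a `session_design`: list with `n_blocks`, `rng_seed`, `scenes`
#'   (list of `scene_spec` in presentation order) and `trials` (data frame
#'   with block, trial, condition, regularity, change_type, change_time_s,
#'   gap_start_s, decoy).
#' @export
build_session <- function(rng_seed, n_blocks = 8L, trials_per_condition = 4L,
                          decoys_per_condition = 1L, duration_s = 9) {
  set.seed(rng_seed)
  regs <- c("REG", "RND")
  chgs <- c("CA", "CD", "NC")
  grid <- expand.grid(regularity = regs, change_type = chgs,
                      stringsAsFactors = FALSE)
  scenes <- list()
  rows <- list()
  for (b in seq_len(n_blocks)) {
    block_scenes <- list()
    block_meta <- list()
    for (i in seq_len(nrow(grid))) {
      for (j in seq_len(trials_per_condition + decoys_per_condition)) {
        sc <- build_scene(grid$change_type[i], grid$regularity[i],
                          duration_s = duration_s)
        decoy <- j > trials_per_condition
        if (decoy) sc <- insert_gap(sc)
        block_scenes[[length(block_scenes) + 1L]] <- sc
        block_meta[[length(block_meta) + 1L]] <- data.frame(
          regularity = sc$regularity, change_type = sc$change_type,
          change_time_s = ifelse(is.na(sc$change_time_s), NA_real_,
                                 sc$change_time_s),
          gap_start_s = if (decoy) sc$gap[["start_s"]] else NA_real_,
          decoy = decoy
        )
      }
    }
    ord <- sample.int(length(block_scenes))
    block_scenes <- block_scenes[ord]
    block_meta <- do.call(rbind, block_meta)[ord, , drop = FALSE]
    block_meta$block <- b
    block_meta$trial <- seq_len(nrow(block_meta))
    scenes <- c(scenes, block_scenes)
    rows[[b]] <- block_meta
  }
  trials <- do.call(rbind, rows)
  trials$condition <- paste(trials$regularity, trials$change_type, sep = "-")
  rownames(trials) <- NULL
  cols <- c("block", "trial", "condition", "regularity", "change_type",
            "change_time_s", "gap_start_s", "decoy")
  structure(list(n_blocks = n_blocks, rng_seed = rng_seed,
                 scenes = scenes, trials = trials[, cols]),
            class = "session_design")
}

#' Serialize a session design
#'
#' `write_trial_table()` writes the trial table as TSV;
#' `write_session_json()` writes the complete design (including every stream
#' schedule) as JSON.
#'
#' @param design a `session_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(design, path) {
  utils::write.table(design$trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
write_session_json <- function(design, path) {
  x <- unclass(design)
  x$scenes <- lapply(x$scenes, function(sc) {
    sc$streams <- lapply(sc$streams, unclass)
    unclass(sc)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %s-%s, %g s, %d streams", x$regularity,
              x$change_type, x$duration_s, length(x$streams)))
  if (!is.na(x$change_time_s))
    cat(sprintf(", change at %.3f s", x$change_time_s))
  if (!is.null(x$gap))
    cat(sprintf(", gap at %.2f s", x$gap[["start_s"]]))
  cat("\n")
  invisible(x)
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> seed %d: %d blocks, %d trials (%d decoys)\n",
              x$rng_seed, x$n_blocks, nrow(x$trials), sum(x$trials$decoy)))
  print(table(x$trials$condition, ifelse(x$trials$decoy, "decoy", "main")))
  invisible(x)
}
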