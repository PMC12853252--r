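# Audio rendering of scene specifications (additive pure-tone synthesis).

#' Render a scene to an audio waveform
#'
#' Additive synthesis of all tone pips on the scene schedule.  Each pip is a
#' pure tone with 3 ms raised-cosine on/off ramps; pips running past the scene
#' end are truncated.  Output is diotic (mono).  If the scene carries a decoy
#' gap, all samples inside the gap are silenced.
#'
#' @param scene a `scene_spec`.
#' @param sample_rate_hz audio sampling rate; must exceed twice the highest
#'   carrier (aliasing guard).
#' @param amplitude per-stream peak amplitude.
#' @param ramp_ms raised-cosine ramp duration (ms).
#' @return numeric waveform of length `duration_s * sample_rate_hz`.
#' @export
render_scene <- function(scene, sample_rate_hz = 44100, amplitude = 0.1,
                         ramp_ms = 3) {
  stopifnot(inherits(scene, "scene_spec"))
  carriers <- vapply(scene$streams, function(s) s$carrier_hz, numeric(1))
  if (any(!is.finite(carriers)))
    stop("all streams need a carrier frequency to render")
  if (max(carriers) >= sample_rate_hz / 2)
    stop("carrier at or above Nyquist frequency; raise sample_rate_hz")
  n <- round(scene$duration_s * sample_rate_hz)
  wave <- numeric(n)
  for (s in scene$streams)
    wave <- wave + render_stream(s, sample_rate_hz, n, amplitude, ramp_ms)
  if (!is.null(scene$gap)) {
    i0 <- floor(scene$gap[["start_s"]] * sample_rate_hz) + 1L
    i1 <- min(n, ceiling((scene$gap[["start_s"]] + scene$gap[["dur_s"]]) *
                           sample_rate_hz))
    wave[i0:i1] <- 0
  }
  wave
}

#' @rdname render_scene
#' @param stream a `stream_spec` with a carrier assigned.
#' @param n_samples output length in samples.
#' @export
render_stream <- function(stream, sample_rate_hz, n_samples, amplitude = 0.1,
                          ramp_ms = 3) {
  wave <- numeric(n_samples)
  pip_n <- round(stream$tone_dur_ms / 1000 * sample_rate_hz)
  env <- pip_envelope(pip_n, ramp_ms / 1000 * sample_rate_hz)
  for (onset_ms in stream$onset_times_ms) {
    i0 <- round(onset_ms / 1000 * sample_rate_hz) + 1L
    if (i0 > n_samples) next
    k <- min(pip_n, n_samples - i0 + 1L)
    t <- (seq_len(k) - 1L) / sample_rate_hz
    wave[i0:(i0 + k - 1L)] <- wave[i0:(i0 + k - 1L)] +
      amplitude * sin(2 * pi * stream$carrier_hz * t) * env[seq_len(k)]
  }
  wave
}

# Unit envelope with raised-cosine on/off ramps of ramp_n samples.
pip_envelope <- function(pip_n, ramp_n) {
  ramp_n <- min(round(ramp_n), floor(pip_n / 2))
  env <- rep(1, pip_n)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 0.5) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[pip_n + 1L - seq_len(ramp_n)] <- up
  }
  env
}

#' Write a waveform to a mono 16-bit PCM WAV file
#'
#' @param wave numeric waveform in \[-1, 1\] (values are clipped).
#' @param path output path.
#' @param sample_rate_hz sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate_hz = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
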