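# Run configuration: one flat, serializable list drives the whole pipeline.
# Every preprocessing / detection threshold from the analysis definition is
# exposed with its standard default.

#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline].  All
#' thresholds default to the analysis' standard values; the `small` preset
#' shrinks the cohort (6 participants, 2 blocks) and the bootstrap counts for
#' quick runs.
#'
#' @param preset `"full"` (36 participants, 8 blocks) or `"small"`.
#' @param ... named overrides of any field.
#' @return a `run_config` list.
#' @export
run_config <- function(preset = c("full", "small"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    n_participants = 36L,
    n_blocks = 8L,
    generator = list(),                 # synth_params overrides
    blinks = TRUE,
    # preprocessing
    fixation_radius_px = 100, closure_pad_ms = 250, hann_ms = 150,
    max_missing_frac = 0.5, outlier_sd = 3, outlier_frac = 0.10,
    # detection
    ms_lambda = 6, ms_dur_ms = c(5, 100), ms_disparity_ms = 10,
    ms_refractory_ms = 50, min_dilation_ms = 100, kernel_alpha_ms = 150,
    # statistics
    n_boot = 1000L, boot_alpha = 0.05, noise_floor_iter = 100L,
    latency_iter = 500L, floor_quantile = 0.95, roi_s = c(0.1, 0.25),
    run_noise_floor = TRUE, run_latencies = TRUE,
    # output
    out_dir = NULL
  )
  if (preset == "small") {
    cfg$n_participants <- 6L
    cfg$n_blocks <- 2L
    cfg$n_boot <- 200L
    cfg$noise_floor_iter <- 20L
    cfg$latency_iter <- 50L
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The configuration round-trips losslessly; the format is chosen from the
#' file extension.
#'
#' @param cfg a `run_config`.
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) {
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  x$out_dir <- if (is.null(x$out_dir)) NULL else x$out_dir
  do.call(run_config, c(list(preset = "full"), x))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> seed %d: %d participants x %d blocks; %d bootstrap iter\n",
    x$seed, x$n_participants, x$n_blocks, x$n_boot))
  invisible(x)
}
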