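# End-to-end orchestration: simulate -> preprocess -> detect -> analyze ->
# report.  Participants are processed one at a time so only condition-level
# series (not raw traces) are retained.

#' Run the full analysis pipeline on synthetic sessions
#'
#' Simulates `n_participants` sessions, scores the decoy task, runs the
#' pupil, dilation-rate and microsaccade pipelines per participant, and
#' computes the group statistics: sustained REG-RND pupil difference
#' (bootstrap + surrogate noise floor), change-locked pupil / dilation-rate /
#' microsaccade-rate comparisons (CA-NC, CD-NC per regularity), divergence
#' latencies, and Wilcoxon effect sizes over significant time points.
#'
#' @param config a `run_config`.
#' @return a `pipeline_result` list with elements `behavior`, `sustained`,
#'   `change` (per comparison: `bootstrap_result`, effect size, optional
#'   latency distribution), `participants` (per-participant series), and
#'   `manifest`.  If `config$out_dir` is set, artifacts (TSV series, JSON
#'   results, manifest) are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  set.seed(cfg$seed)
  part_seeds <- sample.int(2^31 - 2, cfg$n_participants)
  params <- do.call(synth_params, cfg$generator)
  kernel <- causal_kernel(cfg$kernel_alpha_ms)
  parts <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    sim <- simulate_participant(p, part_seeds[p], params,
                                n_blocks = cfg$n_blocks,
                                blinks = cfg$blinks)
    parts[[p]] <- participant_summary(sim, params, kernel, cfg$ms_lambda)
  }
  res <- group_analysis(parts, cfg)
  res$behavior <- compare_behavior(lapply(parts, `[[`, "behavior"))
  res$manifest <- list(package = "oculoscene",
                       version = as.character(utils::packageVersion(
                         "oculoscene")),
                       seed = cfg$seed, n_participants = cfg$n_participants,
                       n_blocks = cfg$n_blocks)
  res$config <- cfg
  res$participants <- parts
  res <- structure(res, class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_results(res, cfg$out_dir)
  res
}

#' Reduce one simulated participant to condition-level series
#'
#' Runs behavior scoring and the pupil, dilation-rate and microsaccade-rate
#' pipelines over a participant's blocks and keeps only the per-condition
#' time series (plus the NC control epochs needed for the surrogate noise
#' floor).
#'
#' @param sim output of [simulate_participant].
#' @param params the `synth_params` used for simulation (fixation center).
#' @param kernel a `causal_kernel`.
#' @param lambda microsaccade velocity-threshold multiplier.
#' @return list with per-condition mean series (`seq_mean`, `chg_mean`,
#'   `pdr`, `ms` and their time axes), NC epoch matrices, and the
#'   `behavior_summary`.
#' @export
participant_summary <- function(sim, params = synth_params(),
                                kernel = causal_kernel(), lambda = 6) {
  presses <- sim$presses
  seq_ep <- participant_pupil_epochs(sim$blocks, presses, "sequence", params)
  chg_ep <- participant_pupil_epochs(sim$blocks, presses, "change", params)
  pdr <- participant_pdr(sim$blocks, presses, kernel = kernel,
                         params = params)
  msr <- participant_ms_rate(sim$blocks, presses, "change", kernel, lambda,
                             params)
  list(
    id = sim$id,
    behavior = score_behavior(sim$design$trials, presses),
    seq_mean = lapply(seq_ep, function(e) average_condition(e)$mean),
    seq_time = seq_ep[[1]]$time_s,
    seq_nc_epochs = do.call(rbind, lapply(seq_ep, `[[`, "data")),
    chg_mean = lapply(chg_ep, function(e) average_condition(e)$mean),
    chg_time = chg_ep[[1]]$time_s,
    chg_nc_epochs = do.call(rbind,
                            lapply(chg_ep[grep("NC", names(chg_ep))],
                                   `[[`, "data")),
    pdr = lapply(pdr, `[[`, "rate_hz"),
    pdr_time = pdr[[1]]$time_s,
    ms = lapply(msr, `[[`, "rate_hz"),
    ms_time = msr[[1]]$time_s)
}

#' Stack one per-participant condition series into a matrix
#'
#' @param parts list of [participant_summary] outputs.
#' @param field series field (`"seq_mean"`, `"chg_mean"`, `"pdr"`, `"ms"`).
#' @param label condition label.
#' @return participants x time matrix.
#' @export
stack_series <- function(parts, field, label) {
  rows <- lapply(parts, function(pp) pp[[field]][[label]])
  ok <- !vapply(rows, is.null, logical(1))
  do.call(rbind, rows[ok])
}

group_analysis <- function(parts, cfg) {
  out <- list()
  # sustained pupil: REG - RND over NC trials
  seq_time <- parts[[1]]$seq_time
  reg <- stack_series(parts, "seq_mean", "REG")
  rnd <- stack_series(parts, "seq_mean", "RND")
  sus_boot <- bootstrap_difference(reg - rnd, seq_time, cfg$n_boot,
                                   cfg$boot_alpha)
  sus_floor <- NULL
  if (cfg$run_noise_floor)
    sus_floor <- noise_floor(lapply(parts, `[[`, "seq_nc_epochs"), seq_time,
                             cfg$noise_floor_iter, cfg$n_boot,
                             cfg$boot_alpha, cfg$floor_quantile)
  out$sustained <- list(
    bootstrap = sus_boot, floor = sus_floor,
    intervals = significant_intervals(sus_boot, sus_floor, roi_s = NULL),
    effect = effect_over_sig(reg, rnd, sus_boot))
  # change-locked comparisons per measure
  out$change <- list()
  for (meas in c("chg_mean", "pdr", "ms")) {
    tfield <- c(chg_mean = "chg_time", pdr = "pdr_time", ms = "ms_time")[meas]
    time_s <- parts[[1]][[tfield]]
    comps <- list()
    for (rg in c("REG", "RND")) {
      nc <- stack_series(parts, meas, paste0(rg, "-NC"))
      for (ct in c("CA", "CD")) {
        ch <- stack_series(parts, meas, paste0(rg, "-", ct))
        if (is.null(ch) || is.null(nc) || nrow(ch) != nrow(nc)) next
        bt <- bootstrap_difference(ch - nc, time_s, cfg$n_boot,
                                   cfg$boot_alpha)
        comp <- list(bootstrap = bt,
                     intervals = significant_intervals(bt, NULL, cfg$roi_s),
                     effect = effect_over_sig(ch, nc, bt))
        if (cfg$run_latencies && meas == "chg_mean")
          comp$latency <- divergence_latency(ch, nc, time_s,
                                             cfg$latency_iter, cfg$n_boot,
                                             cfg$boot_alpha, min_s = 0)
        comps[[paste0(rg, "-", ct, " vs ", rg, "-NC")]] <- comp
      }
    }
    out$change[[c(chg_mean = "pupil", pdr = "pdr", ms = "ms")[meas]]] <- comps
  }
  out
}

# Wilcoxon effect size from per-participant means over significant points
effect_over_sig <- function(a, b, boot) {
  if (!any(boot$sig_mask)) return(NULL)
  wilcoxon_effect_size(rowMeans(a[, boot$sig_mask, drop = FALSE]),
                       rowMeans(b[, boot$sig_mask, drop = FALSE]))
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # long-format TSV of per-participant condition series
  rows <- list()
  for (pp in res$participants) {
    for (lab in names(pp$seq_mean))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pp$id, analysis = "sequence_pupil", condition = lab,
        time_s = pp$seq_time, value = pp$seq_mean[[lab]])
    for (lab in names(pp$chg_mean))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pp$id, analysis = "change_pupil", condition = lab,
        time_s = pp$chg_time, value = pp$chg_mean[[lab]])
    for (lab in names(pp$ms))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pp$id, analysis = "ms_rate", condition = lab,
        time_s = pp$ms_time, value = pp$ms[[lab]])
  }
  series_path <- file.path(out_dir, "series.tsv")
  utils::write.table(do.call(rbind, rows), series_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  js <- results_json(res)
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- res$manifest
  manifest$checksums <- as.list(tools::md5sum(c(series_path, json_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

results_json <- function(res) {
  boot_js <- function(bt, iv = NULL) {
    x <- list(n_participants = bt$n_participants,
              n_iterations = bt$n_iterations,
              sig_fraction = mean(bt$sig_mask),
              runs = if (is.null(iv)) sig_runs(bt) else iv)
    x
  }
  comp_js <- function(comp) {
    x <- boot_js(comp$bootstrap, comp$intervals)
    if (!is.null(comp$effect)) x$wilcoxon_r <- comp$effect$r
    if (!is.null(comp$latency))
      x$latency <- list(mean_s = comp$latency$mean_s, ci = comp$latency$ci,
                        missing_rate = comp$latency$missing_rate)
    x
  }
  list(
    sustained = c(boot_js(res$sustained$bootstrap, res$sustained$intervals),
                  list(floor_threshold_s =
                         if (is.null(res$sustained$floor)) NULL else
                           res$sustained$floor$threshold_s,
                       wilcoxon_r = if (is.null(res$sustained$effect)) NULL
                       else res$sustained$effect$r)),
    change = lapply(res$change, function(meas) lapply(meas, comp_js)),
    behavior = list(
      hit_rate_reg = mean(res$behavior$hit_rate$reg),
      hit_rate_rnd = mean(res$behavior$hit_rate$rnd),
      median_rt_reg_s = stats::median(res$behavior$rt$reg),
      median_rt_rnd_s = stats::median(res$behavior$rt$rnd)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d participants x %d blocks (seed %d)\n",
              x$config$n_participants, x$config$n_blocks, x$config$seed))
  cat("sustained REG-RND pupil: ")
  print(x$sustained$bootstrap)
  for (meas in names(x$change)) {
    for (nm in names(x$change[[meas]])) {
      iv <- x$change[[meas]][[nm]]$intervals
      cat(sprintf("  %s %s: %d significant run(s)\n", meas, nm, nrow(iv)))
    }
  }
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  print(object)
  invisible(object)
}
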