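# Scaled-down parameter-recovery study shared by the acceptance tests.
# Simulates a cohort with the generator defaults and runs the full pipeline
# chain down to the group statistics.

recovery_cohort <- function(seed, n_participants = 12, n_blocks = 2) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_participants)
  params <- synth_params()
  kernel <- causal_kernel()
  kernel_loc <- causal_kernel(50)    # sharper kernel for latency localization
  parts <- lapply(seq_len(n_participants), function(p) {
    sim <- simulate_participant(p, seeds[p], params, n_blocks = n_blocks)
    out <- participant_summary(sim, params, kernel)
    ms50 <- participant_ms_rate(sim$blocks, sim$presses, "change",
                                kernel_loc, params = params)
    out$ms_loc <- lapply(ms50, `[[`, "rate_hz")
    out$ms_loc_time <- ms50[[1]]$time_s
    out
  })
  list(parts = parts, params = params)
}

# Trough latency of the group-mean change-locked microsaccade rate, pooled
# over all change trials (CA and CD, both regularities; the inhibition is
# change-locked in each).  Uses the sharper localization kernel.
msi_trough_latency <- function(parts) {
  ms_time <- parts[[1]]$ms_loc_time
  chg <- do.call(rbind, lapply(c("REG-CA", "RND-CA", "REG-CD", "RND-CD"),
                               function(lab)
                                 stack_series(parts, "ms_loc", lab)))
  g <- colMeans(chg)
  win <- ms_time >= 0 & ms_time <= 0.5
  ms_time[win][which.min(g[win])]
}

tonic_divergence_onset <- function(parts, n_boot = 1000, floor_iter = 100) {
  seq_time <- parts[[1]]$seq_time
  reg <- stack_series(parts, "seq_mean", "REG")
  rnd <- stack_series(parts, "seq_mean", "RND")
  bt <- bootstrap_difference(reg - rnd, seq_time, n_boot)
  fl <- noise_floor(lapply(parts, `[[`, "seq_nc_epochs"), seq_time,
                    n_iter = floor_iter, n_boot = n_boot)
  list(onset_s = first_sig_time(bt, min_s = 0, floor = fl),
       bootstrap = bt, floor = fl,
       late_diff = mean((colMeans(reg) - colMeans(rnd))[seq_time >= 6]))
}

pd_change_latencies <- function(parts, n_iter = 500, n_boot = 1000) {
  chg_time <- parts[[1]]$chg_time
  nc <- (stack_series(parts, "chg_mean", "REG-NC") +
           stack_series(parts, "chg_mean", "RND-NC")) / 2
  out <- list()
  for (ct in c("CA", "CD")) {
    ch <- (stack_series(parts, "chg_mean", paste0("REG-", ct)) +
             stack_series(parts, "chg_mean", paste0("RND-", ct))) / 2
    out[[ct]] <- divergence_latency(ch, nc, chg_time, n_iter = n_iter,
                                    n_boot = n_boot, min_s = 0,
                                    min_run_s = 0.3)
  }
  out
}

# One synthetic null study for statistical calibration, mirroring the real
# analysis structure: per participant, two null "conditions" of n_trials
# smoothed-noise epochs each; the observed comparison contrasts their means,
# while the noise floor is built from surrogate half-splits of the control
# condition (so the floor is the conservative, lower-trial-count side, as in
# the real procedure).
null_robust_flag <- function(P = 12, n_trials = 8,
                             time_s = seq(0, 2.5, by = 0.01),
                             n_boot = 1000, floor_iter = 100) {
  T_ <- length(time_s)
  fs <- 1 / (time_s[2] - time_s[1])
  mk_cond <- function() t(replicate(n_trials,
                                    hann_smooth(rnorm(T_), 150, fs) +
                                      rnorm(1, 0, 0.05)))
  cond_a <- lapply(seq_len(P), function(i) mk_cond())
  control <- lapply(seq_len(P), function(i) mk_cond())
  diffs <- t(vapply(seq_len(P), function(i)
    colMeans(cond_a[[i]]) - colMeans(control[[i]]), numeric(T_)))
  bt <- bootstrap_difference(diffs, time_s, n_boot)
  fl <- noise_floor(control, time_s, n_iter = floor_iter, n_boot = n_boot)
  longest_sig_run_s(bt) > fl$threshold_s
}
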