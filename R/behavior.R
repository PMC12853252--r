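# Decoy gap-detection task scoring.

#' Score gap-detection behavior
#'
#' Key presses within 2 s (strictly) after a target gap onset are hits; the
#' reaction time of a hit is measured from gap onset.  Any other press is a
#' false alarm.  Trials containing any press are flagged for exclusion from
#' ocular analyses.  Hit rate and reaction time are compared between REG and
#' RND decoys with a paired Wilcoxon signed-rank test at the group stage
#' ([compare_behavior]).
#'
#' @param trials session trial table (`build_session()$trials`).
#' @param presses press table with `block`, `trial`, `press_s`
#'   (scene-relative seconds).
#' @param hit_window_s hit window after gap onset (s, strict upper bound).
#' @return a `behavior_summary`: list with `by_condition` (data frame:
#'   regularity, n_gap, hits, hit_rate, median_rt_s), `n_false_alarms`,
#'   `fa_times_s` (within-trial false-alarm times), `pressed_trials`
#'   (data frame of block/trial to exclude).
#' @export
score_behavior <- function(trials, presses, hit_window_s = 2) {
  key <- paste(trials$block, trials$trial)
  hits <- logical(nrow(trials))
  rts <- rep(NA_real_, nrow(trials))
  fa_times <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    pr <- presses$press_s[paste(presses$block, presses$trial) == key[i]]
    if (!length(pr)) next
    gap <- trials$gap_start_s[i]
    if (is.finite(gap)) {
      dt <- pr - gap
      ok <- dt > 0 & dt < hit_window_s
      if (any(ok)) {
        hits[i] <- TRUE
        rts[i] <- min(dt[ok])
      }
      fa_times <- c(fa_times, pr[!ok])
    } else {
      fa_times <- c(fa_times, pr)
    }
  }
  gap_trials <- is.finite(trials$gap_start_s)
  by_cond <- do.call(rbind, lapply(unique(trials$regularity), function(rg) {
    sel <- gap_trials & trials$regularity == rg
    data.frame(regularity = rg, n_gap = sum(sel), hits = sum(hits[sel]),
               hit_rate = if (any(sel)) mean(hits[sel]) else NA_real_,
               median_rt_s = stats::median(rts[sel], na.rm = TRUE))
  }))
  pressed <- unique(presses[, c("block", "trial")])
  structure(list(by_condition = by_cond,
                 n_false_alarms = length(fa_times),
                 fa_times_s = fa_times,
                 pressed_trials = pressed,
                 hits = hits, rts = rts),
            class = "behavior_summary")
}

#' Group comparison of decoy performance between REG and RND
#'
#' Paired Wilcoxon signed-rank tests on hit rate and median reaction time
#' across participants.
#'
#' @param summaries list of `behavior_summary` (one per participant).
#' @return list with `hit_rate` and `rt`, each carrying the paired values
#'   and the `wilcox.test` result.
#' @export
compare_behavior <- function(summaries) {
  get <- function(s, rg, col) {
    b <- s$by_condition
    b[b$regularity == rg, col]
  }
  hr_reg <- vapply(summaries, get, numeric(1), rg = "REG", col = "hit_rate")
  hr_rnd <- vapply(summaries, get, numeric(1), rg = "RND", col = "hit_rate")
  rt_reg <- vapply(summaries, get, numeric(1), rg = "REG",
                   col = "median_rt_s")
  rt_rnd <- vapply(summaries, get, numeric(1), rg = "RND",
                   col = "median_rt_s")
  safe_test <- function(x, y) {
    if (all(x == y)) return(NULL)
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
  }
  list(hit_rate = list(reg = hr_reg, rnd = hr_rnd,
                       test = safe_test(hr_reg, hr_rnd)),
       rt = list(reg = rt_reg, rnd = rt_rnd,
                 test = safe_test(rt_reg, rt_rnd)))
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> %d false alarms\n", x$n_false_alarms))
  print(x$by_condition, row.names = FALSE)
  invisible(x)
}
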