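# Bootstrap time-point statistics for condition-difference time series:
# participant resampling with sign-consistency significance, a
# surrogate-split noise floor for robustness, resampled divergence
# latencies, and Wilcoxon effect sizes.

#' Bootstrap significance of a condition-difference time course
#'
#' Resamples participants with replacement (`n_iter` iterations) and averages
#' the per-participant difference series.  A time point is significant when
#' the iteration means fall consistently above or below zero:
#' `max(frac > 0, frac < 0) > 1 - alpha`, i.e. more than 95% of iterations
#' on one side of zero at the default `alpha = 0.05`.
#'
#' @param diffs participants x time matrix of difference series.
#' @param time_s time axis (s).
#' @param n_iter bootstrap iterations.
#' @param alpha consistency criterion: significant when the common-sign
#'   fraction exceeds `1 - alpha`.
#' @return a `bootstrap_result`: list with `time_s`, `diff_mean`, `sig_mask`,
#'   `prop_consistent`, `n_iterations`, `n_participants`.
#' @export
bootstrap_difference <- function(diffs, time_s = NULL, n_iter = 1000,
                                 alpha = 0.05) {
  stopifnot(is.matrix(diffs))
  P <- nrow(diffs)
  if (P < 2) stop("bootstrap needs at least 2 participants")
  if (is.null(time_s)) time_s <- seq_len(ncol(diffs))
  idx <- matrix(sample.int(P, P * n_iter, replace = TRUE), nrow = P)
  # iteration means via resampling-weight matrix multiplication
  W <- matrix(0, P, n_iter)
  for (it in seq_len(n_iter)) {
    tb <- tabulate(idx[, it], nbins = P)
    W[, it] <- tb / P
  }
  M <- crossprod(W, diffs)                       # n_iter x T
  pos <- colMeans(M > 0)
  neg <- colMeans(M < 0)
  prop <- pmax(pos, neg)
  structure(list(time_s = time_s, diff_mean = colMeans(diffs),
                 sig_mask = prop > 1 - alpha, prop_consistent = prop,
                 n_iterations = n_iter, n_participants = P),
            class = "bootstrap_result")
}

#' Significant runs of a bootstrap result
#'
#' `sig_runs()` lists the contiguous significant intervals;
#' `longest_sig_run_s()` returns the longest one (0 when none).
#'
#' @param boot a `bootstrap_result`.
#' @return data frame with `start_s`, `end_s`, `length_s`; or a scalar.
#' @export
sig_runs <- function(boot) {
  rr <- runs_of(boot$sig_mask)
  if (!nrow(rr))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      length_s = numeric(0)))
  dt <- stats::median(diff(boot$time_s))
  data.frame(start_s = boot$time_s[rr[, 1]], end_s = boot$time_s[rr[, 2]],
             length_s = (rr[, 2] - rr[, 1] + 1) * dt)
}

#' @rdname sig_runs
#' @export
longest_sig_run_s <- function(boot) {
  r <- sig_runs(boot)
  if (!nrow(r)) 0 else max(r$length_s)
}

#' First significant time of a bootstrap result
#'
#' Returns the start of the first significant run beginning at or after
#' `min_s`.  With `min_run_s > 0`, isolated significant samples (spurious
#' flickers at the smoothing scale) are ignored and only runs of at least
#' that duration count; with a `noise_floor`, only runs outlasting the floor
#' threshold count.
#'
#' @param boot a `bootstrap_result`.
#' @param min_s earliest admissible time (s).
#' @param min_run_s minimal run duration (s) for a run to count.
#' @param floor optional `noise_floor`; runs must exceed its threshold.
#' @return time in seconds, or `NA` if no qualifying run exists.
#' @export
first_sig_time <- function(boot, min_s = -Inf, min_run_s = 0, floor = NULL) {
  r <- sig_runs(boot)
  if (!is.null(floor)) r <- r[r$length_s > floor$threshold_s, , drop = FALSE]
  # a run straddling min_s counts from min_s onward
  r <- r[r$length_s >= min_run_s & r$end_s >= min_s, , drop = FALSE]
  if (!nrow(r)) NA_real_ else max(r$start_s[1], min_s)
}

#' Surrogate-split noise floor
#'
#' In each iteration, every participant's control-condition trials are
#' randomly split into two surrogate halves (odd counts: the larger half on
#' a random side); the two surrogate condition means are compared with
#' [bootstrap_difference], and the longest spuriously significant interval is
#' recorded.  The distribution of these longest runs defines the noise
#' floor; observed effects whose significant runs exceed its `quantile` are
#' "robust".
#'
#' @param control_epochs list (one element per participant) of trials x time
#'   matrices of control-condition epochs.
#' @param time_s time axis (s).
#' @param n_iter surrogate iterations.
#' @param n_boot inner bootstrap iterations.
#' @param alpha inner consistency criterion.
#' @param quantile decision quantile of the longest-run distribution.
#' @return a `noise_floor`: list with `longest_run_distribution_s`,
#'   `threshold_s`, `quantile`, `n_iter`.
#' @export
noise_floor <- function(control_epochs, time_s = NULL, n_iter = 100,
                        n_boot = 1000, alpha = 0.05, quantile = 0.95) {
  P <- length(control_epochs)
  runs <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    diffs <- matrix(NA_real_, P, ncol(control_epochs[[1]]))
    for (p in seq_len(P)) {
      ep <- control_epochs[[p]]
      n <- nrow(ep)
      n_a <- if (n %% 2 == 0) n / 2 else
        (n %/% 2) + stats::rbinom(1, 1, 0.5)
      a <- sample.int(n, n_a)
      diffs[p, ] <- colMeans(ep[a, , drop = FALSE]) -
        colMeans(ep[-a, , drop = FALSE])
    }
    bt <- bootstrap_difference(diffs, time_s, n_iter = n_boot, alpha = alpha)
    runs[it] <- longest_sig_run_s(bt)
  }
  structure(list(longest_run_distribution_s = runs,
                 threshold_s = stats::quantile(runs, quantile, names = FALSE),
                 quantile = quantile, n_iter = n_iter),
            class = "noise_floor")
}

#' Label significant intervals against the noise floor and an ROI
#'
#' Flags each significant run of a `bootstrap_result` as robust when it
#' outlasts the noise-floor threshold, and (for change-locked analyses) tags
#' runs outside the 100-250 ms post-change region of interest as
#' exploratory.  No false-discovery-rate correction is applied.
#'
#' @param boot a `bootstrap_result`.
#' @param floor a `noise_floor`, or `NULL` to skip the robustness flag.
#' @param roi_s region of interest `c(start, end)` in s, or `NULL` to skip
#'   the exploratory label.
#' @return data frame of runs with `start_s`, `end_s`, `length_s`, `robust`,
#'   `exploratory`.
#' @export
significant_intervals <- function(boot, floor = NULL,
                                  roi_s = c(0.1, 0.25)) {
  r <- sig_runs(boot)
  r$robust <- if (is.null(floor)) NA else r$length_s > floor$threshold_s
  r$exploratory <- if (is.null(roi_s)) NA else
    !(r$start_s <= roi_s[2] & r$end_s >= roi_s[1])
  r
}

#' Resampled divergence-latency distribution
#'
#' In each of `n_iter` iterations, participants are resampled with
#' replacement, the bootstrap significance procedure is run on the resampled
#' difference series, and the first significant time at or after `min_s` is
#' recorded (missing when no point is significant).
#'
#' @param series_a,series_b participants x time matrices for the two
#'   conditions (same participants, same time axis).
#' @param time_s time axis (s).
#' @param n_iter outer resampling iterations.
#' @param n_boot inner bootstrap iterations.
#' @param alpha inner consistency criterion.
#' @param min_s earliest admissible latency (s).
#' @param min_run_s minimal significant-run duration for a latency to count
#'   (0 reproduces the plain first-significant-sample rule).
#' @param ci percentile CI coverage.
#' @return a `latency_distribution`: list with `latencies_s` (NA when an
#'   iteration had no significant point), `mean_s`, `ci`, `sd_s`,
#'   `missing_rate`.
#' @export
divergence_latency <- function(series_a, series_b, time_s = NULL,
                               n_iter = 500, n_boot = 1000, alpha = 0.05,
                               min_s = 0, min_run_s = 0, ci = 0.95) {
  stopifnot(all(dim(series_a) == dim(series_b)))
  P <- nrow(series_a)
  diffs <- series_a - series_b
  lat <- rep(NA_real_, n_iter)
  for (it in seq_len(n_iter)) {
    rs <- sample.int(P, P, replace = TRUE)
    bt <- bootstrap_difference(diffs[rs, , drop = FALSE], time_s,
                               n_iter = n_boot, alpha = alpha)
    lat[it] <- first_sig_time(bt, min_s, min_run_s)
  }
  ok <- lat[!is.na(lat)]
  qs <- if (length(ok)) stats::quantile(ok, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                                        names = FALSE) else c(NA, NA)
  structure(list(latencies_s = lat,
                 mean_s = if (length(ok)) mean(ok) else NA_real_,
                 ci = qs, sd_s = if (length(ok) > 1) stats::sd(ok) else NA,
                 missing_rate = mean(is.na(lat))),
            class = "latency_distribution")
}

#' Wilcoxon signed-rank effect size r
#'
#' Paired signed-rank test on `a - b`; the standardized statistic Z (exact
#' for 20 or fewer untied nonzero pairs, normal approximation with tie
#' correction otherwise) gives `r = |Z| / sqrt(N)` with N the number of
#' nonzero pairs.
#'
#' @param a,b paired per-participant scores.
#' @return list with `r`, `z`, `v` (signed-rank statistic), `n`, `p`.
#' @export
wilcoxon_effect_size <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(r = 0, z = 0, v = NA_real_, n = 0L, p = 1))
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (n <= 20 && !any(duplicated(abs(d)))) {
    p <- stats::wilcox.test(a[a - b != 0], b[a - b != 0], paired = TRUE,
                            exact = TRUE)$p.value
    z <- sign(v - mu) * stats::qnorm(1 - min(1, p) / 2)
  } else {
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(r = abs(z) / sqrt(n), z = z, v = v, n = n, p = p)
}

#' Pointwise and windowed RT-pupil correlation across participants
#'
#' Product-moment correlation between a per-participant scalar (e.g. the
#' RND - REG reaction-time difference) and a per-participant time series
#' (e.g. the sustained RND - REG pupil difference) at each time point, plus
#' the correlation with the series averaged over `window_s`.
#'
#' @param scalar per-participant values (length P).
#' @param series participants x time matrix.
#' @param time_s time axis (s).
#' @param window_s averaging window for the windowed correlation.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `time_s`, `r`, `p` (pointwise), and `windowed`
#'   (`r`, `p`, `window_s`).
#' @export
rt_pd_correlation <- function(scalar, series, time_s,
                              window_s = c(6, 10),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  P <- length(scalar)
  if (P < 3) stop("need at least 3 participants")
  stopifnot(nrow(series) == P)
  if (method == "spearman") {
    scalar <- rank(scalar)
    series <- apply(series, 2, rank)
  }
  x <- scalar - mean(scalar)
  Y <- sweep(series, 2, colMeans(series))
  r <- as.numeric(crossprod(x, Y)) /
    (sqrt(sum(x^2)) * sqrt(colSums(Y^2)))
  r[!is.finite(r)] <- NA
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((P - 2) / (1 - r^2)),
                            df = P - 2))
  win <- time_s >= window_s[1] & time_s <= window_s[2]
  wmean <- rowMeans(series[, win, drop = FALSE])
  wt <- stats::cor.test(scalar, wmean,
                        method = if (method == "spearman") "pearson" else
                          method)
  list(time_s = time_s, r = r, p = p,
       windowed = list(r = unname(wt$estimate), p = wt$p.value,
                       window_s = window_s))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  r <- sig_runs(x)
  cat(sprintf(
    "<bootstrap_result> %d participants, %d iterations, %d significant run(s)\n",
    x$n_participants, x$n_iterations, nrow(r)))
  if (nrow(r)) print(r)
  invisible(x)
}

#' @export
plot.bootstrap_result <- function(x, ...) {
  graphics::plot(x$time_s, x$diff_mean, type = "l", xlab = "time (s)",
                 ylab = "condition difference", ...)
  graphics::abline(h = 0, lty = 3)
  if (any(x$sig_mask)) {
    ylo <- min(x$diff_mean)
    graphics::points(x$time_s[x$sig_mask],
                     rep(ylo, sum(x$sig_mask)), pch = 15, cex = 0.4)
  }
  invisible(x)
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf(
    "<noise_floor> %d surrogate iterations; %g-quantile threshold %.3f s\n",
    x$n_iter, x$quantile, x$threshold_s))
  invisible(x)
}

#' @export
print.latency_distribution <- function(x, ...) {
  cat(sprintf(
    "<latency_distribution> mean %.3f s, CI [%.3f, %.3f] s, missing %.1f%%\n",
    x$mean_s, x$ci[1], x$ci[2], 100 * x$missing_rate))
  invisible(x)
}
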