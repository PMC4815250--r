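#' Block-level closed-loop performance metrics
#'
#' TPR is the fraction of attempted trials whose intent was correctly
#' detected within the block; FPR the fraction of catch trials incorrectly
#' detected. Responsiveness is summarized as intents per minute,
#' `60 / (seconds from trial start to accepted detection)`, computed only
#' over correctly detected attempted trials, with its coefficient of
#' variation (sample SD / mean). Latency is detection time minus kinematic
#' movement onset; negative values mean the intent preceded movement.
#'
#' @param outcomes `trial_outcomes` rows from one block (or any subset).
#' @return object of class `block_metrics`: `tpr_pct`, `fpr_pct`,
#'   `intents_per_min`, `cov`, `latencies_s`, `n_attempted`, `n_catch`,
#'   `n_detected`.
#' @export
block_metrics <- function(outcomes) {
  att <- outcomes[!outcomes$is_catch, , drop = FALSE]
  cat_ <- outcomes[outcomes$is_catch, , drop = FALSE]
  detected <- att[!is.na(att$final_detection_time_s), , drop = FALSE]
  ipm <- 60 / detected$detect_delay_s
  cov <- if (length(ipm) >= 2 && mean(ipm) > 0) stats::sd(ipm) / mean(ipm)
         else NA_real_
  structure(list(
    tpr_pct = if (nrow(att)) 100 * nrow(detected) / nrow(att) else NA_real_,
    fpr_pct = if (nrow(cat_))
      100 * sum(!is.na(cat_$final_detection_time_s)) / nrow(cat_)
      else NA_real_,
    intents_per_min = ipm, cov = cov,
    latencies_s = detected$latency_s[!is.na(detected$latency_s)],
    n_attempted = nrow(att), n_catch = nrow(cat_),
    n_detected = nrow(detected)), class = "block_metrics")
}

#' @export
print.block_metrics <- function(x, ...) {
  cat(sprintf("<block_metrics> TPR %.1f%% (%d/%d), FPR %s, intents/min %s, CoV %s\n",
              x$tpr_pct, x$n_detected, x$n_attempted,
              if (is.na(x$fpr_pct)) "n/a" else sprintf("%.1f%%", x$fpr_pct),
              if (length(x$intents_per_min))
                sprintf("%.1f", stats::median(x$intents_per_min)) else "n/a",
              if (is.na(x$cov)) "n/a" else sprintf("%.2f", x$cov)))
  invisible(x)
}

#' Kinematic movement onset by velocity threshold
#'
#' First sample at which the joint velocity exceeds the threshold.
#'
#' @param velocity velocity series, deg/s.
#' @param fs sampling rate, Hz.
#' @param threshold threshold in deg/s (> 0).
#' @param t_offset time of the first sample, seconds (for sub-series).
#' @return onset time in seconds, or NA when no crossing occurs.
#' @export
movement_onset_from_kinematics <- function(velocity, fs, threshold,
                                           t_offset = 0) {
  if (threshold <= 0) stop("threshold must be positive")
  i <- which(velocity > threshold)
  if (!length(i)) return(NA_real_)
  t_offset + (i[1] - 1) / fs
}

#' Velocity threshold from practice trials
#'
#' The per-subject threshold is 5% of the mean peak velocity over practice
#' trials.
#'
#' @param peak_velocities peak velocity of each practice trial, deg/s.
#' @return threshold in deg/s.
#' @export
practice_velocity_threshold <- function(peak_velocities) {
  0.05 * mean(peak_velocities)
}

#' Compare a metric between two days (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test (exact for small samples without ties, normal
#' approximation otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param metrics_a,metrics_b numeric samples (e.g., block-wise TPR).
#' @return list with `p_value` and `statistic`.
#' @export
compare_days <- function(metrics_a, metrics_b) {
  if (length(metrics_a) < 2 || length(metrics_b) < 2)
    stop("need >= 2 observations per group")
  w <- suppressWarnings(stats::wilcox.test(metrics_a, metrics_b,
                                           alternative = "two.sided"))
  list(p_value = w$p.value, statistic = unname(w$statistic))
}

#' Linear trend of a metric across blocks
#'
#' Ordinary least-squares regression of the metric on the block index.
#'
#' @param metric numeric vector (one value per block).
#' @param block_index block indices; default `seq_along(metric)`.
#' @return list with `slope` and `p_value` (NA when degenerate).
#' @export
trend_slope <- function(metric, block_index = seq_along(metric)) {
  if (length(metric) < 3) stop("need >= 3 blocks for a trend")
  fit <- stats::lm(metric ~ block_index)
  co <- summary(fit)$coefficients
  if (nrow(co) < 2) return(list(slope = 0, p_value = NA_real_))
  list(slope = unname(co[2, 1]), p_value = unname(co[2, 4]))
}
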