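#' Online (closed-loop) decision configuration
#'
#' @param tau_c probability threshold the prediction must exceed.
#' @param n_c consecutive supra-threshold windows required before the BMI
#'   fires an intent (per-subject tuned values of 2-6 are typical).
#' @param tick_s prediction period, 0.05 s.
#' @param emg_thresh_mv named per-muscle RMS thresholds (mV).
#' @param gate_timeout_s EMG confirmation window after an intent, 1 s.
#' @param trial_timeout_s trial budget, 15 s.
#' @param vel_thresh_dps joint-velocity threshold defining kinematic
#'   movement onset (deg/s); see [practice_velocity_threshold()].
#' @return object of class `online_config`.
#' @export
online_config <- function(tau_c = 0.5, n_c = 3, tick_s = 0.05,
                          emg_thresh_mv = c(biceps = 8, triceps = 8),
                          gate_timeout_s = 1, trial_timeout_s = 15,
                          vel_thresh_dps = 2) {
  if (tau_c <= 0 || tau_c >= 1) stop("tau_c must lie in (0, 1)")
  if (n_c < 1) stop("n_c must be >= 1")
  if (any(emg_thresh_mv <= 0)) stop("EMG thresholds must be positive")
  structure(list(tau_c = tau_c, n_c = n_c, tick_s = tick_s,
                 emg_thresh_mv = emg_thresh_mv, gate_timeout_s = gate_timeout_s,
                 trial_timeout_s = trial_timeout_s,
                 vel_thresh_dps = vel_thresh_dps), class = "online_config")
}

#' Causal sliding-window predictions over a whole session
#'
#' Streams the session through the causal preprocessing chain, computes the
#' spatial average of the model's channels at 20 Hz, and scores the
#' trailing `wl_O`-length window every 50 ms with the calibrated SVC.
#' Because every stage is causal and state-carrying, the result is
#' bit-identical whether the recording is processed whole or chunk by chunk.
#'
#' @param session a `raw_session` at the native rate.
#' @param model a `calibrated_model`.
#' @param cfg an [online_config()].
#' @param montage montage for the Laplacian.
#' @return data.frame with `time_s`, `prob`, `supra` (one row per tick for
#'   which a full window exists; empty when the session is shorter than
#'   `wl_O`).
#' @export
stream_predict <- function(session, model, cfg = online_config(),
                           montage = standard_montage()) {
  missing_ch <- setdiff(model$channels, session$eeg_labels)
  if (length(missing_ch))
    stop("session lacks model channel(s): ", paste(missing_ch, collapse = ", "))
  filt <- filter_chain(session, montage)
  fs <- filt$fs_eeg
  trace <- spatial_average(filt$eeg, model$channels)
  n_w <- round(model$wl_s * fs) + 1
  step <- max(1L, round(cfg$tick_s * fs))
  if (length(trace) < n_w)
    return(data.frame(time_s = numeric(), prob = numeric(), supra = logical()))
  sw <- sliding_windows(trace, n_w, step)
  fx <- extract_features(sw$W, model$go_stats, dt = 1 / fs)
  pr <- svc_prob(model$svm, scale_apply(fx, model$scaling))
  data.frame(time_s = (sw$edges - 1) / fs, prob = pr, supra = pr >= cfg$tau_c)
}

#' Consecutive-window intent rule
#'
#' An intent fires at the `n_c`-th consecutive supra-threshold tick; the
#' counter then resets fully, so a sustained supra-threshold run cannot
#' re-fire immediately.
#'
#' @param pred data.frame from [stream_predict()] (or any frame with
#'   `time_s` and `supra`).
#' @param cfg an [online_config()].
#' @return data.frame of intent events with `time_s` and `tick` (row index).
#' @export
intent_rule <- function(pred, cfg = online_config()) {
  run <- 0L
  hits <- integer(0)
  for (j in seq_len(nrow(pred))) {
    run <- if (pred$supra[j]) run + 1L else 0L
    if (run == cfg$n_c) {
      hits <- c(hits, j)
      run <- 0L
    }
  }
  data.frame(tick = hits, time_s = pred$time_s[hits])
}

#' EMG gate: confirm a BMI intent with muscle activity
#'
#' Accepts the intent iff either muscle's trailing-RMS envelope exceeds its
#' threshold at any tick within `(t, t + gate_timeout_s]`.
#'
#' @param intent_time_s time of the BMI intent, seconds.
#' @param envelopes result of [condition_emg()].
#' @param cfg an [online_config()].
#' @return list with `accept` and `gate_time_s` (first crossing, or NA).
#' @export
emg_gate <- function(intent_time_s, envelopes, cfg = online_config()) {
  idx <- which(envelopes$time_s > intent_time_s &
               envelopes$time_s <= intent_time_s + cfg$gate_timeout_s)
  if (!length(idx)) return(list(accept = FALSE, gate_time_s = NA_real_))
  thr <- cfg$emg_thresh_mv[envelopes$muscles]
  over <- sweep(envelopes$envelope[, idx, drop = FALSE], 1, thr, ">")
  any_over <- apply(over, 2, any)
  if (!any(any_over)) return(list(accept = FALSE, gate_time_s = NA_real_))
  list(accept = TRUE, gate_time_s = envelopes$time_s[idx[which(any_over)[1]]])
}

#' Replay a session block through the closed-loop decision logic
#'
#' For each trial (target onset to target onset + 15 s) the BMI prediction
#' stream is scanned with the tau_c/N_c rule, every intent is checked
#' against the EMG gate, and the first accepted intent ends the trial.
#' Catch-trial acceptances are false positives. Intents during fixation
#' intervals are logged (attribute `fixation_intents`) but never trigger
#' movement and do not enter block metrics. Detection latency is measured
#' against the kinematic movement onset (velocity-threshold crossing);
#' negative latency means intent preceded movement.
#'
#' @param session a `raw_session` with EMG and kinematics.
#' @param model a `calibrated_model`.
#' @param cfg an [online_config()].
#' @param blocks optional block ids to replay (default: all).
#' @param montage montage for the Laplacian.
#' @param gate logical: apply the EMG gate (TRUE), or accept BMI intents
#'   outright (`FALSE`, the BMI-only condition used for bound checks).
#' @return data.frame of per-trial outcomes (class `trial_outcomes`):
#'   `trial_id`, `block`, `is_catch`, `bmi_intent_time_s`,
#'   `emg_gate_passed`, `final_detection_time_s`, `detect_delay_s` (from
#'   trial start), `latency_s`, `timed_out`.
#' @export
run_block <- function(session, model, cfg = online_config(), blocks = NULL,
                      montage = standard_montage(), gate = TRUE) {
  pred <- stream_predict(session, model, cfg, montage)
  env <- condition_emg(session, tick_s = cfg$tick_s)
  fs <- session$fs_eeg

  ev <- session$events
  starts <- ev[ev$kind %in% c("target_onset", "catch_target_onset"), ,
               drop = FALSE]
  if (!is.null(blocks)) starts <- starts[starts$block %in% blocks, , drop = FALSE]

  out <- list()
  trial_windows <- cbind((starts$sample - 1) / fs,
                         (starts$sample - 1) / fs + cfg$trial_timeout_s)
  for (r in seq_len(nrow(starts))) {
    t_on <- trial_windows[r, 1]
    t_end <- trial_windows[r, 2]
    is_catch <- starts$kind[r] == "catch_target_onset"
    in_trial <- pred$time_s >= t_on & pred$time_s <= t_end

    bmi_t <- NA_real_
    gate_ok <- NA
    final_t <- NA_real_
    intents <- intent_rule(pred[in_trial, , drop = FALSE], cfg)
    for (k in seq_len(nrow(intents))) {
      g <- if (gate) emg_gate(intents$time_s[k], env, cfg)
           else list(accept = TRUE, gate_time_s = intents$time_s[k])
      if (g$accept && g$gate_time_s > t_end)
        g <- list(accept = FALSE, gate_time_s = NA_real_) # past trial budget
      if (is.na(bmi_t)) bmi_t <- intents$time_s[k]
      if (g$accept) {
        bmi_t <- intents$time_s[k]
        gate_ok <- TRUE
        final_t <- g$gate_time_s
        break
      }
      gate_ok <- FALSE
    }

    lat <- lat_gated <- NA_real_
    if (!is_catch && !is.na(final_t)) {
      kin_on <- kinematic_onset_in(session, t_on, t_end, cfg$vel_thresh_dps)
      if (!is.na(kin_on)) {
        lat <- bmi_t - kin_on       # intent-based (the BMI decision)
        lat_gated <- final_t - kin_on # after EMG confirmation
      }
    }
    out[[r]] <- data.frame(
      trial_id = starts$trial_id[r], block = starts$block[r],
      is_catch = is_catch, bmi_intent_time_s = bmi_t,
      emg_gate_passed = gate_ok, final_detection_time_s = final_t,
      detect_delay_s = if (is.na(final_t)) NA_real_ else final_t - t_on,
      latency_s = lat, latency_gated_s = lat_gated,
      timed_out = is.na(final_t))
  }
  res <- do.call(rbind, out)

  # intents outside every trial window: fixation / inter-trial, logged only
  in_any <- rep(FALSE, nrow(pred))
  for (r in seq_len(nrow(starts)))
    in_any <- in_any | (pred$time_s >= trial_windows[r, 1] &
                        pred$time_s <= trial_windows[r, 2])
  fix_int <- intent_rule(pred[!in_any, , drop = FALSE], cfg)
  fix_int$gate_accepted <- vapply(fix_int$time_s, function(t)
    emg_gate(t, env, cfg)$accept, FALSE)
  attr(res, "fixation_intents") <- fix_int
  class(res) <- c("trial_outcomes", class(res))
  res
}

kinematic_onset_in <- function(session, t0, t1, thresh) {
  if (is.null(session$kin)) return(NA_real_)
  fs <- session$kin$fs
  i0 <- max(1, floor(t0 * fs) + 1)
  i1 <- min(length(session$kin$velocity), floor(t1 * fs) + 1)
  seg <- session$kin$velocity[i0:i1]
  movement_onset_from_kinematics(seg, fs, thresh, t_offset = (i0 - 1) / fs)
}

#' Sweep tau_c / N_c on a held-out block
#'
#' Grid sweep of the online decision parameters maximizing TPR - FPR on a
#' (synthetic) tuning session, mirroring the empirical day-3 tuning step.
#' Ties prefer larger tau_c then larger N_c (the more conservative rule).
#'
#' @param session tuning session.
#' @param model calibrated model.
#' @param cfg base config (EMG thresholds etc.).
#' @param tau_grid,n_grid candidate values.
#' @return list with `tau_c`, `n_c`, `table`.
#' @export
tune_online_params <- function(session, model, cfg = online_config(),
                               tau_grid = seq(0.4, 0.8, by = 0.1),
                               n_grid = 2:5) {
  tab <- expand.grid(tau_c = tau_grid, n_c = n_grid)
  tab$tpr <- NA_real_
  tab$fpr <- NA_real_
  for (r in seq_len(nrow(tab))) {
    c2 <- cfg
    c2$tau_c <- tab$tau_c[r]
    c2$n_c <- tab$n_c[r]
    m <- block_metrics(run_block(session, model, c2))
    tab$tpr[r] <- m$tpr_pct
    tab$fpr[r] <- if (is.na(m$fpr_pct)) 0 else m$fpr_pct
  }
  score <- tab$tpr - tab$fpr
  ord <- order(-score, -tab$tau_c, -tab$n_c)
  list(tau_c = tab$tau_c[ord[1]], n_c = tab$n_c[ord[1]], table = tab)
}
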