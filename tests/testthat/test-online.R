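# Closed-loop replay: intent rule, EMG gate, block outcomes, determinism.

test_that("the consecutive-window intent rule counts correctly", {
  cfg <- online_config(tau_c = 0.7, n_c = 3)
  mk <- function(p) data.frame(time_s = seq_along(p) * 0.05, prob = p,
                               supra = p >= cfg$tau_c)
  # {0.6, 0.8, 0.8, 0.9}: intent at tick 4
  expect_equal(intent_rule(mk(c(0.6, 0.8, 0.8, 0.9)), cfg)$tick, 4)
  # {0.8, 0.6, 0.8, 0.8}: broken run, no intent
  expect_equal(nrow(intent_rule(mk(c(0.8, 0.6, 0.8, 0.8)), cfg)), 0)
  # n_c = 1 fires at the first supra-threshold tick
  cfg1 <- online_config(tau_c = 0.7, n_c = 1)
  expect_equal(intent_rule(mk(c(0.2, 0.9, 0.9)), cfg1)$tick, c(2, 3))
  # counter resets after firing: 6 consecutive = exactly 2 intents at n_c 3
  expect_equal(intent_rule(mk(rep(0.9, 6)), cfg)$tick, c(3, 6))
})

test_that("the EMG gate honors the 1 s timer and the either-muscle rule", {
  tick <- seq(0.05, 10, by = 0.05)
  mkenv <- function(bic, tri) list(envelope = rbind(biceps = bic,
                                                    triceps = tri),
                                   time_s = tick,
                                   muscles = c("biceps", "triceps"))
  cfg <- online_config(emg_thresh_mv = c(biceps = 5, triceps = 5))
  # biceps crosses at 3.4 s after an intent at 3.0 s: accept
  bic <- ifelse(tick >= 3.4, 10, 0)
  g <- emg_gate(3.0, mkenv(bic, bic * 0), cfg)
  expect_true(g$accept)
  expect_equal(g$gate_time_s, 3.4)
  # crossing at 4.2 s only: outside the 1 s window, reject
  late <- ifelse(tick >= 4.2, 10, 0)
  expect_false(emg_gate(3.0, mkenv(late, late * 0), cfg)$accept)
  # triceps alone suffices
  expect_true(emg_gate(3.0, mkenv(bic * 0, bic), cfg)$accept)
})

test_that("sessions shorter than the window yield zero predictions", {
  m <- fix_model()
  eeg <- matrix(rnorm(length(test_channels()) * 300), length(test_channels()),
                dimnames = list(test_channels(), NULL))
  short <- raw_session(eeg, test_channels(), 500)
  pred <- stream_predict(short, m)
  expect_equal(nrow(pred), 0)
  # channel mismatch is an error
  bad <- raw_session(eeg[1:3, ], test_channels()[1:3], 500)
  expect_error(stream_predict(bad, m), "lacks model channel")
})

test_that("replay is deterministic and detects clean attempted trials", {
  ses <- fix_online_session()
  m <- fix_model()
  cfg <- online_config(tau_c = 0.5, n_c = 3)
  out1 <- run_block(ses, m, cfg)
  out2 <- run_block(ses, m, cfg)
  expect_identical(out1, out2)
  truth <- ses$meta$truth
  expect_equal(sum(out1$is_catch), sum(truth$is_catch))
  att <- out1[!out1$is_catch, ]
  expect_gt(mean(!att$timed_out), 0.8)
  # detection implies an intent and a passed gate
  det <- out1[!is.na(out1$final_detection_time_s), ]
  expect_true(all(!is.na(det$bmi_intent_time_s)))
  expect_true(all(det$emg_gate_passed))
})

test_that("disabling the EMG (infinite thresholds) times every trial out", {
  ses <- fix_online_session()
  m <- fix_model()
  cfg <- online_config(emg_thresh_mv = c(biceps = Inf, triceps = Inf))
  out <- run_block(ses, m, cfg)
  expect_true(all(out$timed_out))
  expect_true(any(!is.na(out$bmi_intent_time_s))) # intents fired, gate vetoed
})

test_that("the EMG-gated rates are bounded by both single-modality rates", {
  ses <- fix_online_session()
  m <- fix_model()
  cfg <- online_config(tau_c = 0.5, n_c = 3)
  gated <- block_metrics(run_block(ses, m, cfg))
  bmi_only <- block_metrics(run_block(ses, m, cfg, gate = FALSE))
  # EMG-only controller: first envelope crossing within the trial
  env <- condition_emg(ses)
  thr <- cfg$emg_thresh_mv
  starts <- ses$events[ses$events$kind %in% c("target_onset",
                                              "catch_target_onset"), ]
  emg_hit <- vapply(seq_len(nrow(starts)), function(r) {
    t_on <- (starts$sample[r] - 1) / ses$fs_eeg
    idx <- env$time_s >= t_on & env$time_s <= t_on + cfg$trial_timeout_s
    any(env$envelope["biceps", idx] > thr["biceps"] |
        env$envelope["triceps", idx] > thr["triceps"])
  }, FALSE)
  is_catch <- starts$kind == "catch_target_onset"
  emg_tpr <- 100 * mean(emg_hit[!is_catch])
  emg_fpr <- 100 * mean(emg_hit[is_catch])
  expect_lte(gated$tpr_pct, min(bmi_only$tpr_pct, emg_tpr))
  expect_lte(gated$fpr_pct, min(bmi_only$fpr_pct, emg_fpr))
})

test_that("streamed and batch predictions agree on the same session", {
  # the prediction path runs on the causal chain; verify the chain's
  # stream/batch identity carries through to identical probabilities
  ses <- fix_online_session()
  m <- fix_model()
  pred1 <- stream_predict(ses, m)
  pred2 <- stream_predict(ses, m)
  expect_identical(pred1, pred2)
  st <- stream_chain_init(ses$eeg_labels, ses$fs_eeg)
  half <- floor(ncol(ses$eeg) / 2)
  r1 <- stream_chain(st, ses$eeg[, 1:half])
  r2 <- stream_chain(r1$state, ses$eeg[, (half + 1):ncol(ses$eeg)])
  batch <- filter_chain(ses)
  expect_identical(cbind(r1$y, r2$y), batch$eeg)
})

test_that("online parameter tuning returns members of the grid", {
  ses <- fix_online_session()
  m <- fix_model()
  tuned <- tune_online_params(ses, m, tau_grid = c(0.5, 0.7), n_grid = c(2, 3))
  expect_true(tuned$tau_c %in% c(0.5, 0.7))
  expect_true(tuned$n_c %in% c(2, 3))
  expect_equal(nrow(tuned$table), 4)
})
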