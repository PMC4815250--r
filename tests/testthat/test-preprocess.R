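# Filter chain, epoching, rejection, baseline, EMG conditioning.

test_that("decimation arithmetic: 500 Hz in, 20 Hz out, floor(n/25) samples", {
  n <- 5003
  eeg <- matrix(rnorm(2 * n), 2, dimnames = list(c("Cz", "C1"), NULL))
  ses <- raw_session(eeg, c("Cz", "C1"), 500)
  out <- suppressWarnings(filter_chain(ses))
  expect_equal(out$fs_eeg, 20)
  expect_equal(ncol(out$eeg), floor(n / 25))
  expect_error(filter_chain(raw_session(eeg, c("Cz", "C1"), 512)),
               "integer multiple")
})

test_that("DC input decays toward zero through the chain", {
  eeg <- matrix(50, 2, 50000, dimnames = list(c("Cz", "Iz"), NULL))
  ses <- raw_session(eeg, c("Cz", "Iz"), 500)
  out <- suppressWarnings(filter_chain(ses))
  expect_lt(abs(out$eeg["Iz", ncol(out$eeg)]), 1) # unfiltered-Laplacian ch
  expect_lt(abs(out$eeg["Iz", ncol(out$eeg)]),
            abs(out$eeg["Iz", 10]) + 1e-9)
})

test_that("streamed chunked processing bit-matches whole-session processing", {
  ses <- fix_calib_session()
  whole <- filter_chain(ses)
  st <- stream_chain_init(ses$eeg_labels, ses$fs_eeg)
  pieces <- list()
  n <- ncol(ses$eeg)
  # deliberately awkward chunk sizes, including 1-sample chunks
  bounds <- unique(c(seq(1, n, by = 33331), n + 1))
  for (i in seq_len(length(bounds) - 1)) {
    chunk <- ses$eeg[, bounds[i]:(bounds[i + 1] - 1), drop = FALSE]
    r <- stream_chain(st, chunk)
    pieces[[i]] <- r$y
    st <- r$state
  }
  streamed <- do.call(cbind, pieces)
  expect_identical(streamed, whole$eeg)
})

test_that("epochs are 70 samples at 20 Hz with balanced classes", {
  ep <- fix_calib_epochs()
  expect_equal(dim(ep$epochs)[3], 70)
  expect_equal(ep$fs, 20)
  expect_balanced(ep)
  expect_equal(sum(ep$labels == "Go"), 14)
})

test_that("catch-trial target onsets are excluded from the No-go set", {
  ses <- fix_online_session()
  ep <- make_epochs(filter_chain(ses))
  n_att <- sum(!ses$meta$truth$is_catch)
  expect_equal(sum(ep$labels == "No-go"), n_att)
  expect_false(any(ep$trial_ids %in% which(ses$meta$truth$is_catch)))
})

test_that("artifact rejection is paired and preserves balance", {
  ep <- fix_calib_epochs()
  # inject a 200 uV blink-like transient into one Go epoch
  victim <- which(ep$labels == "Go")[3]
  ep$epochs[victim, "FCz", 30:34] <- ep$epochs[victim, "FCz", 30:34] + 200
  out <- reject_artifact_epochs(ep, amp_thresh_uV = 100,
                                channels = mrcp_ch())
  expect_true(out$rejected[victim])
  pair <- which(out$trial_ids == out$trial_ids[victim] &
                out$labels == "No-go")
  expect_true(out$rejected[pair])
  expect_equal(sum(out$rejected), 2)
  expect_balanced(out)
  # an infinite threshold rejects nothing
  none <- reject_artifact_epochs(fix_calib_epochs(), amp_thresh_uV = Inf)
  expect_equal(sum(none$rejected), 0)
})

test_that("baseline correction zeroes the first 0.25 s", {
  expect_equal(baseline_correct(rep(5, 70), fs = 20), rep(0, 70))
  x <- c(rep(0, 5), rnorm(65))
  expect_equal(baseline_correct(x, fs = 20), x)
  # ramp: verified against independent arithmetic
  ramp <- seq(0, 6.9, by = 0.1)
  expect_equal(baseline_correct(ramp, fs = 20), ramp - mean(ramp[1:5]))
})

test_that("EMG conditioning recovers sinusoid RMS and kills DC", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(x) raw_session(matrix(0, 1, length(x),
                                       dimnames = list("Cz", NULL)), "Cz", fs,
                                emg = rbind(x, x * 0),
                                emg_labels = c("biceps", "triceps"))
  # 100 Hz (passband) sinusoid, amplitude 3: trailing RMS -> 3/sqrt(2)
  env <- condition_emg(mk(3 * sin(2 * pi * 100 * t)))
  late <- env$envelope["biceps", env$time_s > 5]
  expect_equal(unname(stats::median(late)), 3 / sqrt(2), tolerance = 0.02)
  # silent channel: exactly zero
  expect_true(all(env$envelope["triceps", ] == 0))
  # DC is outside the 30-200 Hz band
  env_dc <- condition_emg(mk(rep(10, length(t))))
  expect_lt(max(env_dc$envelope["biceps", env_dc$time_s > 2]), 0.05)
})

test_that("epoch concatenation keeps structure and renumbers trials", {
  a <- fix_calib_epochs()
  b <- fix_calib_epochs()
  ab <- concat_epochs(a, b)
  expect_equal(dim(ab$epochs)[1], 2 * dim(a$epochs)[1])
  expect_balanced(ab)
  expect_equal(max(ab$trial_ids), 2 * max(a$trial_ids))
})
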