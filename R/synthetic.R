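#' MRCP template parameters
#'
#' Describes the slow negative cortical potential planted on the affected
#' channels of a synthetic trial: a half-cosine descent that begins
#' `ramp_start_s` before movement onset, reaches `amplitude_uV` at the
#' (jittered) per-trial peak, and returns linearly to baseline over
#' `rebound_s`. Amplitudes of -4 to -12 uV and ramps starting 1.5-2 s before
#' onset are typical of pre-movement negativity.
#'
#' @param amplitude_uV negative peak amplitude in microvolts (must be <= 0).
#' @param ramp_start_s ramp onset relative to movement onset, seconds.
#' @param peak_jitter_sd_s SD of per-trial peak-latency jitter, seconds.
#' @param peak_offset_s mean cortical peak time relative to the kinematic
#'   movement onset (seconds, typically <= 0): the pre-movement negativity
#'   peaks at or before the physical onset, and in slowed (paretic)
#'   movement execution the measurable velocity crossing lags the cortical
#'   event. Default 0 (peak at the onset trigger).
#' @param rebound_s return-to-baseline duration after the peak, seconds.
#' @param affected_channels named numeric vector: channel label -> gain in
#'   `[0, 1]`. Defaults to a fronto-central/centro-parietal patch centred on
#'   FCz/Cz with gain tapering outward.
#' @return object of class `mrcp_params`.
#' @export
mrcp_params <- function(amplitude_uV = -8, ramp_start_s = -1.5,
                        peak_jitter_sd_s = 0.3, peak_offset_s = 0,
                        rebound_s = 1,
                        affected_channels = default_mrcp_gains()) {
  if (amplitude_uV > 0) stop("amplitude_uV must be negative (or 0 for null)")
  if (peak_jitter_sd_s < 0) stop("peak_jitter_sd_s must be >= 0")
  if (ramp_start_s >= 0) stop("ramp_start_s must precede movement onset")
  if (rebound_s <= 0) stop("rebound_s must be positive")
  if (length(affected_channels) == 0 || is.null(names(affected_channels)))
    stop("affected_channels must be a non-empty named gain vector")
  structure(list(amplitude_uV = amplitude_uV, ramp_start_s = ramp_start_s,
                 peak_jitter_sd_s = peak_jitter_sd_s,
                 peak_offset_s = peak_offset_s, rebound_s = rebound_s,
                 affected_channels = affected_channels),
            class = "mrcp_params")
}

#' @rdname mrcp_params
#' @export
default_mrcp_gains <- function() {
  c(FCz = 1, Cz = 1, CPz = 0.9, C1 = 0.9, C2 = 0.9, FC1 = 0.8, FC2 = 0.8,
    CP1 = 0.8, CP2 = 0.8, C3 = 0.5, C4 = 0.5, FC3 = 0.4, FC4 = 0.4,
    CP3 = 0.4, CP4 = 0.4, Fz = 0.4, Pz = 0.4)
}

#' Session schedule parameters
#'
#' @param n_blocks number of 20-trial blocks.
#' @param trials_per_block trials per block, default 20.
#' @param catch_per_block instructed no-attempt (catch) trials per block.
#'   Closed-loop blocks carry 1-5; calibration blocks carry 0 (the
#'   calibration task has no catch trials).
#' @param fixation_range_s inter-trial fixation interval bounds, seconds.
#' @param trial_timeout_s trial duration budget, default 15 s.
#' @param rng_seed integer seed making the session fully reproducible.
#' @return object of class `session_plan`.
#' @export
session_plan <- function(n_blocks = 1, trials_per_block = 20,
                         catch_per_block = 3, fixation_range_s = c(4, 6),
                         trial_timeout_s = 15, rng_seed = 1) {
  if (n_blocks < 1 || trials_per_block < 5) stop("implausible block structure")
  if (catch_per_block < 0 || catch_per_block > 5 ||
      catch_per_block > trials_per_block)
    stop("catch_per_block must lie in [0, 5] and fit in the block")
  if (any(fixation_range_s < 0) || diff(fixation_range_s) < 0 ||
      fixation_range_s[2] > trial_timeout_s)
    stop("fixation_range_s must be an interval within [0, trial_timeout_s]")
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 catch_per_block = catch_per_block,
                 fixation_range_s = fixation_range_s,
                 trial_timeout_s = trial_timeout_s, rng_seed = rng_seed),
            class = "session_plan")
}

#' EMG and kinematics generator parameters
#'
#' @param baseline_rms_mv EMG baseline noise RMS (mV).
#' @param burst_rms_mv peak RMS of the movement burst (mV); Gaussian-windowed
#'   30-200 Hz noise.
#' @param delay_s electromechanical delay of the burst after movement onset.
#' @param burst_dur_s burst support duration.
#' @return parameter list.
#' @export
emg_params <- function(baseline_rms_mv = 2, burst_rms_mv = 25, delay_s = 0,
                       burst_dur_s = 1.5) {
  list(baseline_rms_mv = baseline_rms_mv, burst_rms_mv = burst_rms_mv,
       delay_s = delay_s, burst_dur_s = burst_dur_s)
}

#' @param range_deg elbow excursion (0-60 degrees supported by the device).
#' @param move_dur_s minimum-jerk movement duration.
#' @param hold_s hold at the target before returning.
#' @param fs encoder sampling rate, 1000 Hz native.
#' @rdname emg_params
#' @export
kin_params <- function(range_deg = 60, move_dur_s = 1.5, hold_s = 0.5,
                       fs = 1000) {
  list(range_deg = range_deg, move_dur_s = move_dur_s, hold_s = hold_s, fs = fs)
}

# run code under a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' 1/f-shaped (pink) noise
#'
#' White Gaussian noise spectrally shaped to a 1/f amplitude profile and
#' rescaled to unit RMS; the spectral character of background EEG.
#'
#' @param n number of samples.
#' @return numeric vector, unit RMS.
#' @export
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5)) # pad to a fast FFT length
  w <- stats::rnorm(m)
  k <- 0:(m - 1)
  fidx <- pmin(k, m - k) # two-sided frequency index
  wgt <- 1 / sqrt(pmax(fidx, 1))
  wgt[1] <- 0 # drop DC
  shaped <- Re(stats::fft(stats::fft(w) * wgt, inverse = TRUE))[seq_len(n)] / m
  shaped / sqrt(mean(shaped^2))
}

# background EEG: independent pink noise per channel plus one shared
# low-rank pink component so spatial re-referencing has structure to remove
eeg_background <- function(n_ch, n, noise_level) {
  shared <- pink_noise(n)
  load <- stats::runif(n_ch, 0.2, 0.6)
  out <- matrix(0, n_ch, n)
  for (c in seq_len(n_ch)) {
    e <- pink_noise(n)
    out[c, ] <- (e + load[c] * shared) / sqrt(1 + load[c]^2) * noise_level
  }
  out
}

# template evaluated on absolute time axis t (s), onset/peak in same units
mrcp_waveform <- function(t, onset_s, peak_s, params) {
  ramp0 <- onset_s + params$ramp_start_s
  a <- params$amplitude_uV
  y <- numeric(length(t))
  up <- t >= ramp0 & t <= peak_s
  if (peak_s > ramp0)
    y[up] <- a / 2 * (1 - cos(pi * (t[up] - ramp0) / (peak_s - ramp0)))
  reb <- t > peak_s & t <= peak_s + params$rebound_s
  y[reb] <- a * (1 - (t[reb] - peak_s) / params$rebound_s)
  y
}

#' Generate a single synthetic MRCP trial
#'
#' One multichannel EEG segment spanning `t_range` around a movement onset
#' placed at time 0: affected channels carry the gain-scaled MRCP template
#' (peak latency jittered per trial), all channels carry 1/f background
#' noise at `noise_level` RMS.
#'
#' @param params an [mrcp_params()] object.
#' @param noise_level background RMS in microvolts (> 0 unless 0 requested
#'   explicitly for noiseless checks).
#' @param fs sampling rate, default 500 Hz.
#' @param t_range segment extent around movement onset, seconds.
#' @param channels channel labels to synthesize; default full montage.
#' @return list with `eeg` (channels x samples), `t` (time axis, s),
#'   `onset_s = 0`, and `peak_s` (ground-truth jittered peak time).
#' @export
generate_trial <- function(params, noise_level = 2, fs = 500,
                           t_range = c(-3, 2),
                           channels = standard_montage()$label) {
  if (fs <= 0) stop("fs must be positive")
  if (noise_level < 0) stop("noise_level must be non-negative")
  t <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(t)
  peak_s <- params$peak_offset_s + stats::rnorm(1, 0, params$peak_jitter_sd_s)
  eeg <- if (noise_level > 0) eeg_background(length(channels), n, noise_level)
         else matrix(0, length(channels), n)
  wave <- mrcp_waveform(t, params$peak_offset_s, peak_s, params)
  gains <- params$affected_channels
  hit <- match(names(gains), channels)
  for (i in seq_along(gains)) {
    if (!is.na(hit[i])) eeg[hit[i], ] <- eeg[hit[i], ] + gains[i] * wave
  }
  rownames(eeg) <- channels
  list(eeg = eeg, t = t, onset_s = 0, peak_s = peak_s)
}

# minimum-jerk position profile from 0 to `range` over `dur` seconds
min_jerk <- function(t, dur, range) {
  s <- pmin(pmax(t / dur, 0), 1)
  range * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

#' Generate a full synthetic session
#'
#' Lays out `n_blocks` blocks of trials with uniformly drawn fixation gaps,
#' randomized catch-trial positions, trigger events (target-onset for every
#' trial, movement-onset and target-reached for attempted trials only),
#' MRCP templates and EMG bursts on attempted trials, and a minimum-jerk
#' elbow trajectory at 1000 Hz. Identical `rng_seed`s give bit-identical
#' sessions. Ground truth (per-trial onset, peak latency, catch flags) is
#' stored in `meta$truth`.
#'
#' @param plan a [session_plan()].
#' @param params an [mrcp_params()].
#' @param emg an [emg_params()] list.
#' @param kin a [kin_params()] list.
#' @param noise_level EEG background RMS, microvolts.
#' @param fs amplifier sampling rate (EEG and EMG), Hz.
#' @param channels EEG channel labels; default full 64-channel montage.
#' @param prep_range_s bounds of the self-paced preparation delay between
#'   target onset and movement onset, seconds.
#' @return a [raw_session()].
#' @export
generate_session <- function(plan, params = mrcp_params(), emg = emg_params(),
                             kin = kin_params(), noise_level = 2, fs = 500,
                             channels = standard_montage()$label,
                             prep_range_s = c(2.5, 4.5)) {
  stopifnot(inherits(plan, "session_plan"), inherits(params, "mrcp_params"))
  with_seed(plan$rng_seed, {
    n_trials <- plan$n_blocks * plan$trials_per_block

    # schedule: fixation gap, target onset, (prep, movement, reach) or catch
    fix <- stats::runif(n_trials, plan$fixation_range_s[1], plan$fixation_range_s[2])
    prep <- stats::runif(n_trials, prep_range_s[1], prep_range_s[2])
    jit <- stats::rnorm(n_trials, 0, params$peak_jitter_sd_s)
    is_catch <- logical(n_trials)
    for (b in seq_len(plan$n_blocks)) {
      idx <- (b - 1) * plan$trials_per_block + seq_len(plan$trials_per_block)
      if (plan$catch_per_block > 0)
        is_catch[sample(idx, plan$catch_per_block)] <- TRUE
    }

    t_on <- numeric(n_trials)   # target onset
    t_mo <- rep(NA_real_, n_trials)
    t_tr <- rep(NA_real_, n_trials)
    clock <- 2 # lead-in so the first No-go epoch fits
    for (i in seq_len(n_trials)) {
      clock <- clock + fix[i]
      t_on[i] <- clock
      if (is_catch[i]) {
        clock <- clock + plan$trial_timeout_s
      } else {
        t_mo[i] <- t_on[i] + prep[i]
        t_tr[i] <- t_mo[i] + kin$move_dur_s
        clock <- t_tr[i] + kin$hold_s + 1
      }
    }
    total_s <- clock + 3 # tail so the last Go epoch fits
    n <- ceiling(total_s * fs)

    eeg <- if (noise_level > 0) eeg_background(length(channels), n, noise_level)
           else matrix(0, length(channels), n)
    t_axis <- (seq_len(n) - 1) / fs
    gains <- params$affected_channels
    hit <- match(names(gains), channels)
    ctx_on <- t_mo + params$peak_offset_s # cortical onset may lead movement
    for (i in which(!is_catch)) {
      span <- t_axis >= ctx_on[i] + params$ramp_start_s - 0.5 &
              t_axis <= ctx_on[i] + jit[i] + params$rebound_s + 0.5
      wave <- mrcp_waveform(t_axis[span], ctx_on[i], ctx_on[i] + jit[i], params)
      for (k in seq_along(gains)) {
        if (!is.na(hit[k])) eeg[hit[k], span] <- eeg[hit[k], span] + gains[k] * wave
      }
    }
    rownames(eeg) <- channels

    # EMG: baseline noise + Gaussian-windowed 30-200 Hz burst at movement
    bp <- list(hp = butter_sos(4, 30, fs, "high"), lp = butter_sos(4, 200, fs, "low"))
    band_noise <- function() {
      x <- stats::rnorm(n)
      y <- sos_filter(bp$lp, sos_filter(bp$hp, x)$y)$y
      y / sqrt(mean(y^2))
    }
    emg_mat <- matrix(0, 2, n)
    for (m in 1:2) {
      base <- band_noise() * emg$baseline_rms_mv
      carrier <- band_noise()
      win <- numeric(n)
      for (i in which(!is_catch)) {
        t0 <- t_mo[i] + emg$delay_s
        sel <- t_axis >= t0 & t_axis <= t0 + emg$burst_dur_s
        ctr <- t0 + emg$burst_dur_s * 0.3
        win[sel] <- pmax(win[sel],
                         exp(-0.5 * ((t_axis[sel] - ctr) / (emg$burst_dur_s / 5))^2))
      }
      emg_mat[m, ] <- base + carrier * win * emg$burst_rms_mv
    }

    # kinematics: minimum-jerk reach, hold, return
    nk <- ceiling(total_s * kin$fs)
    tk <- (seq_len(nk) - 1) / kin$fs
    pos <- numeric(nk)
    for (i in which(!is_catch)) {
      go <- min_jerk(tk - t_mo[i], kin$move_dur_s, kin$range_deg)
      back <- min_jerk(tk - (t_mo[i] + kin$move_dur_s + kin$hold_s),
                       kin$move_dur_s, kin$range_deg)
      seg <- tk >= t_mo[i] & tk < t_mo[i] + 2 * kin$move_dur_s + kin$hold_s + 0.5
      pos[seg] <- pos[seg] + (go - back)[seg]
    }
    vel <- c(0, diff(pos)) * kin$fs

    s_of <- function(t) pmin(pmax(round(t * fs) + 1, 1), n)
    ev <- rbind(
      data.frame(kind = ifelse(is_catch, "catch_target_onset", "target_onset"),
                 sample = s_of(t_on), trial_id = seq_len(n_trials),
                 block = rep(seq_len(plan$n_blocks), each = plan$trials_per_block)),
      data.frame(kind = "movement_onset", sample = s_of(t_mo[!is_catch]),
                 trial_id = which(!is_catch),
                 block = ((which(!is_catch) - 1) %/% plan$trials_per_block) + 1L),
      data.frame(kind = "target_reached", sample = s_of(t_tr[!is_catch]),
                 trial_id = which(!is_catch),
                 block = ((which(!is_catch) - 1) %/% plan$trials_per_block) + 1L))

    raw_session(eeg, channels, fs, emg = emg_mat, fs_emg = fs,
                kin = list(position = pos, velocity = vel, fs = kin$fs),
                events = ev,
                meta = list(truth = list(
                  onset_s = t_mo, peak_s = t_mo + params$peak_offset_s + jit,
                  is_catch = is_catch,
                  target_on_s = t_on,
                  block = rep(seq_len(plan$n_blocks), each = plan$trials_per_block)),
                  plan = unclass(plan), noise_level = noise_level))
  })
}
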