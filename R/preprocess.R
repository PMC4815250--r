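#' Causal delta-band filter chain with Large-Laplacian re-referencing
#'
#' The MRCP preprocessing cascade: causal 4th-order Butterworth high-pass at
#' 0.1 Hz, Large-Laplacian spatial re-reference (each channel minus the mean
#' of its next-nearest montage neighbors), causal 4th-order Butterworth
#' low-pass at 1 Hz, then decimation to 20 Hz. With content limited to 1 Hz
#' by the low-pass, 20 Hz sampling needs no extra anti-aliasing stage.
#' Every stage is causal, so the output at sample t depends on inputs at
#' samples <= t only and block-wise streaming (see [stream_chain()])
#' reproduces the same samples bit-for-bit.
#'
#' Event sample indices are remapped onto the decimated grid; EMG and
#' kinematics are passed through untouched at their native rates.
#'
#' @param session a `raw_session` at a rate divisible by `target_fs`.
#' @param montage montage for the Laplacian, default [standard_montage()].
#' @param target_fs output rate, default 20 Hz.
#' @param hp_hz,lp_hz band edges, defaults 0.1 and 1 Hz.
#' @return a `raw_session` with `fs_eeg = target_fs`.
#' @export
filter_chain <- function(session, montage = standard_montage(),
                         target_fs = 20, hp_hz = 0.1, lp_hz = 1) {
  fs <- session$fs_eeg
  decim <- fs / target_fs
  if (decim != round(decim))
    stop("sampling rate ", fs, " is not an integer multiple of ", target_fs)
  st <- stream_chain_init(session$eeg_labels, fs, montage, target_fs,
                          hp_hz, lp_hz)
  out <- stream_chain(st, session$eeg)
  y <- out$y
  n20 <- ncol(y)

  ev <- session$events
  if (nrow(ev)) {
    ev$sample <- as.integer(ceiling(ev$sample / decim))
    ev <- ev[ev$sample >= 1 & ev$sample <= n20, , drop = FALSE]
  }
  res <- session
  res$eeg <- y
  res$fs_eeg <- target_fs
  res$events <- ev
  res$meta$filtered <- list(hp_hz = hp_hz, lp_hz = lp_hz, decim = decim)
  res
}

#' Streaming (block-wise) form of the preprocessing chain
#'
#' `stream_chain_init()` builds a state object; `stream_chain()` consumes an
#' arbitrary chunk of raw samples (channels x samples at the native rate)
#' and returns whatever new 20 Hz samples became available plus the updated
#' state. Feeding a recording in chunks of any size yields exactly the
#' samples [filter_chain()] produces in one shot -- the property that lets
#' offline calibration and closed-loop replay share one signal path.
#'
#' @param labels channel labels of the incoming data.
#' @param fs native sampling rate.
#' @param montage,target_fs,hp_hz,lp_hz as in [filter_chain()].
#' @return for `stream_chain_init`, a state object; for `stream_chain`, a
#'   list with `y` (channels x new 20 Hz samples) and `state`.
#' @export
stream_chain_init <- function(labels, fs, montage = standard_montage(),
                              target_fs = 20, hp_hz = 0.1, lp_hz = 1) {
  sos <- delta_band_sos(fs, hp_hz, lp_hz)
  list(sos = sos, W = laplacian_matrix(labels, montage), fs = fs,
       decim = as.integer(fs / target_fs), labels = labels,
       zi_hp = matrix(0, 2 * nrow(sos$hp), length(labels)),
       zi_lp = matrix(0, 2 * nrow(sos$lp), length(labels)),
       seen = 0L)
}

#' @param state state from `stream_chain_init` (or a previous call).
#' @param chunk channels x samples matrix at the native rate.
#' @rdname stream_chain_init
#' @export
stream_chain <- function(state, chunk) {
  hp <- sos_filter(state$sos$hp, chunk, state$zi_hp)
  lap <- state$W %*% hp$y
  lp <- sos_filter(state$sos$lp, lap, state$zi_lp)
  # emit one output per full decimation frame: global indices 0 (mod decim),
  # so a batch of n samples yields exactly floor(n / decim) outputs
  idx_global <- state$seen + seq_len(ncol(chunk))
  keep <- which(idx_global %% state$decim == 0L)
  y <- lp$y[, keep, drop = FALSE]
  rownames(y) <- state$labels
  state$zi_hp <- hp$zf
  state$zi_lp <- lp$zf
  state$seen <- state$seen + ncol(chunk)
  list(y = y, state = state)
}

#' Labeled Go/No-go epoch set
#'
#' Cuts the filtered 20 Hz session into `[-2.5, 1)` s epochs: movement-onset
#' aligned epochs are the "Go" class (motor preparation present),
#' target-onset aligned epochs are "No-go" (subject fixating). Catch-trial
#' target onsets are excluded from calibration sets. Trials whose Go epoch
#' falls outside the record lose their No-go epoch too, keeping the classes
#' balanced.
#'
#' @param session filtered `raw_session` (normally 20 Hz).
#' @param t_range epoch window, seconds, default `c(-2.5, 1)`.
#' @return object of class `epoch_set`: list with `epochs`
#'   (trials x channels x samples array), `labels` (factor Go/No-go),
#'   `trial_ids`, `align`, `rejected`, `reject_reason`, `channels`, `fs`,
#'   `t0`.
#' @export
make_epochs <- function(session, t_range = c(-2.5, 1)) {
  go <- epoch_slices(session, "movement_onset", t_range)
  nogo <- epoch_slices(session, "target_onset", t_range)
  common <- intersect(go$trial_id, nogo$trial_id)
  go <- go[go$trial_id %in% common, , drop = FALSE]
  nogo <- nogo[nogo$trial_id %in% common, , drop = FALSE]

  sl <- rbind(go, nogo)
  n_samp <- round(diff(t_range) * session$fs_eeg)
  ep <- array(0, c(nrow(sl), nrow(session$eeg), n_samp),
              dimnames = list(NULL, session$eeg_labels, NULL))
  for (i in seq_len(nrow(sl))) {
    ep[i, , ] <- session$eeg[, sl$start[i]:(sl$end[i] - 1)]
  }
  structure(list(
    epochs = ep,
    labels = factor(rep(c("Go", "No-go"), c(nrow(go), nrow(nogo))),
                    levels = c("Go", "No-go")),
    trial_ids = sl$trial_id,
    align = rep(c("movement_onset", "target_onset"), c(nrow(go), nrow(nogo))),
    rejected = logical(nrow(sl)),
    reject_reason = character(nrow(sl)),
    channels = session$eeg_labels,
    fs = session$fs_eeg, t0 = t_range[1]), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d Go / %d No-go, %d rejected), %d ch x %d samples @ %g Hz\n",
              length(x$labels), sum(x$labels == "Go"), sum(x$labels == "No-go"),
              sum(x$rejected), dim(x$epochs)[2], dim(x$epochs)[3], x$fs))
  invisible(x)
}

#' Append epoch sets (e.g., calibration days 1 and 2)
#' @param ... `epoch_set` objects with identical channels/fs/epoch length.
#' @return combined `epoch_set`.
#' @export
concat_epochs <- function(...) {
  sets <- list(...)
  base <- sets[[1]]
  for (s in sets[-1]) {
    stopifnot(identical(s$channels, base$channels), s$fs == base$fs)
    off <- max(base$trial_ids)
    base$epochs <- abind3(base$epochs, s$epochs)
    base$labels <- factor(c(as.character(base$labels), as.character(s$labels)),
                          levels = c("Go", "No-go"))
    base$trial_ids <- c(base$trial_ids, s$trial_ids + off)
    base$align <- c(base$align, s$align)
    base$rejected <- c(base$rejected, s$rejected)
    base$reject_reason <- c(base$reject_reason, s$reject_reason)
  }
  base
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = list(NULL, dimnames(a)[[2]], NULL))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Amplitude-criterion artifact rejection with paired class balance
#'
#' Automated stand-in for visual inspection: a Go epoch whose peak-to-peak
#' amplitude on any selected channel exceeds the threshold is flagged, and
#' the same trial's No-go epoch is flagged with it so the class distribution
#' stays balanced.
#'
#' @param epochs an `epoch_set`.
#' @param amp_thresh_uV peak-to-peak threshold, default 100 uV.
#' @param channels channels to screen; default all.
#' @return the `epoch_set` with updated `rejected`/`reject_reason`.
#' @export
reject_artifact_epochs <- function(epochs, amp_thresh_uV = 100,
                                   channels = NULL) {
  if (amp_thresh_uV <= 0) stop("amp_thresh_uV must be positive")
  ch <- if (is.null(channels)) seq_along(epochs$channels)
        else match(channels, epochs$channels)
  if (anyNA(ch)) stop("unknown channel in `channels`")
  go_idx <- which(epochs$labels == "Go" & !epochs$rejected)
  for (i in go_idx) {
    seg <- matrix(epochs$epochs[i, ch, ], nrow = length(ch))
    pp <- apply(seg, 1, function(x) diff(range(x)))
    if (max(pp) > amp_thresh_uV) {
      pair <- which(epochs$trial_ids == epochs$trial_ids[i])
      epochs$rejected[pair] <- TRUE
      epochs$reject_reason[pair] <- ifelse(
        epochs$labels[pair] == "Go", "amplitude", "paired")
    }
  }
  epochs
}

#' Baseline-correct epochs for grand-average display
#'
#' Subtracts from each epoch its mean over the first 0.25 s
#' (`[-2.5, -2.25]` s). Used only when computing grand averages for
#' visualization; never applied in the classification path.
#'
#' @param epoch numeric vector/matrix (channels x samples) or `epoch_set`.
#' @param fs sampling rate (taken from the epoch set when given one).
#' @param baseline_s baseline extent from epoch start, default 0.25 s.
#' @return same shape as the input, baseline removed.
#' @export
baseline_correct <- function(epoch, fs = 20, baseline_s = 0.25) {
  nb <- max(1, round(baseline_s * fs))
  if (inherits(epoch, "epoch_set")) {
    nb <- max(1, round(baseline_s * epoch$fs))
    for (i in seq_len(dim(epoch$epochs)[1])) {
      seg <- matrix(epoch$epochs[i, , ], nrow = dim(epoch$epochs)[2])
      epoch$epochs[i, , ] <- seg - rowMeans(seg[, seq_len(nb), drop = FALSE])
    }
    return(epoch)
  }
  if (is.matrix(epoch)) epoch - rowMeans(epoch[, seq_len(nb), drop = FALSE])
  else epoch - mean(epoch[seq_len(nb)])
}

#' Trailing-RMS EMG envelopes on the online tick grid
#'
#' Band-pass filters each EMG channel causally (30-200 Hz, 8th order
#' Butterworth realized as a 4th-order high-pass cascaded with a 4th-order
#' low-pass) and computes the RMS over a trailing 300 ms window, evaluated
#' every `tick_s` seconds.
#'
#' @param session `raw_session` with EMG at its native rate.
#' @param band band edges in Hz, default `c(30, 200)`.
#' @param rms_window_s trailing window, default 0.3 s.
#' @param tick_s evaluation step, default 0.05 s.
#' @return list with `envelope` (muscles x ticks matrix, mV), `time_s`
#'   (tick times), `muscles`.
#' @export
condition_emg <- function(session, band = c(30, 200), rms_window_s = 0.3,
                          tick_s = 0.05) {
  if (is.null(session$emg)) stop("session has no EMG channels")
  fs <- session$fs_emg
  hp <- butter_sos(4, band[1], fs, "high")
  lp <- butter_sos(4, band[2], fs, "low")
  filt <- sos_filter(lp, sos_filter(hp, session$emg)$y)$y
  n <- ncol(filt)
  w <- round(rms_window_s * fs)
  step <- round(tick_s * fs)
  ticks <- seq(step, n, by = step)
  env <- matrix(0, nrow(filt), length(ticks))
  csum <- apply(filt^2, 1, cumsum) # samples x muscles
  for (j in seq_along(ticks)) {
    hi <- ticks[j]
    lo <- max(0, hi - w)
    tot <- csum[hi, ] - if (lo > 0) csum[lo, ] else 0
    env[, j] <- sqrt(tot / (hi - lo))
  }
  rownames(env) <- session$emg_labels
  list(envelope = env, time_s = ticks / fs, muscles = session$emg_labels)
}
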