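#' Design a causal Butterworth filter as second-order sections
#'
#' Even-order Butterworth low- or high-pass design via the bilinear transform
#' of the analog prototype, returned as cascaded biquads (second-order
#' sections) for numerical robustness at extreme normalized cutoffs such as
#' 0.1 Hz at a 500 Hz sampling rate.
#'
#' @param order filter order (even; the pipeline uses 4th order throughout).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return an `L x 6` matrix of SOS rows `(b0, b1, b2, 1, a1, a2)` with
#'   `L = order / 2`.
#' @examples
#' sos <- butter_sos(4, 1, fs = 500, type = "low")
#' @export
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order <= 0 || order %% 2 != 0) stop("order must be a positive even integer")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) stop("cutoff must lie in (0, fs/2)")

  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  proto <- complex(modulus = 1, argument = theta) # left-half-plane poles

  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  if (type == "low") {
    sp <- warped * proto
    zz <- rep(-1 + 0i, order) # n zeros at infinity -> z = -1
    zref <- 1 + 0i            # unit gain at DC
  } else {
    sp <- warped / proto
    zz <- rep(1 + 0i, order)  # n zeros at s = 0 -> z = +1
    zref <- -1 + 0i           # unit gain at Nyquist
  }
  fs2 <- 2 * fs
  zp <- (fs2 + sp) / (fs2 - sp)
  g <- Re(prod(zref - zp) / prod(zref - zz))

  # pair conjugate poles into biquads (even-order Butterworth: all complex)
  upper <- zp[Im(zp) > 0]
  if (length(upper) != order / 2) stop("unexpected pole configuration")
  L <- order / 2
  sos <- matrix(0, L, 6)
  zr <- Re(zz[1])
  for (s in seq_len(L)) {
    p <- upper[s]
    sos[s, ] <- c(1, -2 * zr, zr^2, 1, -2 * Re(p), Mod(p)^2)
  }
  sos[1, 1:3] <- sos[1, 1:3] * g
  sos
}

#' Apply an SOS filter causally, carrying state
#'
#' Direct-form-II-transposed filtering of one signal or a channels-by-samples
#' matrix. The returned final state can be fed back in as `zi` so that
#' block-wise (streaming) filtering reproduces whole-record filtering
#' bit-for-bit; this equivalence is what lets offline calibration and the
#' online replay see identical signals.
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x numeric vector, or matrix (channels x samples).
#' @param zi initial state: `L x 2` matrix for a vector input, `2L x nch`
#'   matrix for a matrix input. `NULL` means rest (all zeros).
#' @return list with `y` (filtered, same shape as `x`) and `zf` (final state).
#' @export
sos_filter <- function(sos, x, zi = NULL) {
  L <- nrow(sos)
  if (is.matrix(x)) {
    if (is.null(zi)) zi <- matrix(0, 2 * L, nrow(x))
    out <- sosfilt_mat_cpp(sos, x, zi)
    dimnames(out$y) <- dimnames(x)
    out
  } else {
    if (is.null(zi)) zi <- matrix(0, L, 2)
    sosfilt_cpp(sos, as.numeric(x), zi)
  }
}

#' Cascade of the delta-band filters used for MRCP extraction
#'
#' Convenience constructor for the two causal 4th-order Butterworth stages:
#' a 0.1 Hz high-pass and a 1 Hz low-pass (applied on either side of the
#' Large-Laplacian re-reference in [filter_chain()]).
#'
#' @param fs sampling rate in Hz.
#' @param hp_hz,lp_hz -3 dB cutoffs; defaults 0.1 and 1 Hz.
#' @param order per-stage order, default 4.
#' @return list with elements `hp` and `lp`, each an SOS matrix.
#' @export
delta_band_sos <- function(fs, hp_hz = 0.1, lp_hz = 1, order = 4) {
  list(hp = butter_sos(order, hp_hz, fs, "high"),
       lp = butter_sos(order, lp_hz, fs, "low"))
}
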