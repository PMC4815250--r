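#' Spatial average over selected MRCP channels
#'
#' Pointwise arithmetic mean X(t) of the selected channel traces V_k(t),
#' the single time series on which windows are placed and online prediction
#' runs. Smooths single-trial variability without changing units.
#'
#' @param epoch channels x samples matrix (one epoch), or an `epoch_set`.
#' @param channels labels to average (M >= 1).
#' @return numeric vector for a matrix input; epochs x samples matrix for an
#'   `epoch_set`.
#' @export
spatial_average <- function(epoch, channels) {
  if (length(channels) == 0) stop("channel list must be non-empty")
  if (inherits(epoch, "epoch_set")) {
    idx <- match(channels, epoch$channels)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
    n_ep <- dim(epoch$epochs)[1]
    out <- matrix(0, n_ep, dim(epoch$epochs)[3])
    for (i in seq_len(n_ep)) {
      out[i, ] <- colMeans(matrix(epoch$epochs[i, idx, ], nrow = length(idx)))
    }
    return(out)
  }
  idx <- match(channels, rownames(epoch))
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  colMeans(epoch[idx, , drop = FALSE])
}

# time axis of an epoch (seconds relative to the alignment event)
epoch_time <- function(n, fs = 20, t0 = -2.5) t0 + (seq_len(n) - 1) / fs

# index of the sample at time t (nearest-sample convention)
time_index <- function(t, fs = 20, t0 = -2.5) round((t - t0) * fs) + 1

#' Locate the negative peak of a spatial-average trace
#'
#' Argmin of the trace within the search interval (default `[-2, 0.5]` s
#' relative to the alignment event). Exact ties break toward the latest
#' time, matching the convention that later peaks reflect filter lag rather
#' than artifact.
#'
#' @param trace numeric vector (one epoch's spatial average).
#' @param fs,t0 sampling rate and epoch start time.
#' @param search_interval two-element interval in seconds.
#' @return peak time in seconds.
#' @export
find_negative_peak <- function(trace, fs = 20, t0 = -2.5,
                               search_interval = c(-2, 0.5)) {
  i0 <- max(1, time_index(search_interval[1], fs, t0))
  i1 <- min(length(trace), time_index(search_interval[2], fs, t0))
  seg <- trace[i0:i1]
  rel <- max(which(seg == min(seg)))
  epoch_time(length(trace), fs, t0)[i0 + rel - 1]
}

#' Window specification for feature extraction
#'
#' A window is defined by its leading edge (onset time, looking back) and
#' length: it spans `[edge_s - wl_s, edge_s]`.
#'
#' @param edge_s leading-edge time, seconds relative to the alignment event.
#' @param wl_s window length, seconds (0.5-1.0 in the optimization loop).
#' @param mode `"fixed"` or `"adaptive"`.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(edge_s, wl_s, mode = c("fixed", "adaptive")) {
  structure(list(edge_s = edge_s, wl_s = wl_s, mode = match.arg(mode)),
            class = "window_spec")
}

#' Place the per-trial adaptive window at the negative MRCP peak
#'
#' The adaptive window's leading edge coincides with the time of the
#' trace's negative peak, compensating trial-to-trial latency jitter.
#' Training trials whose peak falls strictly earlier than -1.5 s are
#' treated as artifact-corrupted and rejected (a peak at exactly -1.5 s is
#' retained). A window that would leave the epoch is clamped to fit.
#'
#' @param trace spatial-average trace of one epoch.
#' @param wl_s window length, seconds.
#' @param fs,t0 epoch timing.
#' @param search_interval peak search interval, default `[-2, 0.5]` s.
#' @param reject_before_s screening bound, default -1.5 s.
#' @return a `window_spec`, or `NULL` when the trial is rejected.
#' @export
place_adaptive_window <- function(trace, wl_s, fs = 20, t0 = -2.5,
                                  search_interval = c(-2, 0.5),
                                  reject_before_s = -1.5) {
  peak <- find_negative_peak(trace, fs, t0, search_interval)
  if (peak < reject_before_s) return(NULL)
  t_end <- epoch_time(length(trace), fs, t0)[length(trace)]
  edge <- min(max(peak, t0 + wl_s), t_end)
  window_spec(edge, wl_s, "adaptive")
}

#' Fixed window placement
#'
#' Go windows sit at +0.5 s after movement onset (the fixed-window edge is
#' shifted past the onset to compensate the causal-filter lag of the MRCP
#' peak), spanning `[0.5 - wl, 0.5]`. No-go windows sit at -0.5 s before
#' target onset, spanning `[-0.5 - wl, -0.5]`, and are used for both fixed
#' and adaptive Go modes.
#'
#' @param wl_s window length, seconds.
#' @param align_kind `"Go"` (movement-onset aligned) or `"No-go"`.
#' @param go_edge_s,nogo_edge_s edge conventions, defaults 0.5 and -0.5 s.
#' @return a `window_spec`.
#' @export
place_fixed_window <- function(wl_s, align_kind = c("Go", "No-go"),
                               go_edge_s = 0.5, nogo_edge_s = -0.5) {
  align_kind <- match.arg(align_kind)
  window_spec(if (align_kind == "Go") go_edge_s else nogo_edge_s, wl_s, "fixed")
}

# extract the amplitude vector of a window from a trace
window_values <- function(trace, spec, fs = 20, t0 = -2.5) {
  n_w <- round(spec$wl_s * fs) + 1
  edge <- time_index(spec$edge_s, fs, t0)
  trace[(edge - n_w + 1):edge]
}

#' Go-class cluster statistics for the Mahalanobis feature
#'
#' Sample mean and covariance of the windowed Go-class amplitude vectors,
#' with a ridge term added before inversion. Fit on training folds only to
#' avoid leaking test data into the feature definition.
#'
#' @param go_windows matrix, one windowed amplitude vector per row.
#' @param ridge_eps ridge added to the diagonal; default
#'   `1e-6 * trace(Sigma) / dim` (with a tiny absolute floor for the
#'   degenerate all-identical case).
#' @return object of class `go_stats` with `mu`, `sigma`, `sigma_inv`,
#'   `ridge_eps`, `n`.
#' @export
fit_go_stats <- function(go_windows, ridge_eps = NULL) {
  go_windows <- as.matrix(go_windows)
  if (nrow(go_windows) < 2) stop("need at least 2 Go windows")
  mu <- colMeans(go_windows)
  sigma <- stats::cov(go_windows)
  d <- ncol(go_windows)
  if (is.null(ridge_eps))
    ridge_eps <- max(1e-6 * sum(diag(sigma)) / d, 1e-12)
  reg <- sigma + diag(ridge_eps, d)
  inv <- tryCatch(solve(reg), error = function(e)
    stop("covariance singular even after ridge ", ridge_eps,
         "; raise ridge_eps", call. = FALSE))
  structure(list(mu = mu, sigma = sigma, sigma_inv = inv,
                 ridge_eps = ridge_eps, n = nrow(go_windows)),
            class = "go_stats")
}

#' Extract the four time-domain MRCP features from a windowed trace
#'
#' Computes slope (least-squares linear fit of amplitude against time,
#' uV/s), negative peak amplitude (window minimum, uV), area (trapezoidal
#' integral, uV.s) and Mahalanobis distance to the Go cluster,
#' `d = sqrt((x - mu)' Sigma^-1 (x - mu))`, which is 0 when the sample
#' coincides with the cluster mean.
#'
#' @param x windowed amplitude vector, or a matrix of windows (one per row).
#' @param stats a `go_stats` object whose dimension matches the window.
#' @param dt sample spacing in seconds (1/20 at the decimated rate).
#' @param slope_estimator `"lsfit"` (default) or `"endpoints"`
#'   (last minus first over the window length).
#' @return a 1 x 4 (or rows x 4) matrix with columns
#'   `slope`, `neg_peak`, `area`, `mahal_d`.
#' @export
extract_features <- function(x, stats, dt = 0.05,
                             slope_estimator = c("lsfit", "endpoints")) {
  slope_estimator <- match.arg(slope_estimator)
  W <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  d <- ncol(W)
  if (length(stats$mu) != d)
    stop("window length ", d, " does not match Go statistics (",
         length(stats$mu), ")")
  tt <- (seq_len(d) - 1) * dt
  slope <- if (slope_estimator == "lsfit") {
    tc <- tt - mean(tt)
    as.numeric(W %*% tc) / sum(tc^2)
  } else {
    (W[, d] - W[, 1]) / ((d - 1) * dt)
  }
  neg_peak <- apply(W, 1, min)
  area <- dt * (rowSums(W) - (W[, 1] + W[, d]) / 2)
  centered <- sweep(W, 2, stats$mu)
  q <- rowSums((centered %*% stats$sigma_inv) * centered)
  mahal <- sqrt(pmax(q, 0))
  cbind(slope = slope, neg_peak = neg_peak, area = area, mahal_d = mahal)
}

# all sliding-window placements of length n_w through a trace, one per row,
# ordered chronologically by leading edge
sliding_windows <- function(trace, n_w, step = 1) {
  edges <- seq(n_w, length(trace), by = step)
  W <- matrix(0, length(edges), n_w)
  for (j in seq_along(edges)) W[j, ] <- trace[(edges[j] - n_w + 1):edges[j]]
  list(W = W, edges = edges)
}
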