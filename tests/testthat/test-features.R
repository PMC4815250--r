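# Spatial averaging, window placement, the four features, Go statistics.

test_that("spatial average equals the brute-force per-sample mean", {
  ep <- matrix(rnorm(4 * 70), 4, dimnames = list(c("Cz", "C1", "C2", "Pz"),
                                                 NULL))
  # M = 1: identity
  expect_equal(spatial_average(ep, "Cz"), unname(ep["Cz", ]))
  # constants: 2 and 4 -> 3
  cc <- matrix(c(2, 4), 2, 10, dimnames = list(c("a", "b"), NULL))
  expect_equal(spatial_average(cc, c("a", "b")), rep(3, 10))
  # random epoch vs independent recomputation
  manual <- vapply(seq_len(70), function(j) mean(ep[c(1, 3, 4), j]), 0)
  expect_equal(spatial_average(ep, c("Cz", "C2", "Pz")), manual)
  expect_error(spatial_average(ep, character()), "non-empty")
  expect_error(spatial_average(ep, "Oz"), "unknown")
})

test_that("negative peak search respects interval, boundary and tie rules", {
  tt <- epoch_time(70)
  # planted minimum at +0.4 s
  tr <- -dnorm(tt, 0.4, 0.2)
  expect_equal(find_negative_peak(tr), 0.4, tolerance = 1 / 20 + 1e-9)
  # monotonically decreasing trace: right edge of the search interval
  expect_equal(find_negative_peak(-seq_len(70)), 0.5)
  # two equal minima: the later one wins
  tie <- rep(0, 70)
  tie[c(20, 40)] <- -5
  expect_equal(find_negative_peak(tie), tt[40])
})

test_that("adaptive placement screens early peaks and clamps to the epoch", {
  tt <- epoch_time(70)
  mk <- function(peak_t) -dnorm(tt, peak_t, 0.15)
  # peak at -1.8 s: rejected from training
  expect_null(place_adaptive_window(mk(-1.8), 0.6))
  # peak at exactly -1.5 s: retained (strictly "earlier than" rejects)
  w <- place_adaptive_window(mk(-1.5), 0.6)
  expect_equal(w$edge_s, -1.5)
  # peak at 0: window [-0.6, 0]
  w0 <- place_adaptive_window(mk(0), 0.6)
  expect_equal(w0$edge_s, 0)
  expect_equal(w0$edge_s - w0$wl_s, -0.6)
})

test_that("fixed windows sit at the documented edges", {
  g <- place_fixed_window(0.5, "Go")
  expect_equal(c(g$edge_s - g$wl_s, g$edge_s), c(0, 0.5))
  n8 <- place_fixed_window(0.8, "No-go")
  expect_equal(c(n8$edge_s - n8$wl_s, n8$edge_s), c(-1.3, -0.5))
  n10 <- place_fixed_window(1, "No-go")
  expect_equal(c(n10$edge_s - n10$wl_s, n10$edge_s), c(-1.5, -0.5))
  expect_gte(n10$edge_s - n10$wl_s, -2.5) # still inside the epoch
})

test_that("Go statistics match hand-computed values and recover a Gaussian", {
  # 2-sample toy set
  gs <- fit_go_stats(rbind(c(0, 0), c(2, 2)), ridge_eps = 1e-9)
  expect_equal(gs$mu, c(1, 1))
  expect_equal(gs$sigma, matrix(2, 2, 2))
  # degenerate identical windows: regularized inverse = I / eps
  deg <- fit_go_stats(rbind(c(1, 1), c(1, 1)), ridge_eps = 0.1)
  expect_equal(deg$sigma_inv, diag(2) / 0.1)
  # Monte-Carlo consistency at large n
  set.seed(10)
  X <- cbind(rnorm(4000, 2, 1), rnorm(4000, -1, 2))
  big <- fit_go_stats(X)
  expect_equal(big$mu, c(2, -1), tolerance = 0.1)
  expect_equal(unname(diag(big$sigma)), c(1, 4), tolerance = 0.2)
  expect_error(fit_go_stats(matrix(1, 1, 3)), "at least 2")
})

test_that("features match closed forms", {
  gs <- fit_go_stats(rbind(rep(0, 11), rep(0.001, 11)), ridge_eps = 1)
  gs$mu <- rep(0, 11)
  gs$sigma_inv <- diag(11)
  # x = mu -> Mahalanobis 0
  f0 <- extract_features(rep(0, 11), gs)
  expect_equal(unname(f0[1, "mahal_d"]), 0)
  # Sigma = I, x - mu = (3, 4, 0, ...) -> distance 5
  x <- c(3, 4, rep(0, 9))
  expect_equal(unname(extract_features(x, gs)[1, "mahal_d"]), 5)
  # line from -2 to -6 uV over 0.5 s: slope -8 uV/s
  line <- seq(-2, -6, length.out = 11)
  fl <- extract_features(line, gs)
  expect_equal(unname(fl[1, "slope"]), -8)
  expect_equal(unname(fl[1, "neg_peak"]), -6)
  # constant -4 uV over 0.5 s: area -2 uV.s
  fc <- extract_features(rep(-4, 11), gs)
  expect_equal(unname(fc[1, "area"]), -2)
  # endpoint slope estimator agrees on a pure line
  expect_equal(unname(extract_features(line, gs,
                                       slope_estimator = "endpoints")[1, 1]),
               -8)
  expect_error(extract_features(rep(0, 5), gs), "does not match")
})

test_that("Mahalanobis distance is invariant under affine reparameterization", {
  set.seed(11)
  for (rep_i in 1:5) {
    d <- 6
    X <- matrix(rnorm(40 * d), 40)
    gs <- fit_go_stats(X, ridge_eps = 1e-10)
    x <- rnorm(d)
    d0 <- extract_features(x, gs)[1, "mahal_d"]
    A <- matrix(rnorm(d * d), d)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(d * d), d)
    b <- rnorm(d)
    Xt <- t(A %*% t(X) + b)
    gst <- fit_go_stats(Xt, ridge_eps = 1e-10)
    dt <- extract_features(as.numeric(A %*% x + b), gst)[1, "mahal_d"]
    expect_equal(unname(dt), unname(d0), tolerance = 1e-4)
  }
})

test_that("the assembled feature table is 2N x 4", {
  ep <- fix_calib_epochs()
  traces <- spatial_average(ep, mrcp_ch())
  n <- sum(ep$labels == "Go")
  gs <- fit_go_stats(traces[ep$labels == "Go", 1:11])
  feats <- extract_features(traces[, 1:11], gs)
  expect_equal(dim(feats), c(2 * n, 4))
  expect_identical(colnames(feats), c("slope", "neg_peak", "area", "mahal_d"))
  expect_true(all(is.finite(feats)))
})

test_that("the adaptive window holds the trace minimum at its edge", {
  ep <- fix_calib_epochs()
  traces <- spatial_average(ep, mrcp_ch())
  for (i in which(ep$labels == "Go")) {
    w <- place_adaptive_window(traces[i, ], 0.6)
    if (is.null(w)) next
    vals <- window_values(traces[i, ], w)
    peak_t <- find_negative_peak(traces[i, ])
    if (w$edge_s == peak_t) expect_equal(vals[length(vals)],
                                         min(traces[i, time_index(-2):
                                                          time_index(0.5)]))
  }
})
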