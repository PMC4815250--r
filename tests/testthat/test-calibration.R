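# Pseudo-online CV, grid search, window-length rule, permutation test,
# model selection and serialization.

test_that("trial decisions follow the 3-consecutive rule", {
  # G,G,G at placements 5-7: Go with the mean of those three probabilities
  pr <- c(0.1, 0.2, 0.3, 0.4, 0.8, 0.9, 0.7, 0.2)
  d <- trial_decision(pr, tau = 0.5, consec = 3)
  expect_true(d$go)
  expect_equal(d$prob, mean(c(0.8, 0.9, 0.7)))
  expect_equal(d$at, 7)
  # a broken run never fires; probability averages the No-go placements
  pr2 <- c(0.8, 0.6, 0.3, 0.8, 0.8, 0.4)
  d2 <- trial_decision(pr2, tau = 0.5, consec = 3)
  expect_false(d2$go)
  expect_equal(d2$prob, mean(c(0.3, 0.4)))
  # consec = 1 fires at the first supra-threshold placement
  expect_equal(trial_decision(c(0.2, 0.9), 0.5, 1)$at, 2)
})

test_that("separable synthetic data give near-perfect pseudo-online CV", {
  cv <- pseudo_online_cv(fix_separable_epochs(), 0.8, mrcp_ch(), C = 100,
                         gamma = 0.5, n_folds = 5, seed = 3)
  expect_gte(cv$mean_acc, 0.95)
  expect_gte(cv$auc, 0.98)
  expect_equal(length(cv$fold_acc), 5)
  # every retained epoch is scored exactly once across folds
  expect_equal(nrow(cv$trials), sum(!fix_separable_epochs()$rejected))
  expect_true(all(cv$trials$prob >= 0 & cv$trials$prob <= 1))
})

test_that("the CV is reproducible under a seed and honors fold reduction", {
  a <- pseudo_online_cv(fix_calib_epochs(), 0.6, mrcp_ch(), C = 10,
                        gamma = 0.2, n_folds = 5, seed = 12)
  b <- pseudo_online_cv(fix_calib_epochs(), 0.6, mrcp_ch(), C = 10,
                        gamma = 0.2, n_folds = 5, seed = 12)
  expect_identical(a$fold_acc, b$fold_acc)
  expect_identical(a$trials$prob, b$trials$prob)
  expect_warning(
    pseudo_online_cv(fix_calib_epochs(), 0.6, mrcp_ch(), n_folds = 20,
                     seed = 1),
    "folds")
})

test_that("AUC equals the rank-statistic oracle", {
  cv <- pseudo_online_cv(fix_calib_epochs(), 0.8, mrcp_ch(), C = 100,
                         gamma = 0.5, n_folds = 5, seed = 3)
  pr <- cv$trials$prob
  pos <- cv$trials$label == "Go"
  # Mann-Whitney with tie correction, computed independently
  r <- rank(pr)
  auc_rank <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  expect_equal(cv$auc, auc_rank, tolerance = 1e-10)
  # and on a small synthetic set with ties
  p2 <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.8)
  y2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  r2 <- rank(p2)
  oracle <- (sum(r2[y2]) - 3 * 4 / 2) / 9
  expect_equal(roc_curve(p2, y2)$auc, oracle, tolerance = 1e-10)
})

test_that("ROC points are monotone and AUC is bounded", {
  set.seed(4)
  roc <- roc_curve(runif(50), sample(c(TRUE, FALSE), 50, TRUE))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_gte(roc$auc, 0)
  expect_lte(roc$auc, 1)
})

test_that("grid search ties break toward smaller C then smaller gamma", {
  # degenerate constant features make every pair tie
  ep <- fix_calib_epochs()
  flat <- ep
  flat$epochs[] <- 1e-3 # constant epochs: no signal at all
  gs <- suppressWarnings(grid_search(flat, 0.5, mrcp_ch(),
                                     Cs = c(100, 10), gammas = c(0.5, 0.2),
                                     n_folds = 3, seed = 5))
  expect_equal(gs$C, 10)
  expect_equal(gs$gamma, 0.2)
  expect_equal(nrow(gs$table), 4) # |Cs| x |gammas| runs recorded
  expect_true(all(!is.na(gs$table$mean_acc)))
})

test_that("the window grid has 11 candidates and picks the shortest argmax", {
  expect_equal(seq(0.5, 1, by = 0.05), c(0.50, 0.55, 0.60, 0.65, 0.70, 0.75,
                                         0.80, 0.85, 0.90, 0.95, 1.00))
  # shortest-max rule exercised on a reduced grid with real reports
  opt <- optimize_window_length(fix_calib_epochs(), mrcp_ch(),
                                wl_grid = c(0.5, 0.75, 1), Cs = 100,
                                gammas = 0.5, n_folds = 3, seed = 6)
  expect_equal(opt$wl_o_s,
               opt$table$wl_s[which(opt$table$auc == max(opt$table$auc))[1]])
  expect_equal(nrow(opt$table), 3)
})

test_that("final model selection takes the best fold, first on ties", {
  cv <- pseudo_online_cv(fix_calib_epochs(), 0.8, mrcp_ch(), C = 100,
                         gamma = 0.5, n_folds = 5, seed = 3)
  m <- select_final_model(cv)
  expect_equal(m$fold, which.max(cv$fold_acc))
  expect_equal(m$fold_acc, max(cv$fold_acc))
  # tie handling: equalize accuracies and re-select
  cv2 <- cv
  cv2$fold_acc <- rep(0.8, 5)
  expect_equal(select_final_model(cv2)$fold, 1)
})

test_that("the selected model separates its own training windows sanely", {
  m <- fix_model()
  traces <- spatial_average(fix_calib_epochs(), mrcp_ch())
  n_w <- round(m$wl_s * 20) + 1
  go_idx <- which(fix_calib_epochs()$labels == "Go")
  probs <- vapply(go_idx, function(i) {
    w <- place_adaptive_window(traces[i, ], m$wl_s)
    if (is.null(w)) return(NA_real_)
    fx <- extract_features(matrix(window_values(traces[i, ], w), 1),
                           m$go_stats)
    svc_prob(m$svm, scale_apply(fx, m$scaling))
  }, 0)
  expect_gt(mean(probs >= 0.5, na.rm = TRUE), 0.8)
})

test_that("permutation p-values follow the add-one convention", {
  # fabricated nulls exercise the formula without CV cost
  ep <- fix_calib_epochs()
  obs <- pseudo_online_cv(ep, 0.6, mrcp_ch(), C = 10, gamma = 0.2,
                          n_folds = 3, seed = 2)
  pt <- permutation_test(ep, 0.6, mrcp_ch(), C = 10, gamma = 0.2,
                         n_perm = 5, seed = 2, observed = obs, n_folds = 3)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_acc >= pt$observed_acc)) / (1 + 5))
  expect_length(pt$null_acc, 5)
  # n_perm = 1 with observed > permuted: p = 0.5
  if (all(pt$null_acc[1] < obs$mean_acc)) {
    pt1 <- permutation_test(ep, 0.6, mrcp_ch(), C = 10, gamma = 0.2,
                            n_perm = 1, seed = 2, observed = obs, n_folds = 3)
    if (pt1$null_acc < pt1$observed_acc) expect_equal(pt1$p_value, 0.5)
  }
})

test_that("no test-trial look-ahead: future samples cannot change a decision", {
  # instrument a held-out trace: corrupt samples after placement j and check
  # the placement-j feature vector is untouched
  ep <- fix_calib_epochs()
  traces <- spatial_average(ep, mrcp_ch())
  tr <- traces[1, ]
  n_w <- 13
  sw <- sliding_windows(tr, n_w)
  j <- 10
  tr2 <- tr
  tr2[(sw$edges[j] + 1):length(tr2)] <- 1e6
  sw2 <- sliding_windows(tr2, n_w)
  expect_identical(sw$W[seq_len(j), ], sw2$W[seq_len(j), ])
})

test_that("models survive the JSON round trip", {
  m <- fix_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(svc_prob(back$svm, X), svc_prob(m$svm, X), tolerance = 1e-12)
  expect_equal(back$go_stats$mu, unname(m$go_stats$mu), tolerance = 1e-12)
  expect_equal(back$wl_s, m$wl_s)
  expect_equal(back$channels, m$channels)
})
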