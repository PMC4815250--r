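# ---- internal: training-set assembly ---------------------------------------

# Build windowed training vectors from spatial-average traces.
# Adaptive mode screens Go trials whose negative peak precedes -1.5 s.
build_training_windows <- function(traces, labels, idx, wl_s, mode,
                                   fs = 20, t0 = -2.5) {
  n_w <- round(wl_s * fs) + 1
  X <- matrix(0, 0, n_w)
  y <- integer(0)
  used <- integer(0)
  screened <- 0L
  for (i in idx) {
    tr <- traces[i, ]
    if (labels[i] == "Go") {
      spec <- if (mode == "adaptive")
        place_adaptive_window(tr, wl_s, fs, t0)
      else place_fixed_window(wl_s, "Go")
      if (is.null(spec)) { screened <- screened + 1L; next }
    } else {
      spec <- place_fixed_window(wl_s, "No-go")
    }
    X <- rbind(X, window_values(tr, spec, fs, t0))
    y <- c(y, if (labels[i] == "Go") 1L else -1L)
    used <- c(used, i)
  }
  list(X = X, y = y, used = used, screened = screened)
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

# ---- ROC --------------------------------------------------------------------

#' ROC curve and area from assigned trial probabilities
#'
#' Sweeps a threshold over the pooled trial-level P(Go) values; the area is
#' the trapezoidal integral of TPR against FPR.
#'
#' @param prob numeric vector of probabilities.
#' @param truth logical or factor: TRUE / "Go" for positive trials.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(prob, truth) {
  pos <- if (is.logical(truth)) truth else truth == "Go"
  np <- sum(pos)
  nn <- sum(!pos)
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(prob[pos] >= th) / np, 0)
  fpr <- vapply(thr, function(th) sum(prob[!pos] >= th) / nn, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

# ---- pseudo-online cross-validation -----------------------------------------

#' Simulated real-time (pseudo-online) stratified cross-validation
#'
#' Evaluates the Go/No-go classifier the way it will be deployed. Training
#' folds contribute one windowed feature vector per epoch (adaptive or fixed
#' Go window, fixed No-go window at -0.5 s before target onset); Go-cluster
#' statistics, feature z-scaling and the RBF-SVC are fitted per training
#' fold. Each held-out epoch is then classified by sliding a window of the
#' same length through it in 50 ms steps, chronologically: a placement is
#' "Go" when `P(Go | x) >= tau`. If three consecutive placements are Go the
#' trial is Go and receives the mean probability over those three
#' placements; otherwise it is No-go and receives the mean probability over
#' all its No-go placements. Adaptive screening (peak earlier than -1.5 s)
#' applies to training folds only -- an online system cannot screen unseen
#' trials.
#'
#' @param epochs an `epoch_set` (rejected epochs are excluded).
#' @param wl_s window length in seconds.
#' @param channels MRCP channel subset for the spatial average.
#' @param C,gamma SVC hyperparameters.
#' @param mode `"adaptive"` or `"fixed"` Go-window placement.
#' @param n_folds folds, default 10 (reduced with a warning when a class
#'   has fewer epochs than folds).
#' @param tau offline detection threshold, default 0.5.
#' @param consec consecutive Go placements required, default 3.
#' @param tick_s sliding step, default 0.05 s.
#' @param seed optional seed isolating the fold assignment and Platt splits.
#' @param ridge_eps ridge for the Go covariance, see [fit_go_stats()].
#' @param labels optional replacement label factor (used by the permutation
#'   test); defaults to `epochs$labels`.
#' @return object of class `cv_report`: fold accuracies, per-epoch assigned
#'   probabilities and decisions, ROC points, AUC, per-fold model artifacts.
#' @export
pseudo_online_cv <- function(epochs, wl_s, channels, C = 100, gamma = 0.5,
                             mode = c("adaptive", "fixed"), n_folds = 10,
                             tau = 0.5, consec = 3, tick_s = 0.05,
                             seed = NULL, ridge_eps = NULL, labels = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    labs <- if (is.null(labels)) epochs$labels else labels
    fs <- epochs$fs
    t0 <- epochs$t0
    traces <- spatial_average(epochs, channels)
    keep <- which(!epochs$rejected)
    go <- keep[labs[keep] == "Go"]
    ng <- keep[labs[keep] == "No-go"]
    k <- min(n_folds, length(go), length(ng))
    if (k < n_folds)
      warning("fewer than ", n_folds, " epochs in a class; using ", k, " folds")
    fold_go <- sample(rep_len(seq_len(k), length(go)))
    fold_ng <- sample(rep_len(seq_len(k), length(ng)))

    n_w <- round(wl_s * fs) + 1
    step <- max(1L, round(tick_s * fs))
    fold_acc <- numeric(k)
    fold_models <- vector("list", k)
    rows <- list()
    for (f in seq_len(k)) {
      tr_idx <- c(go[fold_go != f], ng[fold_ng != f])
      te_idx <- c(go[fold_go == f], ng[fold_ng == f])
      tw <- build_training_windows(traces, labs, tr_idx, wl_s, mode, fs, t0)
      if (sum(tw$y == 1) < 2 || sum(tw$y == -1) < 2)
        stop("too few training windows after screening; need >= 2 per class")
      gstats <- fit_go_stats(tw$X[tw$y == 1, , drop = FALSE], ridge_eps)
      feats <- extract_features(tw$X, gstats, dt = 1 / fs)
      sc <- scale_fit(feats)
      model <- svc_fit(scale_apply(feats, sc), tw$y, C, gamma)

      correct <- 0
      for (i in te_idx) {
        sw <- sliding_windows(traces[i, ], n_w, step)
        fx <- extract_features(sw$W, gstats, dt = 1 / fs)
        pr <- svc_prob(model, scale_apply(fx, sc))
        dec <- trial_decision(pr, tau, consec)
        correct <- correct + as.integer((dec$go && labs[i] == "Go") ||
                                        (!dec$go && labs[i] == "No-go"))
        rows[[length(rows) + 1]] <- data.frame(
          fold = f, epoch = i, trial_id = epochs$trial_ids[i],
          label = as.character(labs[i]),
          decision = if (dec$go) "Go" else "No-go", prob = dec$prob)
      }
      fold_acc[f] <- correct / length(te_idx)
      fold_models[[f]] <- list(svm = model, go_stats = gstats, scaling = sc,
                               screened = tw$screened)
    }
    tab <- do.call(rbind, rows)
    roc <- roc_curve(tab$prob, tab$label == "Go")
    structure(list(fold_acc = fold_acc, mean_acc = mean(fold_acc),
                   trials = tab, roc = roc$points, auc = roc$auc,
                   wl_s = wl_s, C = C, gamma = gamma, mode = mode,
                   tau = tau, consec = consec, n_folds = k,
                   fold_models = fold_models, channels = channels),
              class = "cv_report")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# trial-level decision from chronological placement probabilities
trial_decision <- function(pr, tau, consec) {
  go_flags <- pr >= tau
  run <- 0L
  for (j in seq_along(go_flags)) {
    run <- if (go_flags[j]) run + 1L else 0L
    if (run == consec) {
      return(list(go = TRUE, prob = mean(pr[(j - consec + 1):j]), at = j))
    }
  }
  nogo <- pr[!go_flags]
  list(go = FALSE, prob = if (length(nogo)) mean(nogo) else mean(pr), at = NA)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> wl = %.2f s (%s), C = %g, gamma = %g: mean acc %.1f%%, AUC %.3f\n",
              x$wl_s, x$mode, x$C, x$gamma, 100 * x$mean_acc, x$auc))
  invisible(x)
}

# ---- hyperparameter grid search ---------------------------------------------

#' Grid search over the C-SVC hyperparameters
#'
#' Evaluates every pair from `C in {10, 100, 1000}` x
#' `gamma in {0.2, 0.5, 0.8, 1}` with [pseudo_online_cv()] at one window
#' length and returns the pair maximizing mean fold accuracy; exact ties
#' break toward the smaller C, then the smaller gamma.
#'
#' @inheritParams pseudo_online_cv
#' @param Cs,gammas candidate grids.
#' @param ... forwarded to [pseudo_online_cv()].
#' @return list with `C`, `gamma`, `report` (the winning `cv_report`) and
#'   `table` (accuracy of every pair).
#' @export
grid_search <- function(epochs, wl_s, channels, Cs = c(10, 100, 1000),
                        gammas = c(0.2, 0.5, 0.8, 1), seed = NULL, ...) {
  best <- NULL
  tab <- expand.grid(C = sort(Cs), gamma = sort(gammas))
  tab <- tab[order(tab$C, tab$gamma), ]
  tab$mean_acc <- NA_real_
  tab$auc <- NA_real_
  for (r in seq_len(nrow(tab))) {
    rep_ <- pseudo_online_cv(epochs, wl_s, channels, C = tab$C[r],
                             gamma = tab$gamma[r], seed = seed, ...)
    tab$mean_acc[r] <- rep_$mean_acc
    tab$auc[r] <- rep_$auc
    if (is.null(best) || rep_$mean_acc > best$report$mean_acc)
      best <- list(C = tab$C[r], gamma = tab$gamma[r], report = rep_)
  }
  c(best, list(table = tab))
}

# ---- window-length optimization ---------------------------------------------

#' Optimize the feature-window length by ROC area
#'
#' Iterates the window length from 0.5 s to 1 s in 50 ms steps (11
#' candidates), runs the grid-searched pseudo-online CV at each, and selects
#' the shortest length attaining the maximum AUC as the optimal window
#' length `wl_O`.
#'
#' @inheritParams grid_search
#' @param wl_grid candidate lengths in seconds.
#' @return list with `wl_o_s`, `table` (per-length AUC/accuracy), and
#'   `reports` (winning `cv_report` per length).
#' @export
optimize_window_length <- function(epochs, channels,
                                   wl_grid = seq(0.5, 1, by = 0.05),
                                   seed = NULL, ...) {
  reports <- vector("list", length(wl_grid))
  tab <- data.frame(wl_s = wl_grid, auc = NA_real_, mean_acc = NA_real_,
                    C = NA_real_, gamma = NA_real_)
  for (i in seq_along(wl_grid)) {
    gs <- grid_search(epochs, wl_grid[i], channels, seed = seed, ...)
    reports[[i]] <- gs$report
    tab$auc[i] <- gs$report$auc
    tab$mean_acc[i] <- gs$report$mean_acc
    tab$C[i] <- gs$C
    tab$gamma[i] <- gs$gamma
  }
  best <- which(tab$auc == max(tab$auc))[1] # grid ascending: shortest argmax
  list(wl_o_s = wl_grid[best], table = tab, reports = reports,
       best_report = reports[[best]])
}

# ---- final model selection --------------------------------------------------

#' Package the best cross-validation fold as the deployable model
#'
#' Among the folds of the report at the optimal window length, the fold
#' with the highest accuracy (first fold on ties) supplies the trained SVC,
#' its Go-cluster statistics and feature scaling.
#'
#' @param report a `cv_report`.
#' @param tau offline/online detection threshold carried by the model.
#' @param tau_c,n_c online decision threshold and consecutive-window count
#'   (defaults mirror the offline rule: tau and 3).
#' @return object of class `calibrated_model`.
#' @export
select_final_model <- function(report, tau = 0.5, tau_c = tau, n_c = 3) {
  f <- which.max(report$fold_acc) # first maximum
  fm <- report$fold_models[[f]]
  structure(list(svm = fm$svm, go_stats = fm$go_stats, scaling = fm$scaling,
                 channels = report$channels, wl_s = report$wl_s,
                 mode = report$mode, tau = tau, tau_c = tau_c, n_c = n_c,
                 fold = f, fold_acc = report$fold_acc[f],
                 C = report$C, gamma = report$gamma),
            class = "calibrated_model")
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat(sprintf("<calibrated_model> %s window wl = %.2f s, C = %g, gamma = %g, fold acc %.1f%%, %d SVs\n",
              x$mode, x$wl_s, x$C, x$gamma, 100 * x$fold_acc, x$svm$n_sv))
  invisible(x)
}

#' Full calibration: window-length optimization plus model selection
#'
#' @inheritParams optimize_window_length
#' @param tau detection threshold stored on the model, default 0.5.
#' @return list with `model` (a `calibrated_model`), `wl_o_s`, `table`, and
#'   `reports` from the optimization loop.
#' @export
calibrate_model <- function(epochs, channels, wl_grid = seq(0.5, 1, by = 0.05),
                            tau = 0.5, seed = NULL, ...) {
  opt <- optimize_window_length(epochs, channels, wl_grid, seed = seed, ...)
  model <- select_final_model(opt$best_report, tau = tau)
  c(list(model = model), opt[c("wl_o_s", "table", "reports")])
}

# ---- channel selection (extension) ------------------------------------------

#' Greedy forward channel selection (extension)
#'
#' The reference procedure selects MRCP channels manually from
#' grand-average inspection; this optional helper automates the second step
#' by greedily adding the candidate channel that most improves mean
#' pseudo-online CV accuracy, stopping when no candidate improves it. It is
#' an extension, not part of the validated method.
#'
#' @param epochs an `epoch_set`.
#' @param candidates candidate channel labels.
#' @param wl_s window length used for scoring.
#' @param max_channels upper bound on the selected set size.
#' @param seed seed shared by all scoring CV runs.
#' @param ... forwarded to [pseudo_online_cv()] (e.g. `n_folds`, `C`).
#' @return list with `channels` (selected, in inclusion order) and `trace`
#'   (accuracy after each inclusion).
#' @export
select_channels_greedy <- function(epochs, candidates, wl_s = 0.8,
                                   max_channels = length(candidates),
                                   seed = 1, ...) {
  chosen <- character()
  best_acc <- -Inf
  trace <- numeric()
  while (length(chosen) < max_channels) {
    accs <- vapply(setdiff(candidates, chosen), function(ch) {
      pseudo_online_cv(epochs, wl_s, c(chosen, ch), seed = seed,
                       ...)$mean_acc
    }, 0)
    if (!length(accs) || max(accs) <= best_acc) break
    chosen <- c(chosen, names(accs)[which.max(accs)])
    best_acc <- max(accs)
    trace <- c(trace, best_acc)
  }
  list(channels = chosen, trace = trace)
}

# ---- permutation test -------------------------------------------------------

#' Label-permutation significance test for the classifier
#'
#' Shuffles the Go/No-go labels, repeats the full stratified pseudo-online
#' cross-validation for each permutation, and compares the observed mean
#' accuracy with the null distribution. The empirical p-value uses the
#' add-one correction `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams pseudo_online_cv
#' @param n_perm number of permutations (paper-scale 1000; 200 by default
#'   for desk-scale runs).
#' @param seed seed for the observed CV, the shuffles, and each
#'   permutation's CV.
#' @param observed optionally, a precomputed observed `cv_report` to reuse.
#' @param ... forwarded to [pseudo_online_cv()].
#' @return list with `p_value`, `observed_acc`, `null_acc` (length
#'   `n_perm`), `n_perm`.
#' @export
permutation_test <- function(epochs, wl_s, channels, C = 100, gamma = 0.5,
                             n_perm = 200, seed = 1, observed = NULL, ...) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(observed))
    observed <- pseudo_online_cv(epochs, wl_s, channels, C = C, gamma = gamma,
                                 seed = seed, ...)
  null_acc <- with_seed(seed + 1, {
    vapply(seq_len(n_perm), function(p) {
      shuffled <- factor(sample(as.character(epochs$labels)),
                         levels = levels(epochs$labels))
      rep_ <- pseudo_online_cv(epochs, wl_s, channels, C = C, gamma = gamma,
                               labels = shuffled, ...)
      rep_$mean_acc
    }, 0)
  })
  list(p_value = (1 + sum(null_acc >= observed$mean_acc)) / (1 + n_perm),
       observed_acc = observed$mean_acc, null_acc = null_acc, n_perm = n_perm)
}

# ---- model serialization ----------------------------------------------------

#' Save or load a calibrated model as portable JSON
#'
#' Scalars, vectors and the support-vector matrix are written as plain JSON
#' so a model calibrated on one machine replays on another.
#'
#' @param model a `calibrated_model`.
#' @param path JSON file path.
#' @return `load_model` returns the `calibrated_model`.
#' @export
save_model <- function(model, path) {
  x <- list(
    sv = model$svm$sv, coef = model$svm$coef, rho = model$svm$rho,
    C = model$C, gamma = model$gamma, platt = as.list(model$svm$platt),
    mu = model$go_stats$mu, sigma = model$go_stats$sigma,
    ridge_eps = model$go_stats$ridge_eps,
    center = model$scaling$center, scale = model$scaling$scale,
    channels = model$channels, wl_s = model$wl_s, mode = model$mode,
    tau = model$tau, tau_c = model$tau_c, n_c = model$n_c)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs <- fit_from_saved_stats(x$mu, as.matrix(x$sigma), x$ridge_eps)
  svm <- structure(list(sv = as.matrix(x$sv), coef = x$coef, rho = x$rho,
                        C = x$C, gamma = x$gamma,
                        platt = c(A = x$platt$A, B = x$platt$B),
                        n_sv = length(x$coef)), class = "svc_model")
  structure(list(svm = svm, go_stats = gs,
                 scaling = list(center = x$center, scale = x$scale),
                 channels = x$channels, wl_s = x$wl_s, mode = x$mode,
                 tau = x$tau, tau_c = x$tau_c, n_c = x$n_c,
                 C = x$C, gamma = x$gamma, fold = NA, fold_acc = NA),
            class = "calibrated_model")
}

fit_from_saved_stats <- function(mu, sigma, ridge_eps) {
  inv <- solve(sigma + diag(ridge_eps, length(mu)))
  structure(list(mu = mu, sigma = sigma, sigma_inv = inv,
                 ridge_eps = ridge_eps, n = NA), class = "go_stats")
}
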