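#' C-SVC with RBF kernel and probability outputs
#'
#' Binary soft-margin support vector classification with the Gaussian
#' kernel `K(xi, xj) = exp(-gamma ||xi - xj||^2)`, solved by sequential
#' minimal optimization (maximal-violating-pair working-set selection, the
#' LIBSVM dual formulation and stopping rule). Probability estimates
#' `P(y = +1 | x)` come from a Platt sigmoid `1 / (1 + exp(A f + B))`
#' fitted to decision values; as in LIBSVM the sigmoid is trained on
#' cross-validated decision values to avoid the overconfidence of in-sample
#' margins.
#'
#' @param x numeric feature matrix (rows = samples). Scale features before
#'   fitting; the calibration layer z-scores per training fold.
#' @param y labels: +1/-1 vector, or a factor whose first level maps to +1.
#' @param C regularization constant (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param probability fit the Platt sigmoid, default TRUE.
#' @param platt_folds folds for the sigmoid's cross-validated decision
#'   values, default 5 (uses the current RNG stream).
#' @param eps SMO stopping tolerance, default 1e-3.
#' @return object of class `svc_model`: support vectors, `coef`
#'   (`alpha_i y_i`), `rho`, kernel parameters, Platt coefficients.
#' @export
svc_fit <- function(x, y, C, gamma, probability = TRUE, platt_folds = 5,
                    eps = 1e-3) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], 1L, -1L)
  y <- as.integer(y)
  stopifnot(all(y %in% c(-1L, 1L)), length(y) == nrow(x))
  if (length(unique(y)) < 2) stop("both classes required to fit the SVC")

  fit <- smo_fit_cpp(x, y, C, gamma, eps = eps)
  sv <- fit$alpha > 1e-12
  platt <- NULL
  if (probability) {
    dec <- platt_cv_decisions(x, y, C, gamma, platt_folds, eps)
    platt <- platt_fit(dec, y)
  }
  structure(list(sv = x[sv, , drop = FALSE], coef = (fit$alpha * y)[sv],
                 rho = fit$rho, C = C, gamma = gamma, platt = platt,
                 n_sv = sum(sv), iter = fit$iter), class = "svc_model")
}

# decision values on held-out folds, for sigmoid training
platt_cv_decisions <- function(x, y, C, gamma, folds, eps) {
  n <- nrow(x)
  fold_id <- sample(rep_len(seq_len(folds), n))
  dec <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2) { # degenerate tiny split: fall back
      dec[!tr] <- 0
      next
    }
    fit <- smo_fit_cpp(x[tr, , drop = FALSE], y[tr], C, gamma, eps = eps)
    svi <- fit$alpha > 1e-12
    m <- list(sv = x[tr, , drop = FALSE][svi, , drop = FALSE],
              coef = (fit$alpha * y[tr])[svi], rho = fit$rho, gamma = gamma)
    dec[!tr] <- svc_decision_raw(m, x[!tr, , drop = FALSE])
  }
  dec
}

# Platt (1999) sigmoid fit with the Lin-Weng-Keerthi Newton iteration
platt_fit <- function(dec, y, max_iter = 100, min_step = 1e-10, sigma = 1e-12) {
  prior1 <- sum(y > 0)
  prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      nA <- A + step * dA
      nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  c(A = A, B = B)
}

svc_decision_raw <- function(model, x) {
  d2 <- outer(rowSums(x^2), rowSums(model$sv^2), "+") -
    2 * x %*% t(model$sv)
  as.numeric(exp(-model$gamma * pmax(d2, 0)) %*% model$coef) - model$rho
}

#' Decision values and class probabilities of a fitted SVC
#'
#' @param model an `svc_model`.
#' @param x matrix of samples (same feature space and scaling as training).
#' @return `svc_decision`: signed decision values (positive = class +1).
#'   `svc_prob`: Platt probabilities `P(y = +1 | x)`.
#' @export
svc_decision <- function(model, x) {
  svc_decision_raw(model, as.matrix(x))
}

#' @rdname svc_decision
#' @export
svc_prob <- function(model, x) {
  if (is.null(model$platt)) stop("model was fitted without probability = TRUE")
  f <- svc_decision(model, x)
  fApB <- model$platt["A"] * f + model$platt["B"]
  unname(ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB))))
}
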