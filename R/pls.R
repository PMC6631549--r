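# PLS1 regression (NIPALS) of survival on a gene subset, and subset scoring
# by two-fold cross-validated squared Pearson correlation (2-FCV R^2).
# Subsets are small (1-20 genes) and samples few (tens), so a plain-R NIPALS
# with the deflation loop is both exact and fast; with as many components as
# predictors on full-rank data it reproduces the OLS fit.

# core NIPALS PLS1 on a plain numeric matrix; no validation, hot path.
# Returns coefficients on the original predictor scale plus intercept.
.pls_core <- function(X, y, ncomp, scale = TRUE) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  Xc <- X - rep(xm, each = n)
  if (scale) {
    xs <- sqrt(colSums(Xc^2) / (n - 1))
    xs[xs == 0] <- 1                       # constant column: weight ends up 0
    Xc <- Xc / rep(xs, each = n)
  } else {
    xs <- rep(1, p)
  }
  ym <- mean(y)
  yc <- y - ym
  ncomp <- max(0L, min(ncomp, p, n - 1L))
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  a <- 0L
  tol <- 1e-12
  while (a < ncomp) {
    w <- crossprod(Xc, yc)                 # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < tol) break
    pv <- crossprod(Xc, tt) / t2
    qa <- sum(yc * tt) / t2
    Xc <- Xc - tt %*% t(pv)
    yc <- yc - qa * tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- pv; qv[a] <- qa
  }
  if (a == 0L) {
    beta_s <- rep(0, p)
  } else {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    beta_s <- W %*% solve(crossprod(P, W), qv[seq_len(a)])
  }
  beta <- as.vector(beta_s) / xs
  list(coefficients = beta, intercept = ym - sum(xm * beta),
       x_means = xm, x_scales = xs, y_mean = ym,
       weights = W, loadings = P, y_loadings = qv[seq_len(a)],
       n_components = a)
}

#' Fit a PLS1 regression of survival on a gene subset
#'
#' NIPALS partial least squares with a univariate response: predictors are
#' centered (and by default autoscaled to unit variance), components are
#' extracted by iterative deflation, and the regression coefficients are
#' folded back to the original predictor scale. With `n_components` equal to
#' the number of (full-rank) predictors the fit reproduces ordinary least
#' squares. A constant predictor column receives weight 0 and is effectively
#' excluded.
#'
#' @param X Numeric samples x genes matrix (the subset's expression).
#' @param y Numeric survival vector; must not be constant.
#' @param n_components Requested number of latent components; automatically
#'   capped at `min(ncol(X), nrow(X) - 1)`.
#' @param scale Autoscale predictors to unit variance (default `TRUE`).
#' @return An object of class `pls_fit`: `coefficients`, `intercept`,
#'   centering/scaling constants, NIPALS weights/loadings, and the number of
#'   components actually extracted.
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
#' y <- 3 * X[, 1] - X[, 2] + rnorm(20, 0, 0.1)
#' fit <- fit_pls(X, y, n_components = 2)
#' cor(predict(fit, X), y)^2
#' @export
fit_pls <- function(X, y, n_components = 3, scale = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y)) .fail("'X' and 'y' must be numeric")
  if (nrow(X) != length(y)) .fail("nrow(X) must equal length(y)")
  if (stats::sd(y) == 0) .fail("'y' must not be constant")
  .check_count(n_components, "n_components", min = 1)
  fit <- .pls_core(X, y, as.integer(n_components), scale = scale)
  fit$gene_ids <- colnames(X)
  class(fit) <- "pls_fit"
  fit
}

#' Predict survival estimates from a fitted PLS model
#'
#' Linear prediction `intercept + X_new %*% coefficients`. Predictions are
#' not clamped to `[0, 100]`: downstream scoring uses a scale-free
#' correlation and clamping would silently change it.
#'
#' @param object A [fit_pls()] result.
#' @param newdata Numeric matrix whose columns match the fitted subset.
#' @param ... Unused.
#' @return Numeric vector of survival estimates.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    .fail("newdata has %d columns; the model was fitted on %d",
          ncol(newdata), length(object$coefficients))
  }
  if (!is.null(object$gene_ids) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$gene_ids)) {
    .fail("newdata columns do not match the fitted gene subset")
  }
  as.vector(object$intercept + newdata %*% object$coefficients)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d predictor(s), %d component(s)\n",
              length(x$coefficients), x$n_components))
  invisible(x)
}

#' Squared Pearson correlation between observed and estimated survival
#'
#' Returns `cor(y, y_hat)^2`; if either vector is constant the score is
#' defined as 0 (a constant estimate carries no predictive information).
#'
#' @param y,y_hat Numeric vectors of equal length (>= 3).
#' @return A number in `[0, 1]`.
#' @examples
#' r_squared(c(1, 2, 3), c(2, 4, 6))
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) .fail("'y' and 'y_hat' lengths differ")
  if (length(y) < 3) .fail("need >= 3 observations")
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) return(0)
  stats::cor(y, y_hat)^2
}

# fast unvalidated 2-FCV given a permutation of 1..n defining the split;
# first ceiling(n/2) entries are fold d0.  Pools out-of-fold estimates and
# returns the squared Pearson correlation with y.
.cv_r2_split <- function(X, y, ncomp, perm, scale = TRUE) {
  n <- length(y)
  h <- ceiling(n / 2)
  i0 <- perm[seq_len(h)]
  i1 <- perm[(h + 1):n]
  f0 <- .pls_core(X[i0, , drop = FALSE], y[i0], ncomp, scale = scale)
  f1 <- .pls_core(X[i1, , drop = FALSE], y[i1], ncomp, scale = scale)
  yhat <- numeric(n)
  yhat[i1] <- f0$intercept + X[i1, , drop = FALSE] %*% f0$coefficients
  yhat[i0] <- f1$intercept + X[i0, , drop = FALSE] %*% f1$coefficients
  if (stats::sd(yhat) == 0) return(0)
  stats::cor(y, yhat)^2
}

#' Two-fold cross-validated R-squared of a PLS model
#'
#' Randomly splits the samples into two (near-)equal folds d0 and d1, fits
#' the PLS model on each fold and predicts the other, pools all out-of-fold
#' estimates, and returns the squared Pearson correlation between observed
#' survival and the pooled estimates (2-FCV R^2). Deterministic per seed.
#'
#' @inheritParams fit_pls
#' @param seed Integer seed for the random split.
#' @return A list of class `cv_score`: `r2`, `fold_assignment` (1/2 per
#'   sample), `seed`, `n_runs = 1`, `per_run_r2`.
#' @export
two_fold_cv <- function(X, y, n_components = 3, seed = 1, scale = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) .fail("nrow(X) must equal length(y)")
  if (n < 4) .fail("two-fold CV needs folds of >= 2 samples (n >= 4)")
  perm <- withr::with_seed(seed, sample.int(n))
  r2 <- .cv_r2_split(X, y, n_components, perm, scale = scale)
  fold <- integer(n)
  fold[perm[seq_len(ceiling(n / 2))]] <- 1L
  fold[fold == 0L] <- 2L
  structure(list(r2 = r2, fold_assignment = fold, seed = as.integer(seed),
                 n_runs = 1L, per_run_r2 = r2), class = "cv_score")
}

#' Repeated two-fold cross-validation
#'
#' Averages the 2-FCV R^2 over `n_runs` independent random splits (seeds
#' `base_seed, base_seed + 1, ...`); the aggregate score is the arithmetic
#' mean of the per-run scores.
#'
#' @inheritParams two_fold_cv
#' @param n_runs Number of independent splits, default 10.
#' @param base_seed Seed of the first split.
#' @return A `cv_score` whose `r2` is the mean of `per_run_r2`.
#' @export
repeated_cv <- function(X, y, n_components = 3, n_runs = 10, base_seed = 1,
                        scale = TRUE) {
  .check_count(n_runs, "n_runs", min = 1)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) .fail("nrow(X) must equal length(y)")
  if (n < 4) .fail("two-fold CV needs folds of >= 2 samples (n >= 4)")
  per <- vapply(seq_len(n_runs), function(k) {
    perm <- withr::with_seed(as.integer(base_seed) + k - 1L, sample.int(n))
    .cv_r2_split(X, y, n_components, perm, scale = scale)
  }, numeric(1))
  structure(list(r2 = mean(per), fold_assignment = NULL,
                 seed = as.integer(base_seed), n_runs = as.integer(n_runs),
                 per_run_r2 = per), class = "cv_score")
}
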