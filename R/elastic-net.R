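#' Fit an elastic-net linear model by cyclic coordinate descent
#'
#' Minimizes \deqn{\frac{1}{2n}\sum_i (y_i - \hat y_i)^2 +
#'   \lambda\left(\alpha \|w\|_1 + \frac{1-\alpha}{2}\|w\|_2^2\right)}
#' by cyclic coordinate descent with soft-thresholding. Predictors are
#' standardized internally (mean 0, sd 1 with denominator `n`) and the
#' returned weights are back-transformed to the original predictor scale.
#'
#' Convergence requires the maximum coefficient change in a sweep to fall
#' below `tol` and the KKT stationarity residual of every coordinate to be
#' at most `kkt_tol`.
#'
#' @param X numeric matrix, n samples by p predictors.
#' @param y numeric response vector of length n.
#' @param alpha penalty mixing weight in \[0, 1\]; 1 = lasso, 0 = ridge.
#' @param lambda penalty strength (single non-negative value, or a
#'   decreasing vector fit with warm starts).
#' @param standardize standardize columns before fitting (default TRUE).
#' @param intercept fit an unpenalized intercept (default TRUE).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum coordinate-descent sweeps per lambda.
#' @param kkt_tol tolerance on the KKT stationarity residual at return.
#' @param record_objective record the penalized objective after every sweep.
#'
#' @return A list with elements `intercept` (scalar, or vector along the
#'   lambda path), `weights` (p-vector, or p x nlambda matrix), `lambda`,
#'   `alpha`, `niter`, `kkt_max`, `dropped` (names/indices of
#'   constant-variance columns excluded from the fit, weight 0), and
#'   `objective_trace` when requested.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda,
                            standardize = TRUE, intercept = TRUE,
                            tol = 1e-7, max_iter = 100000L, kkt_tol = 1e-6,
                            record_objective = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("elastic net requires at least 2 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite values in X or y")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  xbar <- colMeans(X)
  xsd <- sqrt(colMeans(X^2) - xbar^2)  # denominator-n sd
  const_cols <- which(xsd < 1e-12)
  if (length(const_cols) > 0L) {
    warning(sprintf("%d constant-variance column(s) excluded from fit", length(const_cols)))
  }

  if (intercept) {
    ybar <- mean(y)
    yc <- y - ybar
    Xc <- sweep(X, 2L, xbar, "-")
  } else {
    ybar <- 0
    yc <- y
    Xc <- X
  }
  if (standardize) {
    scale_fac <- ifelse(xsd < 1e-12, 1, xsd)
    Xw <- sweep(Xc, 2L, scale_fac, "/")
  } else {
    scale_fac <- rep(1, p)
    Xw <- Xc
  }
  v <- colMeans(Xw^2)
  v[const_cols] <- 0  # kernel skips these

  fit <- enet_cd_path(Xw, yc, alpha, lambda, v, tol, as.integer(max_iter),
                      kkt_tol, record_objective)
  beta_std <- fit$beta
  weights <- beta_std / scale_fac
  ints <- ybar - as.numeric(crossprod(xbar, weights))
  rownames(weights) <- colnames(X)

  out <- list(
    intercept = if (length(lambda) == 1L) ints[1L] else ints,
    weights = if (length(lambda) == 1L) weights[, 1L] else weights,
    lambda = lambda, alpha = alpha,
    niter = fit$niter, kkt_max = fit$kkt_max,
    dropped = const_cols
  )
  if (record_objective) {
    out$objective_trace <- if (length(lambda) == 1L) fit$obj_traces[[1L]] else fit$obj_traces
  }
  out
}

#' Log-spaced lambda path for the elastic net
#'
#' The first (largest) value is the smallest lambda at which every
#' coefficient is zero, `lambda_max = max |x_j' y_c| / (n * max(alpha, 1e-3))`
#' computed on the standardized predictors; the path descends
#' log-uniformly to `lambda_min_ratio * lambda_max`.
#'
#' @inheritParams fit_elastic_net
#' @param nlambda number of path values (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @return decreasing numeric vector of length `nlambda`.
#' @export
lambda_path <- function(X, y, alpha = 0.5, nlambda = 100L,
                        lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  xbar <- colMeans(X)
  xsd <- sqrt(colMeans(X^2) - xbar^2)
  keep <- xsd >= 1e-12
  yc <- y - mean(y)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, xbar[keep], "-"),
              2L, xsd[keep], "/")
  lam_max <- max(abs(crossprod(Xs, yc))) / (n * max(alpha, 1e-3))
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
}

#' Select the elastic-net penalty strength by cross-validation
#'
#' Evaluates a log-spaced lambda path by leave-one-out or k-fold
#' cross-validation and returns the lambda minimizing the mean squared
#' prediction error (`rule = "min"`, the default). Ties on the CV error
#' curve are broken toward the larger lambda (sparser model).
#' `rule = "1se"` instead returns the largest lambda whose CV error is
#' within one standard error of the minimum — the usual convention when a
#' sparser model is preferred under a noisy error curve.
#'
#' The fold fits used to trace the CV error curve run at the looser
#' tolerance `cv_tol`: the curve is insensitive to coefficient error far
#' below the fold-to-fold prediction noise, and the model actually
#' returned to the user is always refit at full tolerance.
#'
#' @inheritParams fit_elastic_net
#' @param folds `"loo"` for leave-one-out, or an integer k >= 2 for k-fold.
#' @param nlambda,lambda_min_ratio path construction, see [lambda_path()].
#' @param seed optional seed controlling the k-fold shuffle.
#' @param cv_tol coordinate-change tolerance for the fold fits.
#' @param rule `"min"` or `"1se"`.
#' @return list with `lambda` (selected value), `lambda_path`, `cv_mse`,
#'   `cv_se`.
#' @export
select_lambda <- function(X, y, alpha = 0.5, folds = "loo",
                          nlambda = 100L, lambda_min_ratio = 1e-3,
                          seed = NULL, cv_tol = 1e-4,
                          rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (identical(folds, "loo")) {
    fold_id <- seq_len(n)
    k <- n
  } else {
    k <- as.integer(folds)
    if (is.na(k) || k < 2L) stop("folds must be \"loo\" or an integer >= 2")
    if (n < k) stop("fewer samples than folds")
    if (!is.null(seed)) set.seed(seed)
    fold_id <- sample(rep_len(seq_len(k), n))
  }
  if (n < 2L || (k == n && n < 3L)) stop("too few samples for cross-validation")

  lams <- lambda_path(X, y, alpha, nlambda, lambda_min_ratio)
  sq_err <- matrix(NA_real_, n, length(lams))
  for (f in seq_len(k)) {
    test <- which(fold_id == f)
    Xtr <- X[-test, , drop = FALSE]
    ytr <- y[-test]
    fit <- fit_elastic_net(Xtr, ytr, alpha = alpha, lambda = lams,
                           tol = cv_tol, kkt_tol = max(1e-6, cv_tol * 10))
    pred <- sweep(X[test, , drop = FALSE] %*% fit$weights, 2L,
                  fit$intercept, "+")
    sq_err[test, ] <- (pred - y[test])^2
  }
  cvm <- colMeans(sq_err)
  # standard error of the CV curve: over fold means for k-fold, over
  # per-observation errors for LOO
  if (k == n) {
    cvse <- apply(sq_err, 2L, stats::sd) / sqrt(n)
  } else {
    fold_means <- apply(sq_err, 2L, function(e) {
      tapply(e, fold_id, mean)
    })
    cvse <- apply(fold_means, 2L, stats::sd) / sqrt(k)
  }
  cutoff <- if (rule == "min") min(cvm) + 1e-15 else {
    i_min <- which.min(cvm)
    cvm[i_min] + cvse[i_min]
  }
  best <- which(cvm <= cutoff)[1L]  # path is decreasing: first = largest
  list(lambda = lams[best], lambda_path = lams, cv_mse = cvm, cv_se = cvse)
}
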