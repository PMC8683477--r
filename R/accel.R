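#' Epigenetic age acceleration
#'
#' Three definitions are available. `"residual"` (default): residuals of
#' an OLS regression of predicted age on chronological age, so
#' acceleration is exactly uncorrelated with chronological age.
#' `"difference"`: predicted minus chronological age.
#' `"residual_methods_literal"`: residuals of chronological age regressed
#' on predicted age, sign-flipped so that positive values still mean
#' biologically older than expected.
#'
#' @param predicted predicted (epigenetic) ages, years.
#' @param chronological chronological ages, years.
#' @param method one of `"residual"`, `"difference"`,
#'   `"residual_methods_literal"`.
#' @return numeric vector of age-acceleration values.
#' @export
compute_accel <- function(predicted, chronological,
                          method = c("residual", "difference",
                                     "residual_methods_literal")) {
  method <- match.arg(method)
  if (length(predicted) != length(chronological)) stop("length mismatch")
  if (method == "difference") return(predicted - chronological)
  if (length(predicted) < 3L) stop("residual method requires >= 3 samples")
  if (method == "residual") {
    if (stats::sd(chronological) == 0) stop("zero variance in chronological age")
    return(unname(stats::resid(stats::lm(predicted ~ chronological))))
  }
  if (stats::sd(predicted) == 0) stop("zero variance in predicted age")
  -unname(stats::resid(stats::lm(chronological ~ predicted)))
}

#' Ordinary least squares with retained design
#'
#' Fits y = intercept + X b by QR-decomposition least squares
#' (via `stats::lm`), keeping the design matrix and residuals so robust
#' covariances can be formed afterwards. A rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param y response vector.
#' @param X numeric matrix of predictors (no intercept column; one is
#'   added), with column names.
#' @return object of class `ols_fit`: `coefficients`, `vcov_classical`,
#'   `se`, `t`, `p` (Student-t, n - k df), `residuals`, `fitted`, `X`
#'   (with intercept), `df_residual`, `sigma2`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n <= ncol(X) + 1L) stop("too few observations for the design")
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[(qx$rank + 1L):ncol(Xi)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(Xi, y)
  e <- fit$residuals
  k <- ncol(Xi)
  df <- n - k
  sigma2 <- sum(e^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xi), colnames(Xi))
  vc <- sigma2 * xtx_inv
  se <- sqrt(diag(vc))
  tt <- fit$coefficients / se
  structure(list(
    coefficients = fit$coefficients, vcov_classical = vc,
    se = se, t = tt, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
    residuals = e, fitted = fit$fitted.values, X = Xi,
    df_residual = df, sigma2 = sigma2, xtx_inv = xtx_inv
  ), class = "ols_fit")
}

#' Heteroskedasticity-robust (sandwich) covariance for an OLS fit
#'
#' Huber-White estimator `(X'X)^-1 X' diag(w) X (X'X)^-1` with
#' `w_i = e_i^2` (HC0), `e_i^2 * n/(n-k)` (HC1) or
#' `e_i^2 / (1 - h_i)^2` (HC3, the small-sample default; `h_i` is the
#' leverage). t statistics and two-sided p-values are recomputed on the
#' Student-t reference with n - k degrees of freedom.
#'
#' @param fit an [ols_fit()].
#' @param flavor `"HC0"`, `"HC1"` or `"HC3"`.
#' @return the fit with elements `vcov_robust`, `se_robust`, `t_robust`,
#'   `p_robust` and `hc_flavor` added.
#' @export
robust_vcov <- function(fit, flavor = c("HC3", "HC0", "HC1")) {
  flavor <- match.arg(flavor)
  X <- fit$X
  e <- fit$residuals
  n <- nrow(X)
  k <- ncol(X)
  w <- switch(flavor,
    HC0 = e^2,
    HC1 = e^2 * n / (n - k),
    HC3 = {
      h <- rowSums((X %*% fit$xtx_inv) * X)
      if (any(h >= 1 - 1e-12)) {
        stop("leverage of 1 (perfect-fit point); HC3 undefined")
      }
      e^2 / (1 - h)^2
    })
  meat <- crossprod(X * w, X)
  vc <- fit$xtx_inv %*% meat %*% fit$xtx_inv
  vc <- (vc + t(vc)) / 2
  se <- sqrt(diag(vc))
  tt <- fit$coefficients / se
  fit$vcov_robust <- vc
  fit$se_robust <- se
  fit$t_robust <- tt
  fit$p_robust <- 2 * stats::pt(abs(tt), fit$df_residual, lower.tail = FALSE)
  fit$hc_flavor <- flavor
  fit
}

#' Age-acceleration vs inbreeding association grid
#'
#' Runs the 2 x 2 grid of linear models — (clock, pacemaker) age
#' acceleration against (F, F_ROH) — each of the form
#' `accel ~ sex + age + inbreeding + age:inbreeding` with
#' heteroskedasticity-robust standard errors, and returns a tidy
#' coefficient table. Samples missing any variable (or listed in
#' `exclude_ids`) are dropped with a count reported.
#'
#' @param accel data.frame with columns `sample_id`, `age`, `sex`
#'   (`"F"`/`"M"` or 0/1), `accel_ec`, `accel_epm`.
#' @param inbreeding data.frame with columns `sample_id`, `f`, `froh`.
#' @param hc_flavor robust covariance flavor (default `"HC3"`).
#' @param exclude_ids ids excluded before fitting (e.g. documented
#'   outliers).
#' @return list with `tidy` (one row per model per coefficient: `accel`,
#'   `inbreeding`, `term`, `estimate`, `se_classical`, `se_robust`, `t`,
#'   `p`) and `fits` (the four robust [ols_fit()] objects).
#' @export
run_inbreeding_analysis <- function(accel, inbreeding, hc_flavor = "HC3",
                                    exclude_ids = character(0)) {
  d <- merge(accel, inbreeding, by = "sample_id")
  d <- d[!d$sample_id %in% exclude_ids, , drop = FALSE]
  sex_num <- if (is.numeric(d$sex)) d$sex else as.numeric(d$sex == "M")
  d$sex_num <- sex_num
  complete <- stats::complete.cases(d[, c("age", "sex_num", "accel_ec",
                                          "accel_epm", "f", "froh")])
  n_drop <- sum(!complete) + (nrow(accel) - nrow(d))
  if (n_drop > 0L) {
    message(sprintf("run_inbreeding_analysis: dropped %d sample(s) (unjoinable, excluded or incomplete)",
                    n_drop))
  }
  d <- d[complete, , drop = FALSE]
  if (nrow(d) < 10L) stop("refusing to fit: fewer than 10 joined samples")

  grid <- expand.grid(accel = c("accel_ec", "accel_epm"),
                      inbreeding = c("f", "froh"), stringsAsFactors = FALSE)
  fits <- list()
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    fvar <- d[[grid$inbreeding[g]]]
    X <- cbind(sex = d$sex_num, age = d$age, inbreeding = fvar,
               `age:inbreeding` = d$age * fvar)
    fit <- robust_vcov(ols_fit(d[[grid$accel[g]]], X), hc_flavor)
    key <- paste(grid$accel[g], grid$inbreeding[g], sep = "~")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      accel = grid$accel[g], inbreeding = grid$inbreeding[g],
      term = names(fit$coefficients),
      estimate = unname(fit$coefficients),
      se_classical = unname(fit$se), se_robust = unname(fit$se_robust),
      t = unname(fit$t_robust), p = unname(fit$p_robust),
      stringsAsFactors = FALSE)
  }
  list(tidy = do.call(rbind, c(rows, make.row.names = FALSE)), fits = fits,
       n = nrow(d))
}
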