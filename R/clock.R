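#' Transform chronological age for clock fitting
#'
#' Square-root transforming age before fitting linearizes the
#' fast-early / slow-late relationship between methylation and age in
#' growing animals.
#'
#' @param age age(s) in years.
#' @param mode `"sqrt"` or `"identity"`.
#' @param offset additive offset in years applied before the transform;
#'   `age + offset` must be non-negative under `sqrt`.
#' @return transformed age(s).
#' @export
transform_age <- function(age, mode = "sqrt", offset = 0) {
  if (mode == "identity") return(age + offset)
  if (mode != "sqrt") stop("unknown transform mode: ", mode)
  if (any(age + offset < 0)) stop("age + offset must be >= 0 for sqrt transform")
  sqrt(age + offset)
}

#' Invert the age transform back to years
#'
#' Exact right-inverse of [transform_age()] on the valid domain. Negative
#' transformed predictions (possible when a clock extrapolates, e.g. in
#' cross-species application) are clamped to 0 years and flagged in the
#' `"clamped"` attribute.
#'
#' @param t transformed age(s).
#' @param mode,offset as in [transform_age()].
#' @return ages in years, with logical attribute `clamped`.
#' @export
inverse_transform_age <- function(t, mode = "sqrt", offset = 0) {
  if (mode == "identity") {
    out <- t - offset
    attr(out, "clamped") <- rep(FALSE, length(t))
    return(out)
  }
  if (mode != "sqrt") stop("unknown transform mode: ", mode)
  clamped <- t < 0
  out <- pmax(t, 0)^2 - offset
  neg <- out < 0
  out[neg] <- 0
  attr(out, "clamped") <- clamped | neg
  out
}

.clock_design <- function(beta, sheet, config) {
  if (!is.null(config$tissue)) {
    sheet <- sheet[sheet$tissue == config$tissue, , drop = FALSE]
    if (nrow(sheet) == 0L) stop("no samples after tissue filter: ", config$tissue)
  }
  common <- intersect(sheet$sample_id, rownames(beta))
  if (length(common) < nrow(sheet)) {
    stop("sample sheet contains ids absent from the beta matrix: ",
         paste(setdiff(sheet$sample_id, common), collapse = ", "))
  }
  sheet <- sheet[match(common, sheet$sample_id), , drop = FALSE]
  X <- drop_incomplete_sites(beta[common, , drop = FALSE])
  list(X = X, sheet = sheet,
       y = transform_age(sheet$age, config$transform, config$offset))
}

#' Train an elastic-net epigenetic clock
#'
#' Selects the penalty strength by cross-validation on the full training
#' set ([select_lambda()]), then fits the elastic net at that lambda and
#' returns the sparse clock (nonzero coefficients only) on the
#' transformed-age scale.
#'
#' @param beta samples x sites beta matrix.
#' @param sheet sample sheet ([read_sample_sheet()]); `sheet$sample_id`
#'   must all be present in `beta`.
#' @param config clock configuration block (see [default_config()]);
#'   `config$tissue`, when set, restricts training to that tissue.
#' @return a [clock_model()].
#' @export
train_clock <- function(beta, sheet, config = default_config()$clock) {
  d <- .clock_design(beta, sheet, config)
  n <- nrow(d$X)
  if (n < 10L) stop("refusing to train a clock on fewer than 10 samples (underdetermined)")
  dup <- duplicated(d$X) | duplicated(d$X, fromLast = TRUE)
  if (any(dup) && length(unique(d$y[dup])) > 1L) {
    warning("duplicate methylation profiles with differing ages in training set")
  }
  sel <- select_lambda(d$X, d$y, alpha = config$alpha, folds = config$cv_folds,
                       nlambda = config$nlambda,
                       lambda_min_ratio = config$lambda_min_ratio)
  fit <- fit_elastic_net(d$X, d$y, alpha = config$alpha, lambda = sel$lambda)
  nz <- which(fit$weights != 0)
  clock_model(
    intercept = fit$intercept,
    coefficients = stats::setNames(fit$weights[nz], colnames(d$X)[nz]),
    transform = config$transform, offset = config$offset,
    alpha = config$alpha, lambda = sel$lambda,
    n_train = n, tissue = if (is.null(config$tissue)) "all" else config$tissue
  )
}

#' Leave-one-sample-out clock predictions
#'
#' For each sample the entire training pipeline — lambda selection and
#' elastic-net fit — is re-run with that sample held out, and its age is
#' predicted from the resulting clock, so no information from the sample
#' leaks into its own prediction. The inner lambda-selection folds default
#' to 10-fold (`config$inner_cv_folds`); set to `"loo"` for full nesting.
#'
#' @inheritParams train_clock
#' @return named numeric vector of predicted ages in years.
#' @export
loo_predict <- function(beta, sheet, config = default_config()$clock) {
  d <- .clock_design(beta, sheet, config)
  n <- nrow(d$X)
  if (n < 10L) stop("too few samples for leave-one-out evaluation")
  inner <- if (is.null(config$inner_cv_folds)) 10L else config$inner_cv_folds
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- d$X[-i, , drop = FALSE]
    ytr <- d$y[-i]
    folds <- if (identical(inner, "loo")) "loo" else min(as.integer(inner), n - 1L)
    sel <- select_lambda(Xtr, ytr, alpha = config$alpha, folds = folds,
                         nlambda = config$nlambda,
                         lambda_min_ratio = config$lambda_min_ratio)
    fit <- fit_elastic_net(Xtr, ytr, alpha = config$alpha, lambda = sel$lambda)
    preds[i] <- fit$intercept + sum(d$X[i, ] * fit$weights)
  }
  out <- inverse_transform_age(preds, config$transform, config$offset)
  stats::setNames(as.numeric(out), rownames(d$X))
}

#' Apply a trained clock to new methylation profiles
#'
#' Computes `intercept + sum(w_j * beta_j)` over the model's sites and
#' inverse-transforms to years. This is how a clock trained in one
#' species is applied to methylation profiles of a related species.
#'
#' @param model a [clock_model()].
#' @param beta samples x sites matrix; must contain the model's sites
#'   unless `missing_policy = "zero_contribution"`.
#' @param missing_policy `"error"` (default) or `"zero_contribution"`
#'   (absent model sites contribute nothing; per-sample missing-site
#'   count returned in the `"n_missing_sites"` attribute).
#' @return named vector of predicted ages in years (attributes:
#'   `clamped`, `n_missing_sites`).
#' @export
apply_clock <- function(model, beta, missing_policy = c("error", "zero_contribution")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(model, "clock_model"))
  sites <- names(model$coefficients)
  absent <- setdiff(sites, colnames(beta))
  if (length(absent) > 0L && missing_policy == "error") {
    stop("model site(s) absent from beta matrix: ", paste(absent, collapse = ", "))
  }
  present <- intersect(sites, colnames(beta))
  t_pred <- rep(model$intercept, nrow(beta))
  if (length(present) > 0L) {
    t_pred <- t_pred + as.numeric(beta[, present, drop = FALSE] %*%
                                    model$coefficients[present])
  }
  out <- inverse_transform_age(t_pred, model$transform, model$offset)
  names(out) <- rownames(beta)
  attr(out, "n_missing_sites") <- rep(length(absent), nrow(beta))
  out
}

#' Evaluate age predictions
#'
#' Reports the Pearson correlation and the median absolute error (MAE, in
#' years) between predicted and true ages, optionally stratified at a cut
#' age (MAE computed separately for true age below / at-or-above the
#' split).
#'
#' @param pred,true equal-length numeric vectors of ages in years.
#' @param age_split optional cut age in years.
#' @return list with `pearson_r` (NA with a message if either input has
#'   zero variance), `mae`, `predictions`, and when split:
#'   `mae_below`, `mae_above`.
#' @export
evaluate_predictions <- function(pred, true, age_split = NULL) {
  if (length(pred) != length(true) || length(pred) < 2L) {
    stop("pred and true must have equal length >= 2")
  }
  r <- if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    message("evaluate_predictions: zero-variance input, Pearson r undefined")
    NA_real_
  } else {
    stats::cor(pred, true)
  }
  out <- list(pearson_r = r, mae = stats::median(abs(pred - true)),
              predictions = pred)
  if (!is.null(age_split)) {
    lo <- true < age_split
    out$mae_below <- if (any(lo)) stats::median(abs(pred[lo] - true[lo])) else NA_real_
    out$mae_above <- if (any(!lo)) stats::median(abs(pred[!lo] - true[!lo])) else NA_real_
  }
  out
}
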