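#' Select age-correlated CpG sites for the pacemaker
#'
#' Returns the sites whose methylation has absolute Pearson correlation
#' with chronological age at or above `r_threshold` (0.75 for
#' single-tissue models, 0.6 for combined-tissue models, by convention).
#' Zero-variance sites are excluded (correlation undefined).
#'
#' @param beta samples x sites matrix.
#' @param ages chronological ages, length = nrow(beta).
#' @param r_threshold absolute-correlation threshold in (0, 1].
#' @return character vector of selected site ids.
#' @export
select_sites <- function(beta, ages, r_threshold = 0.75) {
  if (length(ages) != nrow(beta)) stop("ages must match rows of beta")
  if (length(ages) < 3L) stop("site selection requires at least 3 samples")
  if (r_threshold <= 0 || r_threshold > 1) stop("r_threshold must be in (0, 1]")
  sds <- apply(beta, 2L, stats::sd)
  usable <- sds > 0
  r <- rep(NA_real_, ncol(beta))
  r[usable] <- as.numeric(stats::cor(beta[, usable, drop = FALSE], ages))
  colnames(beta)[usable & abs(r) >= r_threshold]
}

#' Fit the epigenetic pacemaker by alternating least squares
#'
#' The pacemaker models methylation as
#' `beta_ij = m0_j + r_j * s_i + e_ij`, with a latent epigenetic state
#' `s_i` per sample and a rate `r_j` and baseline `m0_j` per site, fit by
#' minimizing total squared error. States are initialized at chronological
#' ages and the fit alternates (a) per-site simple regression of
#' methylation on the current states and (b) the per-sample state update
#' `s_i = sum_j r_j (beta_ij - m0_j) / sum_j r_j^2`. Each half-step
#' minimizes the squared error given the other block, so the recorded
#' error trace is non-increasing.
#'
#' @param beta samples x sites matrix of the selected sites (>= 2 sites,
#'   >= 3 samples).
#' @param ages chronological ages in years (state initialization).
#' @param tol relative improvement in total squared error below which the
#'   fit stops (default 1e-6).
#' @param max_iter maximum alternating iterations (default 100).
#' @return object of class `epm_model`: `site_ids`, `rates`, `intercepts`,
#'   `states` (named by sample), `error_trace`, `converged`, `n_iter`.
#' @export
fit_epm <- function(beta, ages, tol = 1e-6, max_iter = 100L) {
  beta <- as.matrix(beta)
  if (nrow(beta) < 3L) stop("pacemaker requires at least 3 samples")
  .fit_epm_core(beta, ages, tol, max_iter)
}

# the alternating optimization itself; leave-one-out refits may run it
# on n - 1 = 2 samples (a line through two points is still defined)
.fit_epm_core <- function(beta, ages, tol, max_iter) {
  n <- nrow(beta)
  m <- ncol(beta)
  if (m < 2L) stop("pacemaker requires at least 2 sites")
  if (n < 2L) stop("pacemaker requires at least 2 samples")
  if (length(ages) != n) stop("ages must match rows of beta")

  s <- as.numeric(ages)
  trace <- numeric(0)
  rates <- NULL
  intercepts <- NULL
  for (it in seq_len(max_iter)) {
    # (a) per-site simple regression of beta_j on s
    sc <- s - mean(s)
    ss <- sum(sc^2)
    if (ss == 0) stop("degenerate states: zero variance")
    rates <- as.numeric(crossprod(beta, sc)) / ss
    intercepts <- colMeans(beta) - rates * mean(s)
    # (b) per-sample state update
    r2 <- sum(rates^2)
    if (r2 == 0) stop("degenerate pacemaker: all site rates are zero")
    s <- as.numeric(sweep(beta, 2L, intercepts, "-") %*% rates) / r2
    err <- sum((beta - outer(s, rates) -
                  matrix(intercepts, n, m, byrow = TRUE))^2)
    trace <- c(trace, err)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (prev == 0 || (prev - err) / prev < tol) {
        return(structure(list(site_ids = colnames(beta), rates = rates,
                              intercepts = intercepts,
                              states = stats::setNames(s, rownames(beta)),
                              error_trace = trace, converged = TRUE,
                              n_iter = it), class = "epm_model"))
      }
    }
  }
  structure(list(site_ids = colnames(beta), rates = rates,
                 intercepts = intercepts,
                 states = stats::setNames(s, rownames(beta)),
                 error_trace = trace, converged = FALSE, n_iter = max_iter),
            class = "epm_model")
}

#' @export
print.epm_model <- function(x, ...) {
  cat(sprintf("Epigenetic pacemaker: %d site(s), %d sample(s), %d iteration(s), %sconverged\n",
              length(x$site_ids), length(x$states), x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Leave-one-out epigenetic states
#'
#' For each sample, the pacemaker is refit without it and the held-out
#' state is computed from the trained rates and intercepts by the state
#' update formula, so each state is estimated out-of-sample.
#'
#' @inheritParams fit_epm
#' @return named numeric vector of leave-one-out states.
#' @export
loo_states <- function(beta, ages, tol = 1e-6, max_iter = 100L) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  if (n < 3L) stop("leave-one-out states require at least 3 samples")
  out <- numeric(n)
  for (i in seq_len(n)) {
    fit <- .fit_epm_core(beta[-i, , drop = FALSE], ages[-i], tol, max_iter)
    out[i] <- sum(fit$rates * (beta[i, ] - fit$intercepts)) / sum(fit$rates^2)
  }
  stats::setNames(out, rownames(beta))
}

#' Fit the state-vs-age trend curve and translate states to ages
#'
#' Fits `s = a * log(age + c) + d` (c > 0) by bounded Levenberg-Marquardt
#' nonlinear least squares with 5 multi-starts over `c`. The fitted curve
#' translates a state back to years via
#' `age = exp((s - d)/a) - c`, clamped at 0.
#'
#' @param states epigenetic states (e.g. leave-one-out states).
#' @param ages chronological ages in years, all >= 0, length >= 4.
#' @return list of class `epm_trend`: `a`, `c`, `d`, `translated_ages`,
#'   `pearson_r` (state vs age), `mae` (translated vs chronological,
#'   years), `rss`.
#' @export
fit_trend <- function(states, ages) {
  if (length(states) != length(ages) || length(ages) < 4L) {
    stop("fit_trend requires >= 4 matched (state, age) pairs")
  }
  if (any(ages < 0)) stop("ages must be non-negative")
  if (stats::sd(states) < 1e-12) {
    stop("degenerate input: constant states (a -> 0), no trend to fit")
  }
  starts <- c(0.1, 0.5, 1, 2, 5)
  best <- NULL
  notes <- character(0)
  for (c0 in starts) {
    lin <- stats::lm(states ~ log(ages + c0))
    st <- list(a = unname(stats::coef(lin)[2L]), c = c0,
               d = unname(stats::coef(lin)[1L]))
    fit <- tryCatch(
      minpack.lm::nlsLM(states ~ a * log(ages + c) + d, start = st,
                        lower = c(a = -Inf, c = 1e-8, d = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- c(notes, sprintf("start c=%g: %s", c0, conditionMessage(fit)))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), c = unname(cf["c"]), d = unname(cf["d"]),
                   rss = rss)
    }
  }
  if (is.null(best)) {
    stop("trend fit failed to converge from all starts:\n",
         paste(notes, collapse = "\n"))
  }
  translated <- translate_state(states, best)
  structure(list(a = best$a, c = best$c, d = best$d,
                 translated_ages = translated,
                 pearson_r = stats::cor(states, ages),
                 mae = stats::median(abs(translated - ages)),
                 rss = best$rss),
            class = "epm_trend")
}

#' Evaluate the fitted trend curve at given ages
#'
#' @param ages ages in years.
#' @param trend an `epm_trend` (or any list with `a`, `c`, `d`).
#' @return expected states `a * log(age + c) + d`.
#' @export
trend_curve <- function(ages, trend) trend$a * log(ages + trend$c) + trend$d

#' Translate epigenetic states to years via a fitted trend
#'
#' Inverts the trend curve: `age = exp((s - d)/a) - c`, clamped at 0.
#'
#' @param states epigenetic states.
#' @param trend an `epm_trend` (or list with `a`, `c`, `d`).
#' @return ages in years.
#' @export
translate_state <- function(states, trend) {
  pmax(exp((states - trend$d) / trend$a) - trend$c, 0)
}

#' Pacemaker age acceleration
#'
#' Two forms are reported: the residual of the state from the fitted
#' trend curve at the sample's chronological age (state units; the
#' default used in downstream association models) and the difference
#' between trend-translated age and chronological age (years).
#'
#' @param states epigenetic states.
#' @param ages chronological ages (years).
#' @param trend fitted [fit_trend()] object.
#' @return data.frame with `state_resid` and `year_diff`.
#' @export
epm_accel <- function(states, ages, trend) {
  data.frame(
    state_resid = as.numeric(states - trend_curve(ages, trend)),
    year_diff = as.numeric(translate_state(states, trend) - ages)
  )
}
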