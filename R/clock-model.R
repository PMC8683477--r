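#' Construct an epigenetic clock model object
#'
#' A clock is a sparse linear model on transformed age: predicted
#' transformed age = intercept + sum over sites of weight * beta. The
#' transform (square root by default, with an additive year offset) maps
#' chronological years to the scale the model is fit on.
#'
#' @param intercept intercept in transformed-age units.
#' @param coefficients named numeric vector, site_id -> weight.
#' @param transform `"sqrt"` or `"identity"`.
#' @param offset transform offset in years (default 0).
#' @param alpha elastic-net mixing weight used in training.
#' @param lambda penalty strength used in training.
#' @param n_train,tissue training metadata.
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients, transform = "sqrt",
                        offset = 0, alpha = NA_real_, lambda = NA_real_,
                        n_train = NA_integer_, tissue = NA_character_) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!transform %in% c("sqrt", "identity")) stop("unknown transform: ", transform)
  if (length(coefficients) > 0L) {
    stopifnot(is.numeric(coefficients), all(is.finite(coefficients)))
    if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
      stop("coefficients must be named by site_id")
    }
  }
  if (!is.na(lambda) && lambda < 0) stop("lambda must be >= 0")
  structure(list(intercept = intercept, coefficients = coefficients,
                 transform = transform, offset = offset,
                 alpha = alpha, lambda = lambda,
                 n_train = n_train, tissue = tissue),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock: %d site(s), transform=%s (offset %g y), alpha=%g, lambda=%g\n",
              length(x$coefficients), x$transform, x$offset, x$alpha, x$lambda))
  invisible(x)
}

# 17 significant digits: round-trips IEEE doubles through decimal text
.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a clock model to its portable CSV format
#'
#' Header metadata lines (`#key,value`) carry the intercept, transform,
#' offset, alpha and lambda; the body is `site_id,coefficient` rows.
#' Numbers are written at 17 significant digits so that
#' `read_clock(write_clock(m))` reproduces `m` exactly.
#'
#' @param model a [clock_model()].
#' @param path output path.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  if (!all(is.finite(model$coefficients)) || !is.finite(model$intercept)) {
    stop("clock has non-finite coefficients")
  }
  hdr <- c(
    paste0("#intercept,", .fmt17(model$intercept)),
    paste0("#transform,", model$transform),
    paste0("#offset,", .fmt17(model$offset)),
    paste0("#alpha,", .fmt17(model$alpha)),
    paste0("#lambda,", .fmt17(model$lambda)),
    paste0("#n_train,", model$n_train),
    paste0("#tissue,", model$tissue),
    "site_id,coefficient"
  )
  body <- if (length(model$coefficients) > 0L) {
    paste0(names(model$coefficients), ",", .fmt17(model$coefficients))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a clock model written by [write_clock()]
#'
#' @param path path to the clock CSV.
#' @return a [clock_model()].
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), ",", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = ","), ""),
                          vapply(kv, `[[`, "", 1L))
  for (field in c("intercept", "transform", "offset")) {
    if (!field %in% names(meta)) stop("clock file missing metadata field: ", field)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) >= 1L && grepl("^site_id", body[1L])) body <- body[-1L]
  coefs <- numeric(0)
  if (length(body) > 0L) {
    parts <- strsplit(body, ",", fixed = TRUE)
    coefs <- stats::setNames(as.numeric(vapply(parts, `[[`, "", 2L)),
                             vapply(parts, `[[`, "", 1L))
  }
  num_or_na <- function(key) {
    if (key %in% names(meta)) suppressWarnings(as.numeric(meta[[key]])) else NA_real_
  }
  clock_model(
    intercept = as.numeric(meta[["intercept"]]),
    coefficients = coefs,
    transform = meta[["transform"]],
    offset = as.numeric(meta[["offset"]]),
    alpha = num_or_na("alpha"),
    lambda = num_or_na("lambda"),
    n_train = as.integer(num_or_na("n_train")),
    tissue = if ("tissue" %in% names(meta)) meta[["tissue"]] else NA_character_
  )
}
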