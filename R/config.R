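#' Default pipeline configuration
#'
#' One block per stage, every threshold at its documented default. All
#' stochastic stages carry a seed.
#'
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    clock = list(
      transform = "sqrt", offset = 0, alpha = 0.5,
      nlambda = 100L, lambda_min_ratio = 1e-3,
      cv_folds = "loo", inner_cv_folds = 10L, tissue = NULL, seed = 1L
    ),
    epm = list(
      r_threshold = 0.75, tol = 1e-6, max_iter = 100L
    ),
    roh = list(
      window_snps = 150L, window_het = 0L, window_missing = 2L,
      hit_frac = 0.05, min_snps = 150L, min_length_kb = 1500,
      screened_length_bp = NULL
    ),
    filters = list(
      qd_min = 2, fs_max = 60, sor_max = 3, mq_min = 40,
      mqranksum_min = -12.5, readposranksum_min = -8,
      maf_min = 0.01, min_mac = 3L
    ),
    accel = list(
      method = "residual", hc_flavor = "HC3", exclude_ids = character(0)
    ),
    ewas = list(
      alpha = 1e-4, z_cap = 40, top_k = 500L, stouffer_weights = "sqrt_n"
    ),
    simulate = list(seed = 1L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults from
#' [default_config()]; everything else keeps its default. Thresholds are
#' checked against their legal ranges.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg nested configuration list.
#' @return the validated configuration.
#' @export
validate_config <- function(cfg) {
  stopifnot(
    cfg$clock$alpha >= 0, cfg$clock$alpha <= 1,
    cfg$clock$transform %in% c("sqrt", "identity"),
    cfg$epm$r_threshold > 0, cfg$epm$r_threshold <= 1,
    cfg$roh$window_snps >= 1, cfg$roh$hit_frac > 0, cfg$roh$hit_frac <= 1,
    cfg$filters$maf_min >= 0, cfg$filters$maf_min < 0.5,
    cfg$ewas$alpha > 0, cfg$ewas$alpha < 1,
    cfg$accel$hc_flavor %in% c("HC0", "HC1", "HC3")
  )
  cfg
}
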