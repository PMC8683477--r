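#' Draw chronological ages
#'
#' Ages are drawn log-uniformly on \[min_age, max_age\], giving the
#' right-skewed age structure typical of managed wildlife cohorts (many
#' young animals, few old ones).
#'
#' @param n number of ages.
#' @param min_age,max_age age range in years; `0 <= min_age < max_age`.
#' @param seed RNG seed.
#' @return numeric vector of n ages in years.
#' @export
gen_ages <- function(n, min_age = 0.15, max_age = 25, seed = NULL) {
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer")
  if (!(min_age >= 0 && min_age < max_age)) stop("need 0 <= min_age < max_age")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  exp(stats::runif(n, log(min_age), log(max_age)))
}

.state_curve <- function(age, a = 5, c = 1) a * log(age + c)

#' Simulate a methylation beta matrix with known age structure
#'
#' Sites fall in three roles. `clock_linear` sites are linear in
#' square-root age (mean beta `m0_j + r_j * sqrt(age)`), mirroring the
#' transform the clock is fit on. `pacemaker_shared` sites all track one
#' shared nonlinear epigenetic-state trajectory
#' `s(age) = a * log(age + c)` (mean beta `m0_j + r_j * s(age)`), the
#' fast-early/slow-late shape of pacemaker models. `null` sites are
#' age-independent. Gaussian noise of sd `noise_sd` is added and values
#' are clipped to \[0, 1\]. Optional additive tissue and sex offsets are
#' drawn per site.
#'
#' @param ages chronological ages in years.
#' @param n_sites total number of CpG sites.
#' @param frac_clock,frac_pacemaker fractions of sites in each
#'   age-dependent role (sum must be <= 1; the rest are null).
#' @param noise_sd beta-unit noise standard deviation.
#' @param clock_slope absolute slope of clock sites, beta units per
#'   sqrt-year (sign random per site).
#' @param tissue_labels optional character vector per sample; when given,
#'   non-reference tissues receive per-site offsets ~ N(0, tissue_offset_sd).
#' @param sex optional `"F"`/`"M"` vector; males receive per-site offsets
#'   ~ N(0, sex_offset_sd).
#' @param tissue_offset_sd,sex_offset_sd offset scales in beta units.
#' @param state_curve list with `a` and `c` of the shared trajectory.
#' @param seed RNG seed.
#' @return list with `beta` (samples x sites matrix, ids in dimnames) and
#'   `truth` (per-site role/slope/intercept table, per-sample true state,
#'   curve parameters, offsets, noise sd).
#' @export
gen_methylation <- function(ages, n_sites = 2000, frac_clock = 0.025,
                            frac_pacemaker = 0.15, noise_sd = 0.01,
                            clock_slope = 0.02,
                            tissue_labels = NULL, sex = NULL,
                            tissue_offset_sd = 0.02, sex_offset_sd = 0.01,
                            state_curve = list(a = 5, c = 1), seed = NULL) {
  if (frac_clock < 0 || frac_pacemaker < 0 || frac_clock + frac_pacemaker > 1) {
    stop("role fractions must be >= 0 and sum to <= 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ages)
  n_clock <- round(frac_clock * n_sites)
  n_pm <- round(frac_pacemaker * n_sites)
  role <- rep(c("clock_linear", "pacemaker_shared", "null"),
              c(n_clock, n_pm, n_sites - n_clock - n_pm))

  r <- numeric(n_sites)
  m0 <- numeric(n_sites)
  sgn <- sample(c(-1, 1), n_sites, replace = TRUE)
  # clock: fixed-magnitude slope per sqrt-year, baseline clear of the clip
  i <- role == "clock_linear"
  r[i] <- sgn[i] * clock_slope
  m0[i] <- stats::runif(sum(i), 0.3, 0.7)
  # pacemaker: shared state reaches ~a*log(max age + c); keep means inside [0,1]
  i <- role == "pacemaker_shared"
  r[i] <- sgn[i] * stats::runif(sum(i), 0.01, 0.03)
  smax <- .state_curve(max(ages), state_curve$a, state_curve$c)
  m0[i] <- ifelse(r[i] > 0,
                  stats::runif(sum(i), 0.02, pmax(0.05, 0.95 - r[i] * smax)),
                  stats::runif(sum(i), pmin(0.95, 0.05 - r[i] * smax), 0.98))
  i <- role == "null"
  m0[i] <- stats::runif(sum(i), 0.05, 0.95)

  state <- .state_curve(ages, state_curve$a, state_curve$c)
  driver <- cbind(clock_linear = sqrt(ages), pacemaker_shared = state,
                  null = 0)
  mean_beta <- matrix(m0, n, n_sites, byrow = TRUE) +
    driver[, role, drop = FALSE] * matrix(r, n, n_sites, byrow = TRUE)

  tissue_off <- NULL
  if (!is.null(tissue_labels)) {
    ref <- tissue_labels[1L]
    tissue_off <- stats::rnorm(n_sites, 0, tissue_offset_sd)
    mean_beta <- mean_beta + outer(as.numeric(tissue_labels != ref), tissue_off)
  }
  sex_off <- NULL
  if (!is.null(sex)) {
    sex_off <- stats::rnorm(n_sites, 0, sex_offset_sd)
    mean_beta <- mean_beta + outer(as.numeric(sex == "M"), sex_off)
  }

  beta <- mean_beta + stats::rnorm(n * n_sites, 0, noise_sd)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(sprintf("S%03d", seq_len(n)),
                         sprintf("cg%05d", seq_len(n_sites)))
  truth <- list(
    sites = data.frame(site_id = colnames(beta), role = role, r = r, m0 = m0,
                       stringsAsFactors = FALSE),
    state = state, ages = ages, noise_sd = noise_sd,
    state_curve = state_curve,
    tissue_offsets = tissue_off, sex_offsets = sex_off
  )
  list(beta = beta, truth = truth)
}

#' Simulate a related species from an existing methylation truth
#'
#' A fraction `conserved_frac` of sites keeps its (intercept, slope) from
#' the base species; the rest receive an intercept shift ~ N(0, shift_sd),
#' emulating divergence of the methylation baseline while age dynamics at
#' conserved sites carry over. Betas are drawn fresh for the given ages
#' with the base noise level and clipped to \[0, 1\].
#'
#' @param truth the `truth` component returned by [gen_methylation()].
#' @param ages ages (years) of the related-species samples.
#' @param conserved_frac fraction of sites left unperturbed, in \[0, 1\].
#' @param shift_sd sd of the intercept shift at non-conserved sites.
#' @param seed RNG seed.
#' @return list with `beta` and the perturbed `truth`.
#' @export
gen_related_species <- function(truth, ages, conserved_frac = 0.9,
                                shift_sd = 0.1, seed = NULL) {
  if (conserved_frac < 0 || conserved_frac > 1) stop("conserved_frac must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  sites <- truth$sites
  n_sites <- nrow(sites)
  shifted <- stats::runif(n_sites) >= conserved_frac
  sites$m0 <- sites$m0 + ifelse(shifted, stats::rnorm(n_sites, 0, shift_sd), 0)

  n <- length(ages)
  state <- .state_curve(ages, truth$state_curve$a, truth$state_curve$c)
  driver <- cbind(clock_linear = sqrt(ages), pacemaker_shared = state, null = 0)
  mean_beta <- matrix(sites$m0, n, n_sites, byrow = TRUE) +
    driver[, sites$role, drop = FALSE] * matrix(sites$r, n, n_sites, byrow = TRUE)
  beta <- mean_beta + stats::rnorm(n * n_sites, 0, truth$noise_sd)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(sprintf("R%03d", seq_len(n)), sites$site_id)
  new_truth <- truth
  new_truth$sites <- sites
  new_truth$state <- state
  new_truth$ages <- ages
  new_truth$shifted <- shifted
  list(beta = beta, truth = new_truth)
}

#' Simulate age-acceleration phenotypes with an age-by-inbreeding interaction
#'
#' Generates `accel_i = b_sex * sex_i + b_age * age_i + b_f * F_i +
#' beta_interaction * age_i * F_i + e_i`, with main effects zero by
#' default. The noise is heteroskedastic by default: its sd grows 10% per
#' decade of age (`sd_i = noise_sd * (1 + 0.01 * age_i)`), reflecting the
#' larger spread of epigenetic age estimates in older animals; set
#' `het_slope = 0` for homoskedastic noise.
#'
#' @param ages,f,sex equal-length vectors (sex coded 0/1 or "F"/"M").
#' @param beta_interaction coefficient of the age x F interaction.
#' @param noise_sd baseline noise sd (years).
#' @param b_sex,b_age,b_f main-effect coefficients (default 0).
#' @param het_slope proportional sd growth per year of age (default 0.01).
#' @param seed RNG seed.
#' @return numeric vector of age-acceleration values (years).
#' @export
gen_accel_phenotypes <- function(ages, f, sex, beta_interaction = 0.5,
                                 noise_sd = 1, b_sex = 0, b_age = 0, b_f = 0,
                                 het_slope = 0.01, seed = NULL) {
  if (length(f) != length(ages) || length(sex) != length(ages)) {
    stop("ages, f and sex must have equal length")
  }
  if (!is.null(seed)) set.seed(seed)
  sex_num <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  sd_i <- noise_sd * (1 + het_slope * ages)
  b_sex * sex_num + b_age * ages + b_f * f + beta_interaction * ages * f +
    stats::rnorm(length(ages), 0, sd_i)
}
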