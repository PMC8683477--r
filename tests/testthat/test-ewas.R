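test_that("screen statistics match the t-distribution oracle", {
  # n = 12, r chosen so that two-sided p is ~0.05 -> |z| ~ 1.96
  n <- 12
  t_crit <- qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
  # build a site with exactly that sample correlation via rotation
  set.seed(71)
  ages <- rnorm(n)
  e <- resid(lm(rnorm(n) ~ ages))
  x <- r_crit * scale(ages) + sqrt(1 - r_crit^2) * scale(e)
  beta <- matrix((x - min(x)) / (max(x) - min(x)), ncol = 1,
                 dimnames = list(NULL, "cg1"))
  res <- site_age_screen(beta, ages)
  expect_equal(res$r, r_crit, tolerance = 1e-9)
  expect_equal(res$p, 0.05, tolerance = 1e-9)
  expect_equal(abs(res$z), qnorm(1 - 0.025), tolerance = 1e-6)
})

test_that("zero correlation gives t = 0, p = 1, z = 0", {
  ages <- c(1, 2, 3, 4, 5, 6)
  beta <- matrix(c(0.3, 0.4, 0.3, 0.4, 0.3, 0.4), ncol = 1,
                 dimnames = list(NULL, "cg1"))
  # construct exact zero correlation: symmetric pattern around age mean
  b2 <- matrix(0.5 + c(-1, 1, 0, 0, 1, -1) * 0.1, ncol = 1,
               dimnames = list(NULL, "cg0"))
  res <- site_age_screen(b2, ages)
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_equal(res$z, 0, tolerance = 1e-12)
})

test_that("perfectly correlated sites are capped and flagged, p stays positive", {
  ages <- gen_ages(30, seed = 72)
  beta <- cbind(perfect = (ages - min(ages)) / diff(range(ages)),
                flat = rep(0.5, 30))
  expect_message(res <- site_age_screen(beta, ages), "zero-variance")
  expect_equal(res$z[1], 40)
  expect_true(res$capped[1])
  expect_gt(res$p[1], 0)
  expect_true(is.na(res$z[2]))
})

test_that("z increases strictly with r at fixed n", {
  ages <- seq(1, 20, length.out = 20)
  set.seed(73)
  sim <- gen_methylation(ages, n_sites = 200, noise_sd = 0.05, seed = 73)
  res <- site_age_screen(sim$beta, ages)
  ok <- !is.na(res$r) & !res$capped
  ord <- order(res$r[ok])
  expect_true(all(diff(res$z[ok][ord]) > 0))
})

test_that("Stouffer identities hold exactly", {
  # equal z, equal weights: z_meta = z * sqrt(2)
  m <- stouffer_meta(matrix(c(1.3, 1.3), 1), weights = c(1, 1))
  expect_equal(m$z_meta, 1.3 * sqrt(2), tolerance = 1e-12)
  # cancellation
  m0 <- stouffer_meta(matrix(c(2, -2), 1), weights = c(1, 1))
  expect_equal(m0$z_meta, 0, tolerance = 1e-12)
  # sqrt(n) weighting, hand formula
  mw <- stouffer_meta(matrix(c(2, 1), 1), n = c(76, 20))
  expect_equal(mw$z_meta, (sqrt(76) * 2 + sqrt(20) * 1) / sqrt(96),
               tolerance = 1e-12)
  # one tissue, unit weight: z unchanged
  m1 <- stouffer_meta(matrix(1.7, 1), weights = 1)
  expect_equal(m1$z_meta, 1.7)
  # missing tissue propagates to a missing meta value
  mna <- stouffer_meta(matrix(c(1, NA), 1), weights = c(1, 1))
  expect_true(is.na(mna$z_meta))
})

test_that("significance counts, overlap and sector classes are as defined", {
  res <- data.frame(
    site_id = paste0("cg", 1:6),
    p_blood = c(1e-6, 1e-6, 1e-6, 0.5, 1e-6, 0.2),
    z_blood = c(5, -5, 5, 1, 5, 1),
    p_biopsy = c(1e-6, 1e-6, 1e-6, 1e-6, 0.5, 0.2),
    z_biopsy = c(5, -5, -5, 5, 1, 1))
  s <- significant_sites(res, alpha = 1e-4)
  expect_equal(s$counts$n[s$counts$tissue == "blood"], c(3, 1))
  expect_equal(s$overlap, 3L)
  expect_equal(unname(s$sectors["shared"]), 2L)
  expect_equal(unname(s$sectors["divergent"]), 1L)
  expect_equal(unname(s$sectors["blood_specific"]), 1L)
  expect_equal(unname(s$sectors["biopsy_specific"]), 1L)
})

test_that("null EWAS calibration: p < alpha frequency matches alpha", {
  ages <- gen_ages(76, seed = 74)
  set.seed(74)
  nsites <- 2e4
  beta <- matrix(runif(76 * nsites, 0.2, 0.8), 76, nsites,
                 dimnames = list(NULL, sprintf("cg%05d", 1:nsites)))
  res <- site_age_screen(beta, ages)
  frac <- mean(res$p < 0.01)
  se <- sqrt(0.01 * 0.99 / nsites)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("top-k selection is extreme-by-z with deterministic ties", {
  res <- data.frame(site_id = sprintf("cg%02d", 1:10),
                    z_meta = c(3, -2, 5, 0, 1, -4, 2, -1, 4, 0))
  top <- top_k_by_z(res, k = 2)
  expect_setequal(top$site_id[top$direction == "positive"], c("cg03", "cg09"))
  expect_setequal(top$site_id[top$direction == "negative"], c("cg06", "cg02"))
  # all z equal: selection is lexicographic and deterministic
  res2 <- data.frame(site_id = sprintf("cg%02d", 10:1), z_meta = rep(1, 10))
  t2 <- top_k_by_z(res2, k = 3)
  expect_equal(t2$site_id[t2$direction == "positive"],
               c("cg01", "cg02", "cg03"))
  # k larger than available: everything returned with a warning
  expect_warning(t3 <- top_k_by_z(res, k = 8), "returning all")
  expect_equal(nrow(t3), 10L)
})

test_that("annotation summaries count TSS classes and compare island z", {
  set.seed(75)
  n_each <- 500
  sel <- data.frame(site_id = sprintf("cg%04d", 1:(2 * n_each)),
                    z = c(rnorm(n_each, 1), rnorm(n_each, 0)))
  ann <- data.frame(site_id = sel$site_id,
                    tss_class = rep("promoter", 2 * n_each),
                    island_flag = rep(c(TRUE, FALSE), each = n_each))
  out <- annotate_summary(sel, ann)
  expect_equal(sum(out$tss_counts), 2 * n_each)
  expect_lt(out$island_test$p, 1e-4)   # +1 shift is detected
  expect_gt(out$island_test$median_diff, 0.5)
  # identical distributions: no signal
  sel2 <- sel
  set.seed(76)
  sel2$z <- rnorm(2 * n_each)
  out2 <- annotate_summary(sel2, ann)
  expect_gt(out2$island_test$p, 1e-4)
  expect_lt(abs(out2$island_test$median_diff), 0.3)
  expect_error(annotate_summary(sel[0, ], ann), "empty")
})

test_that("two-tissue EWAS joins shared sites and carries meta columns", {
  ages_bl <- gen_ages(40, seed = 77)
  ages_bi <- gen_ages(15, seed = 78)
  bl <- gen_methylation(ages_bl, n_sites = 100, noise_sd = 0.02, seed = 77)
  bi <- gen_methylation(ages_bi, n_sites = 100, noise_sd = 0.02, seed = 78)
  res <- ewas_two_tissue(bl$beta, ages_bl, bi$beta, ages_bi)
  expect_equal(nrow(res), 100L)
  expect_true(all(c("z_blood", "z_biopsy", "z_meta", "p_meta") %in% names(res)))
  # meta z respects the sqrt(n) weighting identity on a sample site
  i <- which(!is.na(res$z_meta))[1]
  w <- sqrt(c(40, 15))
  expect_equal(res$z_meta[i],
               sum(w * c(res$z_blood[i], res$z_biopsy[i])) / sqrt(sum(w^2)),
               tolerance = 1e-12)
})

test_that("annotation files validate their enums", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,tss_class,island_flag", "cg1,promoter,TRUE",
               "cg2,intron,FALSE"), path)
  ann <- read_annotation(path)
  expect_equal(nrow(ann), 2L)
  writeLines(c("site_id,tss_class,island_flag", "cg1,enhancer,TRUE"), path)
  expect_error(read_annotation(path), "enhancer")
})
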