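test_that("acceleration definitions: difference, residual, literal variant", {
  expect_equal(compute_accel(6, 5, "difference"), 1)
  pred <- c(1, 2, 3, 4)
  expect_equal(compute_accel(pred, pred, "residual"), rep(0, 4))
  # 4-point fixture solved by hand via the 2x2 normal equations:
  # chron = (0, 1, 2, 3), pred = (1, 1, 3, 3): slope = 0.8, intercept = 0.8
  chron <- c(0, 1, 2, 3)
  pred2 <- c(1, 1, 3, 3)
  expect_equal(compute_accel(pred2, chron, "residual"),
               pred2 - (0.8 + 0.8 * chron), tolerance = 1e-12)
  # residual acceleration is exactly uncorrelated with chronological age
  set.seed(61)
  p3 <- rnorm(50, 10, 3)
  c3 <- rnorm(50, 10, 3)
  expect_lt(abs(cor(compute_accel(p3, c3, "residual"), c3)), 1e-10)
  expect_equal(mean(compute_accel(p3, c3, "residual")), 0, tolerance = 1e-10)
  # literal Methods variant regresses the other way and flips sign
  lit <- compute_accel(pred2, chron, "residual_methods_literal")
  expect_equal(lit, -resid(lm(chron ~ pred2)), ignore_attr = TRUE)
  expect_error(compute_accel(rep(2, 5), 1:5, "residual_methods_literal"),
               "zero variance")
  expect_error(compute_accel(1:5, rep(1, 5), "residual"), "zero variance")
})

test_that("OLS matches the explicit normal-equations oracle", {
  set.seed(62)
  X <- cbind(a = rnorm(8), b = rnorm(8))
  y <- 1 + 2 * X[, "a"] - X[, "b"] + rnorm(8, 0, 0.1)
  fit <- ols_fit(y, X)
  Xi <- cbind(1, X)
  oracle <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(unname(fit$coefficients), as.numeric(oracle), tolerance = 1e-10)
  s2 <- sum((y - Xi %*% oracle)^2) / (8 - 3)
  expect_equal(unname(fit$vcov_classical),
               unname(s2 * solve(crossprod(Xi))), tolerance = 1e-10)
})

test_that("noiseless linear responses are interpolated exactly", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6, 7), b = c(0, 1, 0, 1, 0, 1, 1))
  y <- 2 + 0.5 * X[, 1] - X[, 2]
  fit <- ols_fit(y, X)
  expect_lt(sum(fit$residuals^2), 1e-20)
  expect_equal(unname(fit$coefficients), c(2, 0.5, -1), tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"])
  expect_error(ols_fit(rnorm(10), X), "collinear.*c")
})

test_that("robust covariance equals the direct sandwich evaluation", {
  set.seed(63)
  X <- cbind(x1 = rnorm(6), x2 = rnorm(6))
  y <- rnorm(6)
  fit <- ols_fit(y, X)
  Xi <- fit$X
  e <- fit$residuals
  bread <- solve(crossprod(Xi))
  for (flavor in c("HC0", "HC1", "HC3")) {
    w <- switch(flavor, HC0 = e^2, HC1 = e^2 * 6 / (6 - 3),
                HC3 = e^2 / (1 - diag(Xi %*% bread %*% t(Xi)))^2)
    oracle <- bread %*% t(Xi) %*% diag(w) %*% Xi %*% bread
    rob <- robust_vcov(fit, flavor)
    expect_lt(max(abs(rob$vcov_robust - oracle)), 1e-10)
    ev <- eigen(rob$vcov_robust, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-12))  # positive semi-definite
  }
  # HC1 = HC0 * n/(n-k) entrywise
  h0 <- robust_vcov(fit, "HC0")$vcov_robust
  h1 <- robust_vcov(fit, "HC1")$vcov_robust
  expect_equal(h1, h0 * 6 / (6 - 3), tolerance = 1e-12)
})

test_that("robust covariance agrees with the sandwich package", {
  set.seed(64)
  d <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  d$y <- 1 + d$x1 + rnorm(25, 0, abs(d$x1) + 0.2)
  fit <- ols_fit(d$y, as.matrix(d[, c("x1", "x2")]))
  lmfit <- lm(y ~ x1 + x2, data = d)
  for (flavor in c("HC0", "HC1", "HC3")) {
    expect_equal(unname(robust_vcov(fit, flavor)$vcov_robust),
                 unname(sandwich::vcovHC(lmfit, type = flavor)),
                 tolerance = 1e-8)
  }
})

test_that("homoskedastic |e| = c residuals reduce HC0 to c^2 (X'X)^-1", {
  X <- cbind(x = c(-1, 1, -1, 1))
  y <- c(0.5, -0.5, -0.5, 0.5)  # orthogonal to the design: fit is 0, |e| = 0.5
  fit <- ols_fit(y, X)
  expect_equal(max(abs(abs(fit$residuals) - 0.5)), 0, tolerance = 1e-12)
  rob <- robust_vcov(fit, "HC0")
  expect_equal(unname(rob$vcov_robust),
               unname(0.25 * solve(crossprod(fit$X))), tolerance = 1e-12)
})

test_that("HC3 errors on a perfect-fit (leverage 1) point", {
  X <- cbind(x = c(0, 0, 0, 0, 100))
  y <- c(0.1, -0.2, 0.3, 0.2, 5)
  fit <- ols_fit(y, X)
  expect_error(robust_vcov(fit, "HC3"), "leverage")
})

test_that("the 2x2 inbreeding grid recovers a planted interaction on EPM only", {
  set.seed(65)
  n <- 70
  ages <- gen_ages(n, seed = 65)
  f <- runif(n, 0, 0.37)
  sex <- rep(c("F", "M"), 35)
  accel_epm <- gen_accel_phenotypes(ages, f, sex, beta_interaction = 1,
                                    noise_sd = 1, seed = 66)
  accel_ec <- gen_accel_phenotypes(ages, f, sex, beta_interaction = 0,
                                   noise_sd = 1, seed = 67)
  accel <- data.frame(sample_id = sprintf("S%02d", 1:n), age = ages, sex = sex,
                      accel_ec = accel_ec, accel_epm = accel_epm)
  inb <- data.frame(sample_id = accel$sample_id, f = f,
                    froh = pmax(f + rnorm(n, 0, 0.02), 0))
  res <- run_inbreeding_analysis(accel, inb)
  tidy <- res$tidy
  int <- tidy[tidy$term == "age:inbreeding", ]
  epm_rows <- int[int$accel == "accel_epm", ]
  ec_rows <- int[int$accel == "accel_ec", ]
  expect_true(all(epm_rows$p < 0.05))
  expect_true(all(epm_rows$estimate > 0))
  expect_true(all(ec_rows$p > 0.001))  # no planted effect on the clock side
  expect_equal(nrow(tidy), 4 * 5)
})

test_that("permuted inbreeding kills the interaction estimate", {
  set.seed(68)
  n <- 70
  ages <- gen_ages(n, seed = 69)
  f <- runif(n, 0, 0.37)
  sex <- rep(0:1, 35)
  accel_y <- gen_accel_phenotypes(ages, f, sex, beta_interaction = 0.5,
                                  noise_sd = 1, seed = 70)
  f_perm <- sample(f)
  X <- cbind(sex = sex, age = ages, inbreeding = f_perm,
             `age:inbreeding` = ages * f_perm)
  fit <- robust_vcov(ols_fit(accel_y, X), "HC3")
  expect_lt(abs(fit$t_robust["age:inbreeding"]), 3)
})

test_that("analysis guards: join size and exclusions", {
  accel <- data.frame(sample_id = sprintf("S%d", 1:8), age = 1:8,
                      sex = rep(0:1, 4), accel_ec = rnorm(8),
                      accel_epm = rnorm(8))
  inb <- data.frame(sample_id = accel$sample_id, f = runif(8), froh = runif(8))
  expect_error(run_inbreeding_analysis(accel, inb), "fewer than 10")
})
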