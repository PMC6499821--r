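test_that("the correlation matrix collapses correctly at parameter extremes", {
  sim <- small_sim(5)
  P <- sim$P; D <- sim$D; n <- nrow(P)
  expect_equal(unname(build_correlation(0, 0.5, 1000, P, D)), diag(1, n))
  expect_equal(build_correlation(1, 1, 1000, P, D), P)
  set.seed(30)
  for (i in 1:10) {
    C <- build_correlation(runif(1), runif(1), runif(1, 100, 5000), P, D)
    expect_equal(unname(diag(C)), rep(1, n))
    expect_true(isSymmetric(C))
  }
  expect_error(build_correlation(1.2, 0.5, 1000, P, D), "alpha")
  expect_error(build_correlation(0.5, -0.1, 1000, P, D), "beta")
  expect_error(build_correlation(0.5, 0.5, 1000, P, D[-1, -1]), "dimensions")
})

test_that("alpha = 0 reduces the likelihood to the OLS Gaussian form", {
  sim <- small_sim(6)
  cells <- sim$cells
  y <- cells$log_diversity
  X <- cbind(1, cells$land_fraction, cells$npp)
  n <- length(y)
  nll <- gls_negloglik(c(0, 0.3, 1000), y, X, sim$P, sim$D)
  b <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% b)^2) / n
  expect_equal(nll, n / 2 * log(2 * pi * s2) + n / 2, tolerance = 1e-10)
  # with P = I and distances huge, the value is independent of beta
  Ifake <- diag(1, n); Dfar <- matrix(1e9, n, n); diag(Dfar) <- 0
  v1 <- gls_negloglik(c(0.4, 0.1, 1000), y, X, Ifake, Dfar)
  v2 <- gls_negloglik(c(0.4, 0.9, 1000), y, X, Ifake, Dfar)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("OLS fits match the closed form and lm exactly", {
  sim <- small_sim(7)
  cells <- sim$cells
  fit <- lsgls(log_diversity ~ land_fraction + temp_mean + npp, cells,
               correlation = "none")
  lmfit <- lm(log_diversity ~ land_fraction + temp_mean + npp, cells)
  expect_equal(coef(fit), coef(lmfit), tolerance = 1e-10)
  expect_equal(fit$sigma2, mean(residuals(lmfit)^2), tolerance = 1e-10)
  expect_equal(as.numeric(logLik(lmfit)), fit$logLik, tolerance = 1e-8)
  # predicted R2 in OLS mode is the classical in-sample R2
  expect_equal(predicted_r2(fit), summary(lmfit)$r.squared, tolerance = 1e-10)
})

test_that("a noiseless response is recovered exactly", {
  sim <- small_sim(8)
  cells <- redraw_response(sim, seed = 99, sigma2 = 0)
  fit <- lsgls(log_diversity ~ land_fraction + temp_seasonality + precip_mean + npp,
               cells, correlation = "none")
  b <- sim$config$b
  expect_equal(coef(fit)[names(b)], b, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("the GLS likelihood dominates OLS and degenerate designs error", {
  sim <- small_sim(9)
  cells <- sim$cells
  form <- log_diversity ~ land_fraction + temp_seasonality
  gls <- lsgls(form, cells, P = sim$P, D = sim$D, control = fast_control())
  ols <- lsgls(form, cells, correlation = "none")
  expect_gte(gls$logLik, ols$logLik - 1e-6)
  expect_equal(unname(abs(gls$tval)), unname(abs(gls$coefficients / gls$se)))
  cells$dup <- cells$temp_seasonality
  expect_error(lsgls(log_diversity ~ temp_seasonality + dup, cells,
                     correlation = "none"), "rank deficient")
})

test_that("inference is equivariant under response rescaling", {
  sim <- small_sim(10)
  cells <- sim$cells
  form <- log_diversity ~ land_fraction + precip_mean
  ctrl <- fast_control()
  f1 <- lsgls(form, cells, P = sim$P, D = sim$D, control = ctrl)
  cells2 <- cells; cells2$log_diversity <- 3.7 * cells$log_diversity
  f2 <- lsgls(form, cells2, P = sim$P, D = sim$D, control = ctrl)
  expect_equal(coef(f2), 3.7 * coef(f1), tolerance = 1e-4)
  expect_equal(f2$tval, f1$tval, tolerance = 1e-4)
  expect_equal(f2$pval, f1$pval, tolerance = 1e-4)
  expect_equal(f2$params[1:2], f1$params[1:2], tolerance = 1e-3)
  expect_equal(predicted_r2(f2), predicted_r2(f1), tolerance = 1e-4)
})

test_that("likelihood-ratio tests behave at the identity and for factors", {
  sim <- small_sim(12)
  cells <- sim$cells
  form <- log_diversity ~ land_fraction + npp
  fit <- lsgls(form, cells, P = sim$P, D = sim$D, control = fast_control())
  lr0 <- lr_test(fit, fit0 <- fit, df = 1)   # identical fits
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)
  # k-level biome drops k - 1 columns
  full <- lsgls(log_diversity ~ land_fraction + biome, cells,
                correlation = "none")
  red <- lsgls(log_diversity ~ land_fraction, cells, correlation = "none")
  lr <- lr_test(full, red)
  expect_equal(lr$df, nlevels(cells$biome) - 1L)
  expect_gte(lr$statistic, 0)
  expect_error(lr_test(red, full), "not nested")
})

test_that("leave-one-out predictions define predicted R2", {
  sim <- small_sim(13)
  cells <- redraw_response(sim, seed = 77, sigma2 = 0)
  fit <- lsgls(log_diversity ~ land_fraction + temp_seasonality + precip_mean + npp,
               cells, correlation = "none")
  expect_equal(predicted_r2(fit), 1, tolerance = 1e-8)  # perfect fit
  # GLS LOO predictions equal the direct conditional-mean formula
  fitg <- lsgls(log_diversity ~ land_fraction + npp, sim$cells,
                P = sim$P, D = sim$D, params = c(0.6, 0.5, 1500))
  yhat <- predict(fitg, type = "loo")
  C <- build_correlation(0.6, 0.5, 1500, sim$P, sim$D)
  r <- sim$cells$log_diversity - fitg$fitted.values
  i <- 7
  direct <- fitg$fitted.values[i] +
    C[i, -i] %*% solve(C[-i, -i], r[-i])
  expect_equal(yhat[i], drop(direct), tolerance = 1e-8)
})

test_that("residual types and hotspot flags are coherent", {
  sim <- small_sim(14)
  fit <- lsgls(log_diversity ~ land_fraction, sim$cells,
               P = sim$P, D = sim$D, params = c(0.5, 0.5, 1500))
  sr <- standardized_residuals(fit)
  expect_equal(sr$standardized, residuals(fit, "standardized"))
  expect_equal(sign(sr$flag[abs(sr$standardized) >= 1.96]),
               sign(sr$standardized[abs(sr$standardized) >= 1.96]))
  expect_true(all(sr$flag[abs(sr$standardized) < 1.96] == 0))
  expect_true(is.finite(sr$shapiro_p))
  # zero residuals produce no flags
  cells0 <- redraw_response(sim, seed = 5, sigma2 = 0)
  fit0 <- lsgls(log_diversity ~ land_fraction + temp_seasonality + precip_mean + npp,
                cells0, correlation = "none")
  expect_true(all(standardized_residuals(fit0)$flag == 0))
})

test_that("simulate() draws reproducibly and restores the RNG stream", {
  sim <- small_sim(15)
  fit <- lsgls(log_diversity ~ land_fraction, sim$cells,
               P = sim$P, D = sim$D, params = c(0.5, 0.5, 1500))
  set.seed(123); before <- runif(1)
  set.seed(123)
  s1 <- simulate(fit, nsim = 2, seed = 9)
  after <- runif(1)
  expect_equal(after, before)   # user stream untouched
  s2 <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(s1, s2)
  expect_equal(dim(s1), c(fit$n, 2L))
})
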