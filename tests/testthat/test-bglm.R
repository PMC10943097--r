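# Bayesian GLM fitting, prediction, LOOIC comparison and screening.

test_that("intercept-only Bernoulli posterior matches the Beta oracle", {
  # conjugate oracle: with a flat-ish prior the posterior of p is close to
  # Beta(k + 1, n - k + 1); compare posterior means within 3 MC SEs
  set.seed(2)
  n <- 2000
  y <- rbinom(n, 1, 0.7)
  k <- sum(y)
  fit <- bglm(y ~ 1, data.frame(y = y), family = "bernoulli",
              settings = fast_settings(seed = 4))
  p_draws <- plogis(fit$draws[, "(Intercept)"])
  beta_mean <- (k + 1) / (n + 2)
  mc_se <- sd(p_draws) / sqrt(coda::effectiveSize(fit$draws[, "(Intercept)"]))
  expect_lt(abs(mean(p_draws) - beta_mean), 3 * mc_se + 0.002)
  expect_true(fit$converged)
  expect_true(all(fit$rhat >= 1 - 1e-6, na.rm = TRUE))
})

test_that("draw bookkeeping follows the thinning arithmetic", {
  st <- mcmc_settings(chains = 3, iterations = 4000, warmup = 200, thin = 5)
  expect_equal(st$draws_per_chain, 760L)
  fit <- bglm(y ~ 1, data.frame(y = rnorm(50)), family = "gaussian",
              settings = fast_settings(seed = 1))
  expect_equal(nrow(fit$draws),
               fit$settings$chains * fit$settings$draws_per_chain)
})

test_that("gaussian fit concentrates on a near-constant response", {
  d <- data.frame(y = rep(5, 100) + rnorm(100, 0, 1e-3))
  fit <- bglm(y ~ 1, d, family = "gaussian",
              settings = fast_settings(seed = 3))
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 5), 0.01)
})

test_that("response coding is validated per family", {
  expect_error(bglm(y ~ 1, data.frame(y = c(0, 1, 2)), family = "bernoulli",
                    settings = fast_settings()), "\\{0, 1\\}")
  expect_error(bglm(y ~ 1, data.frame(y = c(1.5, 2)), family = "negbin",
                    settings = fast_settings()), "nonnegative integers")
})

test_that("negbin fit recovers planted log-mean and dispersion", {
  set.seed(8)
  y <- rnbinom(500, size = 5, mu = exp(3))
  fit <- bglm(y ~ 1, data.frame(y = y), family = "negbin",
              settings = fast_settings(seed = 8))
  expect_true(fit$hpd95["(Intercept)", "lower"] <= 3 &&
                3 <= fit$hpd95["(Intercept)", "upper"])
  expect_true(fit$hpd95["r", "lower"] <= 5 * 1.5 &&
                fit$hpd95["r", "upper"] >= 5 / 1.5)
})

test_that("predictions follow the inverse link and flag extrapolation", {
  set.seed(5)
  d <- data.frame(y = rbinom(300, 1, 0.5), x = rnorm(300))
  fit <- bglm(y ~ x, d, family = "bernoulli",
              settings = fast_settings(seed = 5))
  # planted slope 0: predictions at different x are near-identical
  pr <- predict(fit, data.frame(x = c(-1, 0, 1)))
  expect_lt(max(pr$median) - min(pr$median), 0.06)
  expect_true(all(pr$hpd95_lo <= pr$median & pr$median <= pr$hpd95_hi))
  expect_warning(predict(fit, data.frame(x = 50)), "extrapolating")
  d2 <- data.frame(y = rbinom(100, 1, 0.5),
                   g = factor(rep(c("a", "b"), 50)))
  fit2 <- bglm(y ~ g, d2, family = "bernoulli",
               settings = fast_settings(seed = 6))
  expect_error(predict(fit2, data.frame(g = "c")), "level")
  expect_error(predict_probability(
    bglm(y ~ 1, data.frame(y = rnorm(30)), family = "gaussian",
         settings = fast_settings()), data.frame(x = 1)), "bernoulli")
})

test_that("model weights follow exp(-delta/2) and are order-equivariant", {
  set.seed(11)
  x <- rnorm(200)
  y <- rnbinom(200, size = 4, mu = exp(1 + 0.9 * x))
  d <- data.frame(y = y, x = x)
  f1 <- suppressWarnings(bglm(y ~ x, d, family = "negbin",
                              settings = fast_settings(seed = 1)))
  f0 <- suppressWarnings(bglm(y ~ 1, d, family = "negbin",
                              settings = fast_settings(seed = 2)))
  cmp <- compare_models(list(slope = f1, null = f0), force = TRUE)
  expect_equal(sum(cmp$weight), 1)
  # a strong planted effect wins decisively
  expect_equal(cmp$model[1], "slope")
  expect_gt(cmp$weight[1], 0.9)
  # permutation equivariance
  cmp2 <- compare_models(list(null = f0, slope = f1), force = TRUE)
  expect_equal(cmp2[order(cmp2$model), -1], cmp[order(cmp$model), -1],
               tolerance = 1e-12)
  # weight ratio identity at a fixed LOOIC gap
  delta <- 2
  expect_equal(exp(-0 / 2) / exp(-delta / 2), exp(1))
  # identical fits split the weight evenly
  cmp3 <- compare_models(list(a = f1, b = f1), force = TRUE)
  expect_equal(cmp3$weight, c(0.5, 0.5))
  # mismatched responses refuse to compare
  f_other <- bglm(y ~ 1, data.frame(y = rev(y), x = x), family = "negbin",
                  settings = fast_settings(seed = 3))
  expect_error(compare_models(list(f1, f_other), force = TRUE),
               "identical response")
})

test_that("collinearity screen drops duplicates and keeps DCW1 over DCW0", {
  set.seed(14)
  n <- 60
  sstv <- rnorm(n)
  tab <- data.frame(SST_mean = sstv, dup = sstv,
                    Chla_mean = rnorm(n))
  sc <- collinearity_screen(tab, priority = c("SST_mean"))
  expect_true("SST_mean" %in% sc$retained)
  expect_true("dup" %in% sc$dropped)
  # independent predictors all retained
  ind <- as.data.frame(matrix(rnorm(4 * 500), ncol = 4,
                              dimnames = list(NULL, c("a", "b", "c", "d"))))
  expect_equal(sort(collinearity_screen(ind)$retained), c("a", "b", "c", "d"))
  # DCW0 and DCW1 computed from one SST record are near-collinear
  s <- const_series(20, years = 2010:2013)
  s$value <- 20 + rnorm(nrow(s), 0, 2)
  cl <- compute_climatology(s)
  st <- stress_series(s, cl)
  ok <- !is.na(st$dcw0)
  env <- data.frame(DCW0 = -st$dcw0[ok][seq(1, sum(ok), by = 30)],
                    DCW1 = -st$dcw1[ok][seq(1, sum(ok), by = 30)],
                    SST_mean = rnorm(length(seq(1, sum(ok), by = 30))))
  expect_gt(abs(cor(env$DCW0, env$DCW1)), 0.8)
  sc2 <- collinearity_screen(env)
  expect_true("DCW1" %in% sc2$retained)
  expect_true("DCW0" %in% sc2$dropped)
  # constant predictor flagged
  sc3 <- collinearity_screen(data.frame(a = rnorm(10), b = rep(1, 10)))
  expect_equal(sc3$flagged, "b")
})

test_that("the candidate model set enumerates all predictor subsets", {
  specs <- small_coral_model_set(c("SST_mean", "Chla_mean", "DHW0", "DCW1"))
  expect_length(specs, 16L)
  expect_true("intercept_only" %in% names(specs))
  rhs_terms <- vapply(specs, function(f)
    length(attr(terms(f), "term.labels")), integer(1))
  expect_equal(as.integer(sort(table(rhs_terms))), c(1L, 1L, 4L, 4L, 6L))
})
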