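# Synthetic-data generator: moment matching, planted probabilities,
# environmental series.

test_that("solve_size_params matches published-style moment targets", {
  # Monte-Carlo oracle: empirical moments of large samples must sit within
  # 3 sampling SEs of the targets
  cases <- list(list(mean = 66.42, cv = 0.51, skew = -0.03),
                list(mean = 708.47, cv = 0.31, skew = -0.29))
  for (cs in cases) {
    m <- solve_size_params(cs$mean, cs$cv, cs$skew)
    set.seed(101)
    la <- log(draw_areas(4e5, m))
    n <- length(la)
    se_mean_raw <- sd(exp(la)) / sqrt(n)
    expect_lt(abs(mean(exp(la)) - cs$mean), 3 * se_mean_raw)
    cv_hat <- sd(la) / mean(la)
    expect_lt(abs(cv_hat - cs$cv), 0.005)
    sk_hat <- e1071::skewness(la, type = 2)
    se_skew <- sqrt(6 / n)
    expect_lt(abs(sk_hat - cs$skew), 3 * se_skew)
    # analytic moments agree with the solver's own targets to 1e-6
    mm <- coraldemog:::sn_moments(m$xi, m$omega, m$alpha)
    expect_equal(mm$mean_raw, cs$mean, tolerance = 1e-6)
    expect_equal(mm$sd_log / mm$mean_log, cs$cv, tolerance = 1e-6)
    expect_equal(mm$skew_log, cs$skew, tolerance = 1e-6)
  }
})

test_that("zero-variance target degenerates to a point mass", {
  m <- solve_size_params(exp(2.5), 0, 0)
  expect_equal(m$xi, 2.5)
  expect_equal(m$omega, 0)
  expect_equal(unique(draw_areas(50, m)), exp(2.5))
})

test_that("infeasible skewness raises an explicit error", {
  expect_error(solve_size_params(100, 0.5, 0.999), "infeasible")
  expect_error(solve_size_params(100, 0.5, -1.2), "infeasible")
  expect_error(solve_size_params(exp(2.5), 0, 0.3), "point mass")
})

test_that("generate_colony_table plants exact counts and planted rates", {
  m <- solve_size_params(66.42, 0.51, -0.03, taxon = "Pocillopora",
                         habitat = "inshore", n_per_stratum = 50L)
  design <- survey_design(sites = c(S1 = "inshore"),
                          occasions = data.frame(year = 2010L, month = 10L),
                          n_transects = 2L)
  cm <- condition_model(partial_capture_rate = 0)
  tab <- generate_colony_table(list(m), cm, design, seed = 11)
  expect_equal(nrow(tab), 100L)  # fixed counts: 2 transects x 50
  expect_true(all(tab$area_cm2 > 0))
  # reproducibility for a fixed seed
  tab2 <- generate_colony_table(list(m), cm, design, seed = 11)
  expect_identical(tab, tab2)
})

test_that("empty design yields an empty table with full schema", {
  m <- solve_size_params(100, 0.4, 0, taxon = "Acropora",
                         habitat = "inshore", n_per_stratum = 0L)
  design <- survey_design(sites = c(S1 = "inshore"),
                          occasions = data.frame(year = 2010L, month = 10L))
  tab <- generate_colony_table(list(m), condition_model(), design, seed = 1)
  expect_equal(nrow(tab), 0L)
  expect_named(tab, c("site", "shelf", "year", "month", "transect", "genus",
                      "area_cm2", "bleached", "partial_mortality",
                      "partially_captured"))
})

test_that("planted bleaching and partial-capture rates are recovered", {
  # binomial sampling oracle: empirical rate within 3 binomial SEs
  n <- 1e5
  m <- solve_size_params(66.42, 0.51, -0.03, taxon = "Pocillopora",
                         habitat = "inshore", n_per_stratum = as.integer(n))
  design <- survey_design(sites = c(S1 = "inshore"),
                          occasions = data.frame(year = 2010L, month = 10L),
                          n_transects = 1L)
  cm <- condition_model(bleach_intercept = qlogis(0.806), bleach_slope = 0,
                        partial_capture_rate = 0.107)
  tab <- generate_colony_table(list(m), cm, design, seed = 5)
  se_b <- sqrt(0.806 * (1 - 0.806) / n)
  expect_lt(abs(mean(tab$bleached) - 0.806), 3 * se_b)
  se_pc <- sqrt(0.107 * (1 - 0.107) / n)
  expect_lt(abs(mean(tab$partially_captured) - 0.107), 3 * se_pc)
  # partially captured areas are shrunk multiplicatively, never enlarged
  expect_true(all(tab$area_cm2 > 0))
})

test_that("missing stratum model is a configuration error", {
  m <- solve_size_params(100, 0.4, 0, taxon = "Acropora",
                         habitat = "offshore", n_per_stratum = 5L)
  design <- survey_design(sites = c(S1 = "inshore"),
                          occasions = data.frame(year = 2010L, month = 10L))
  expect_error(generate_colony_table(list(m), condition_model(), design,
                                     seed = 1), "no size model")
})

test_that("generate_daily_env: constants, pulses, and gaps behave exactly", {
  # constant series
  em <- env_model(seasonal_amplitude = 0, sst_noise_sd = 0,
                  chla_noise_sd = 0, chla_seasonal_amplitude = 0)
  env <- generate_daily_env(em, c("2010-01-01", "2012-12-31"), seed = 1)
  expect_true(all(env$sst$value == em$baseline_sst))
  expect_false(anyNA(env$sst$value))

  # one +0.7 degC 84-day pulse on a climatology-flat series -> DHW max 8.4
  em2 <- env_model(seasonal_amplitude = 0, sst_noise_sd = 0,
                   anomaly_events = list(list(start = "2011-03-01",
                                              duration = 84,
                                              magnitude = 0.7)))
  env2 <- generate_daily_env(em2, c("2010-01-01", "2012-12-31"), seed = 1)
  clim <- compute_climatology(env$sst)
  dhw <- compute_dhw(env2$sst, clim)
  expect_equal(max(dhw$dhw, na.rm = TRUE), 0.7 * 84 / 7)

  # one 10-day gap window -> exactly 10 missing chlorophyll days
  em3 <- env_model(gap_spec = list(list(start = "2011-06-01", duration = 10)))
  env3 <- generate_daily_env(em3, c("2010-01-01", "2012-12-31"), seed = 1)
  expect_equal(sum(is.na(env3$chla$value)), 10L)

  # too-short record is an error
  expect_error(generate_daily_env(em, c("2010-01-01", "2010-06-30"),
                                  seed = 1), "full year")
})
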