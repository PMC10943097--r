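# Preprocessing, quintile schemes, size summaries, KS comparisons.

test_that("preprocessing applies the 0.8 cm^2 cut-off and period mapping", {
  raw <- rbind(colony_rows(1, area = 0.79),
               colony_rows(1, area = 0.80),
               colony_rows(1, area = 5, year = 2016L, month = 4L),
               colony_rows(1, area = 5, year = 2019L))
  out <- preprocess_colonies(raw)
  expect_equal(nrow(out), 3L)                # 0.79 excluded, 0.80 retained
  expect_equal(min(out$area_cm2), 0.8)
  expect_equal(out$period, c("P1", "P2", "P3"))
  expect_equal(out$log_area, log(out$area_cm2))
})

test_that("partially captured colonies are dropped only in sensitivity mode", {
  raw <- colony_rows(1000, area = 10)
  raw$partially_captured[1:107] <- 1L
  expect_equal(nrow(preprocess_colonies(raw)), 1000L)
  out <- preprocess_colonies(raw, include_partially_captured = FALSE)
  expect_equal(nrow(out), 893L)
  # exclusion never increases stratum counts
  expect_true(nrow(out) <= nrow(preprocess_colonies(raw)))
})

test_that("preprocessing rejects malformed input", {
  raw <- colony_rows(2)
  expect_error(preprocess_colonies(raw[-match("area_cm2", names(raw))]),
               "missing required")
  bad_year <- colony_rows(1, year = 2014L)
  expect_error(preprocess_colonies(bad_year), "period mapping")
  bad_area <- colony_rows(1, area = -1)
  expect_error(preprocess_colonies(bad_area), "non-positive")
  bad_genus <- colony_rows(1); bad_genus$genus <- "Porites"
  expect_error(preprocess_colonies(bad_genus), "unknown genus")
  empty <- preprocess_colonies(colony_rows(0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("period", "log_area") %in% names(empty)))
})

test_that("the shipped synthetic colony CSV round-trips the schema", {
  path <- system.file("extdata", "synthetic_colonies.csv",
                      package = "coraldemog")
  raw <- read.csv(path)
  proc <- preprocess_colonies(raw)
  expect_gt(nrow(proc), 0)
  expect_setequal(unique(proc$period), c("P1", "P2", "P3"))
  expect_true(all(proc$area_cm2 >= 0.8))
  expect_equal(proc$log_area, log(proc$area_cm2))
})

test_that("quintile boundaries follow the linear-interpolation convention", {
  tab <- data.frame(genus = "Acropora", shelf = "inshore", log_area = 1:5)
  sch <- quintile_scheme(tab, "Acropora", "inshore")
  expect_equal(sch$boundaries, c(1.8, 2.6, 3.4, 4.2))
  # identical values: degenerate scheme warns and sends everything to Q5
  tied <- data.frame(genus = "Acropora", shelf = "inshore",
                     log_area = rep(2, 10))
  expect_warning(sch2 <- quintile_scheme(tied, "Acropora", "inshore"),
                 "degenerate")
  expect_equal(unique(assign_size_class(rep(2, 10), sch2)$quintile), 5L)
  expect_error(quintile_scheme(tab[1:3, ], "Acropora", "inshore"),
               "at least 5")
})

test_that("quintiles hold 20% each and classes partition every stratum", {
  set.seed(9)
  n <- 1e5
  tab <- data.frame(genus = "Pocillopora", shelf = "offshore",
                    log_area = rgamma(n, 2, 1))
  sch <- quintile_scheme(tab, "Pocillopora", "offshore")
  cls <- assign_size_class(tab$log_area, sch)
  props <- tabulate(cls$quintile, 5) / n
  expect_true(all(abs(props - 0.2) < 0.005))
  counts <- table(cls$class)
  expect_equal(sum(counts), n)
  expect_equal(unname(counts["small"] + counts["medium"] + counts["large"]),
               n)
  # fixed-across-years contract: subsetting years reuses the pooled scheme
  half <- tab$log_area[1:(n / 2)]
  cls_half <- assign_size_class(half, sch)
  expect_equal(cls_half$quintile, cls$quintile[1:(n / 2)])
})

test_that("size summaries use raw-scale means and log-scale dispersion", {
  tab <- data.frame(genus = "Acropora", shelf = "inshore", period = "P1",
                    area_cm2 = exp(c(2, 4, 6)), log_area = c(2, 4, 6))
  s <- summarize_sizes(tab)
  expect_equal(s$n, 3L)
  expect_equal(s$mean_area, mean(exp(c(2, 4, 6))))
  expect_equal(s$cv, 2 / 4)          # sample SD 2, mean 4, on log scale
  expect_equal(s$skewness, 0)        # symmetric sample
  # scaling all areas by k scales the mean but leaves log-skewness unchanged
  tab2 <- tab; tab2$area_cm2 <- tab$area_cm2 * 10
  tab2$log_area <- log(tab2$area_cm2)
  s2 <- summarize_sizes(tab2)
  expect_equal(s2$mean_area, 10 * s$mean_area)
  expect_equal(s2$skewness, s$skewness)
  # n < 3 -> skewness missing, not zero
  s3 <- summarize_sizes(tab[1:2, ])
  expect_true(is.na(s3$skewness))
  expect_true(s$q20 <= s$q80)
})

test_that("planted skewness is recovered by the summary statistics", {
  m <- solve_size_params(708.47, 0.31, -0.29, taxon = "Turbinaria",
                         habitat = "inshore")
  set.seed(21)
  la <- log(draw_areas(4e5, m))
  tab <- data.frame(genus = "Turbinaria", shelf = "inshore", period = "P1",
                    area_cm2 = exp(la), log_area = la)
  s <- summarize_sizes(tab)
  expect_lt(abs(s$skewness - (-0.29)), 3 * sqrt(6 / length(la)))
})

test_that("KS comparison matches brute-force ECDF supremum", {
  expect_equal(ks_compare(1:10, 1:10)$D, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$D, 1)
  r <- ks_compare(c(1, 3), c(2, 4))
  expect_equal(r$D, 0.5)
  expect_equal(r$n1, 2); expect_equal(r$n2, 2)
  # brute-force oracle on random samples
  set.seed(4)
  a <- rnorm(57); b <- rnorm(101, 0.4)
  grid <- sort(c(a, b))
  brute_D <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(ks_compare(a, b)$D, brute_D)
  # invariance under strictly monotone transforms of both samples
  expect_equal(ks_compare(exp(a), exp(b))$D, brute_D)
  expect_error(ks_compare(numeric(0), b), "nonempty")
})

test_that("ks_table enumerates unordered pairs once", {
  tab <- two_period_table(120, 90, seed = 3)
  tab$genus <- rep(c("Acropora", "Pocillopora", "Turbinaria"),
                   length.out = nrow(tab))
  kt <- ks_table(tab, "genus")
  expect_equal(nrow(kt), 3L)
  expect_true(all(kt$D >= 0 & kt$D <= 1))
})
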