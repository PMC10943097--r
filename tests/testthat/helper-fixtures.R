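# Shared fixture builders for the test suite. All fixtures are built in
# code; nothing is read from disk.

# constant-valued daily series spanning whole years
const_series <- function(value = 20, years = 2010:2012, site = "s1") {
  d <- seq(as.Date(paste0(years[1], "-01-01")),
           as.Date(paste0(years[length(years)], "-12-31")), by = "day")
  data.frame(site = site, date = d, value = value)
}

# seasonal sinusoidal SST: base + amp * sin(2*pi*doy/365)
sine_series <- function(base = 20, amp = 3, years = 2010:2012, site = "s1") {
  s <- const_series(base, years, site)
  doy <- as.integer(format(s$date, "%j"))
  s$value <- base + amp * sin(2 * pi * doy / 365)
  s
}

# minimal schema-complete colony table
colony_rows <- function(n, area = 10, genus = "Acropora", site = "A",
                        shelf = "inshore", year = 2010L, month = 10L,
                        transect = 1L, bleached = 0L, pm = 0L, pc = 0L) {
  data.frame(site = rep_len(site, n), shelf = rep_len(shelf, n),
             year = rep_len(year, n), month = rep_len(month, n),
             transect = rep_len(transect, n), genus = rep_len(genus, n),
             area_cm2 = rep_len(area, n), bleached = rep_len(bleached, n),
             partial_mortality = rep_len(pm, n),
             partially_captured = rep_len(pc, n))
}

# a two-period colony table with planted small-class structure:
# log-areas drawn uniformly, with the P1/P3 sample sizes controlled
two_period_table <- function(n1, n3, seed = 1, sites = c("A", "B")) {
  set.seed(seed)
  mk <- function(n, year) {
    per_site <- diff(round(seq(0, n, length.out = length(sites) + 1)))
    do.call(rbind, lapply(seq_along(sites), function(i) {
      r <- colony_rows(per_site[i], site = sites[i], year = year)
      r$area_cm2 <- exp(runif(per_site[i], 1, 6))
      r
    }))
  }
  preprocess_colonies(rbind(mk(n1, 2010L), mk(n3, 2018L)))
}

# brute-force trailing 84-day inclusive DHW at every valid day
brute_dhw <- function(values, mmm, threshold = 0) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (t in 84:n)
    out[t] <- sum(pmax(0, values[(t - 83):t] - mmm - threshold)) / 7
  out
}

fast_settings <- function(seed = 1, chains = 2L)
  mcmc_settings(chains = chains, iterations = 1200L, warmup = 300L,
                thin = 2L, seed = seed)
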