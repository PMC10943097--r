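# Climatologies and degree heating/cooling week metrics from daily series.
#
# A daily series is a data.frame (site, date, value) on a strictly
# increasing daily grid. SST series must be complete; chlorophyll-a may
# contain missing values until gap-filled.

validate_daily_series <- function(x, allow_missing = FALSE,
                                  name = deparse(substitute(x))) {
  stopifnot(is.data.frame(x), all(c("site", "date", "value") %in% names(x)))
  d <- as.Date(x$date)
  if (nrow(x) > 1 && !all(diff(as.integer(d)) == 1L))
    stop(name, ": dates must be strictly increasing with a daily step")
  if (!allow_missing && anyNA(x$value))
    stop(name, ": series contains missing values")
  if (length(unique(x$site)) != 1)
    stop(name, ": one site per series")
  x$date <- d
  x
}

#' Monthly-mean SST climatology (MMM and mMM)
#'
#' Computes the 12 climatological monthly means of daily SST over a baseline
#' period and derives the maximum of monthly means (MMM), the heat-stress
#' baseline, and the minimum of monthly means (mMM), the cold-stress
#' baseline. The monthly mean for calendar month m is the average over
#' baseline years of that year's month-m mean, so years are weighted equally
#' regardless of record gaps at the ends. Leap days are averaged into
#' February.
#'
#' @param sst daily SST series (site, date, value), no missing values.
#' @param baseline_years optional integer vector of years to use; default is
#'   the full available record.
#' @return object of class \code{coral_climatology}: site, monthly_means
#'   (12), MMM, mMM, baseline year range.
#' @export
compute_climatology <- function(sst, baseline_years = NULL) {
  sst <- validate_daily_series(sst, allow_missing = FALSE, name = "sst")
  yr <- as.integer(format(sst$date, "%Y"))
  mo <- as.integer(format(sst$date, "%m"))
  if (!is.null(baseline_years)) {
    keep <- yr %in% baseline_years
    if (!any(keep)) stop("no data in the requested baseline years")
    sst <- sst[keep, ]; yr <- yr[keep]; mo <- mo[keep]
  }
  covered <- sort(unique(mo))
  if (length(covered) < 12)
    stop("missing calendar month(s) in baseline: ",
         paste(month.name[setdiff(1:12, covered)], collapse = ", "))
  per_year_month <- aggregate(value ~ yr + mo, data =
                                data.frame(value = sst$value, yr = yr, mo = mo),
                              FUN = mean)
  monthly <- vapply(1:12, function(m)
    mean(per_year_month$value[per_year_month$mo == m]), numeric(1))
  structure(list(site = sst$site[1],
                 monthly_means = setNames(monthly, month.abb),
                 MMM = max(monthly), mMM = min(monthly),
                 baseline = range(yr)),
            class = "coral_climatology")
}

#' @export
print.coral_climatology <- function(x, ...) {
  cat("SST climatology for", x$site, " (baseline ",
      paste(x$baseline, collapse = "-"), ")\n", sep = "")
  print(round(x$monthly_means, 2))
  cat(sprintf("MMM = %.2f degC, mMM = %.2f degC\n", x$MMM, x$mMM))
  invisible(x)
}

# trailing 84-day inclusive rolling sum; first 83 entries NA (burn-in)
.roll84 <- function(x) {
  cs <- cumsum(x)
  n <- length(x)
  if (n < 84) stop("series must be at least 84 days long")
  out <- rep(NA_real_, n)
  out[84:n] <- cs[84:n] - c(0, cs[seq_len(n - 84)])
  out
}

.check_site <- function(series, clim) {
  if (!identical(as.character(series$site[1]), as.character(clim$site)))
    stop("site mismatch: series is for '", series$site[1],
         "', climatology for '", clim$site, "'")
}

#' Degree Heating Weeks (DHW)
#'
#' Accumulated weekly heat-stress anomalies: for each day, the sum over the
#' trailing 84 days (12 weeks, inclusive of the current day) of daily SST
#' exceedances above MMM + \code{anomaly_threshold}, divided by 7 to convert
#' days to weeks. With the default 0 deg C threshold every positive anomaly
#' accumulates, so values exceed the conventional satellite DHW product that
#' only accumulates anomalies at least 1 deg C above MMM. The first 83 days
#' are a burn-in and reported as NA.
#'
#' @param sst daily SST series for one site.
#' @param clim \code{coral_climatology} for the same site.
#' @param anomaly_threshold deg C above MMM at which accumulation starts.
#' @return data.frame (site, date, dhw) in deg C-weeks, >= 0 after burn-in.
#' @export
compute_dhw <- function(sst, clim, anomaly_threshold = 0) {
  sst <- validate_daily_series(sst, allow_missing = FALSE, name = "sst")
  stopifnot(inherits(clim, "coral_climatology"))
  .check_site(sst, clim)
  exceed <- pmax(0, sst$value - clim$MMM - anomaly_threshold) / 7
  data.frame(site = sst$site, date = sst$date, dhw = .roll84(exceed))
}

#' Degree Cooling Weeks (DCW)
#'
#' Accumulated weekly cold-stress deficits: the trailing 84-day sum of daily
#' SST deficits below mMM + \code{offset}, divided by 7. Values are stored
#' with a negative sign (more negative = more accumulated cold stress);
#' reporting layers show the magnitude. \code{offset = 0} gives the strict
#' below-mMM metric; \code{offset = 1} starts accumulating as soon as SST is
#' colder than 1 deg C above mMM, capturing low-magnitude cold stress near
#' the poleward range limit of corals.
#'
#' @inheritParams compute_dhw
#' @param offset deg C added to mMM to set the accumulation threshold.
#' @return data.frame (site, date, dcw) in deg C-weeks, <= 0 after burn-in.
#' @export
compute_dcw <- function(sst, clim, offset = 0) {
  sst <- validate_daily_series(sst, allow_missing = FALSE, name = "sst")
  stopifnot(inherits(clim, "coral_climatology"))
  .check_site(sst, clim)
  deficit <- pmin(0, sst$value - (clim$mMM + offset)) / 7
  data.frame(site = sst$site, date = sst$date, dcw = .roll84(deficit))
}

#' Thermal stress series (DHW_0C, DCW_0C, DCW_1C)
#'
#' Convenience wrapper computing the three stress metrics on one grid.
#'
#' @inheritParams compute_dhw
#' @return data.frame of class \code{stress_series} with columns site, date,
#'   dhw0, dcw0, dcw1 (deg C-weeks; dcw columns negative).
#' @export
stress_series <- function(sst, clim) {
  out <- data.frame(site = sst$site, date = as.Date(sst$date),
                    dhw0 = compute_dhw(sst, clim, 0)$dhw,
                    dcw0 = compute_dcw(sst, clim, 0)$dcw,
                    dcw1 = compute_dcw(sst, clim, 1)$dcw)
  class(out) <- c("stress_series", "data.frame")
  out
}

#' Fill chlorophyll-a gaps by linear interpolation
#'
#' Interior runs of missing values are replaced by linear interpolation in
#' time between the flanking observations; leading and trailing gaps are
#' left missing (no extrapolation). Observed values are never changed.
#'
#' @param chla daily series (site, date, value) with possible missing values.
#' @return the series with interior gaps filled.
#' @export
gap_fill_linear <- function(chla) {
  chla <- validate_daily_series(chla, allow_missing = TRUE, name = "chla")
  if (sum(!is.na(chla$value)) < 2)
    stop("need at least 2 non-missing values to interpolate")
  chla$value <- zoo::na.approx(chla$value, x = as.numeric(chla$date),
                               na.rm = FALSE)
  chla
}

#' Annual environmental summaries per site-year
#'
#' Calendar-year means of SST and (gap-filled) chlorophyll-a plus the
#' within-year maxima of the thermal stress metrics: \code{dhw0_max} and the
#' magnitude of the most negative DCW_1C (\code{dcw1_maxmag}, reported
#' positive). Burn-in days (the first 83 of the stress record) are excluded
#' from the maxima. Years with fewer than \code{min_days} days of SST are
#' flagged partial and excluded unless \code{keep_partial = TRUE}.
#'
#' @param sst daily SST series.
#' @param chla_filled gap-filled chlorophyll-a series on the same grid.
#' @param stress \code{\link{stress_series}} on the same grid.
#' @param keep_partial keep partial years (flagged) instead of dropping them.
#' @param min_days minimum days for a complete year (default 360).
#' @return data.frame: site, year, sst_mean, chla_mean, dhw0_max,
#'   dcw1_maxmag, partial.
#' @export
annual_summaries <- function(sst, chla_filled, stress,
                             keep_partial = FALSE, min_days = 360L) {
  sst <- validate_daily_series(sst, allow_missing = FALSE, name = "sst")
  chla_filled <- validate_daily_series(chla_filled, allow_missing = TRUE,
                                       name = "chla_filled")
  stopifnot(inherits(stress, "stress_series"),
            nrow(stress) == nrow(sst), nrow(chla_filled) == nrow(sst))
  yr <- as.integer(format(sst$date, "%Y"))
  years <- sort(unique(yr))
  rows <- lapply(years, function(y) {
    i <- yr == y
    data.frame(site = sst$site[1], year = y,
               sst_mean = mean(sst$value[i]),
               chla_mean = mean(chla_filled$value[i], na.rm = TRUE),
               dhw0_max = if (all(is.na(stress$dhw0[i]))) NA_real_ else
                 max(stress$dhw0[i], na.rm = TRUE),
               dcw1_maxmag = if (all(is.na(stress$dcw1[i]))) NA_real_ else
                 max(-stress$dcw1[i], na.rm = TRUE),
               partial = sum(i) < min_days)
  })
  out <- do.call(rbind, rows)
  if (!keep_partial && any(out$partial)) {
    warning("dropping partial year(s): ",
            paste(out$year[out$partial], collapse = ", "))
    out <- out[!out$partial, ]
  }
  rownames(out) <- NULL
  out
}
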