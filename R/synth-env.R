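# Synthetic daily SST and chlorophyll-a series with planted anomalies.

#' Environmental series model
#'
#' Parameters for synthetic daily sea surface temperature and chlorophyll-a
#' series at one site: a baseline plus seasonal sinusoid (peaking in late
#' Austral summer by default), rectangular heat/cold anomaly pulses, Gaussian
#' noise, and missing-data windows for the chlorophyll record.
#'
#' @param site site label.
#' @param baseline_sst long-term mean SST, deg C.
#' @param seasonal_amplitude seasonal half-range of SST, deg C.
#' @param peak_doy day-of-year at which the SST sinusoid peaks (default 46,
#'   mid February, the Austral summer maximum).
#' @param anomaly_events list of events, each a list with \code{start}
#'   (Date or "YYYY-MM-DD"), \code{duration} (days) and \code{magnitude}
#'   (deg C, signed: positive = heat pulse, negative = cold pulse).
#' @param sst_noise_sd,chla_noise_sd daily Gaussian noise SD.
#' @param chla_baseline,chla_seasonal_amplitude chlorophyll-a baseline and
#'   seasonal half-range, mg m^-3 (winter-peaking: opposite phase to SST).
#' @param gap_spec list of chlorophyll missing-data windows, each a list with
#'   \code{start} and \code{duration} (days).
#' @return object of class \code{env_model}.
#' @export
env_model <- function(site = "site1", baseline_sst = 21,
                      seasonal_amplitude = 3, peak_doy = 46,
                      anomaly_events = list(),
                      sst_noise_sd = 0, chla_baseline = 0.6,
                      chla_seasonal_amplitude = 0.2, chla_noise_sd = 0,
                      gap_spec = list()) {
  stopifnot(seasonal_amplitude >= 0, sst_noise_sd >= 0, chla_noise_sd >= 0)
  structure(list(site = site, baseline_sst = baseline_sst,
                 seasonal_amplitude = seasonal_amplitude, peak_doy = peak_doy,
                 anomaly_events = anomaly_events,
                 sst_noise_sd = sst_noise_sd, chla_baseline = chla_baseline,
                 chla_seasonal_amplitude = chla_seasonal_amplitude,
                 chla_noise_sd = chla_noise_sd, gap_spec = gap_spec),
            class = "env_model")
}

.pulse <- function(dates, events) {
  out <- numeric(length(dates))
  for (ev in events) {
    start <- as.Date(ev$start)
    idx <- dates >= start & dates < start + as.integer(ev$duration)
    out[idx] <- out[idx] + ev$magnitude
  }
  out
}

#' Generate synthetic daily SST and chlorophyll-a series
#'
#' SST is baseline + seasonal sinusoid + configured anomaly pulses + noise
#' and has no missing days; chlorophyll-a is generated analogously (opposite
#' seasonal phase) and then set to missing inside each configured gap window.
#'
#' @param model an \code{\link{env_model}}.
#' @param date_range length-2 vector (Date or "YYYY-MM-DD") of first and last
#'   day, inclusive. Must span at least one full year; two or more full years
#'   are needed before a climatology can be computed downstream.
#' @param seed integer seed.
#' @return list with elements \code{sst} and \code{chla}, each a data.frame
#'   (site, date, value).
#' @export
generate_daily_env <- function(model, date_range, seed) {
  stopifnot(inherits(model, "env_model"))
  if (missing(seed)) stop("a seed is required")
  dates <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  if (length(dates) < 365)
    stop("date range must span at least one full year; ",
         "climatology is undefined on shorter records")
  if (length(dates) < 730)
    warning("date range shorter than two full years; ",
            "climatology baselines will rest on a single year")
  set.seed(as.integer(seed))
  doy <- as.integer(format(dates, "%j"))
  phase <- cos(2 * pi * (doy - model$peak_doy) / 365.25)
  sst <- model$baseline_sst + model$seasonal_amplitude * phase +
    .pulse(dates, model$anomaly_events) +
    rnorm(length(dates), 0, model$sst_noise_sd)
  chla <- model$chla_baseline - model$chla_seasonal_amplitude * phase +
    rnorm(length(dates), 0, model$chla_noise_sd)
  chla <- pmax(chla, 0.01)
  for (gap in model$gap_spec) {
    start <- as.Date(gap$start)
    chla[dates >= start & dates < start + as.integer(gap$duration)] <- NA_real_
  }
  list(sst = data.frame(site = model$site, date = dates, value = sst),
       chla = data.frame(site = model$site, date = dates, value = chla))
}
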