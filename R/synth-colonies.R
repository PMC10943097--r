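# Synthetic colony tables with planted condition probabilities.

#' Condition model for bleaching and partial mortality
#'
#' Logit-scale coefficients linking colony log-area to the probabilities of
#' bleaching and partial mortality, plus the additive (logit) effect of
#' bleached status on partial mortality and the fraction of colonies only
#' partially captured in survey photographs.
#'
#' @param bleach_intercept,bleach_slope logit-scale intercept and log-area
#'   slope for the probability of bleaching.
#' @param pm_intercept,pm_slope logit-scale intercept and log-area slope for
#'   the probability of partial mortality.
#' @param pm_bleached_boost additive logit-scale effect of bleached status on
#'   partial mortality.
#' @param partial_capture_rate proportion of colonies flagged as extending
#'   beyond the photo frame, in [0, 1]. Default 0.107.
#' @return object of class \code{condition_model}.
#' @export
condition_model <- function(bleach_intercept = qlogis(0.2), bleach_slope = 0,
                            pm_intercept = qlogis(0.05), pm_slope = 0,
                            pm_bleached_boost = 0,
                            partial_capture_rate = 0.107) {
  if (partial_capture_rate < 0 || partial_capture_rate > 1)
    stop("partial_capture_rate must lie in [0, 1]")
  structure(list(bleach_intercept = bleach_intercept,
                 bleach_slope = bleach_slope,
                 pm_intercept = pm_intercept, pm_slope = pm_slope,
                 pm_bleached_boost = pm_bleached_boost,
                 partial_capture_rate = partial_capture_rate),
            class = "condition_model")
}

#' Survey design grid
#'
#' Expands sites (with shelf positions), survey occasions and transects into
#' the stratum grid used by \code{\link{generate_colony_table}}. The default
#' mirrors a subtropical monitoring design: two inshore and two offshore
#' sites, three transects, Austral-spring surveys in October with an
#' additional April survey in the bleaching year.
#'
#' @param sites named character vector mapping site name to shelf position
#'   ("inshore" or "offshore").
#' @param occasions data.frame with columns \code{year}, \code{month}.
#' @param n_transects transects per site per occasion.
#' @return data.frame with columns site, shelf, year, month, transect.
#' @export
survey_design <- function(sites = c("Southwest" = "inshore",
                                    "Northwest" = "inshore",
                                    "South" = "offshore",
                                    "North" = "offshore"),
                          occasions = data.frame(
                            year = c(2010L, 2012L, 2016L, 2016L, 2018L, 2019L),
                            month = c(10L, 10L, 4L, 10L, 10L, 10L)),
                          n_transects = 3L) {
  stopifnot(all(sites %in% c("inshore", "offshore")),
            all(c("year", "month") %in% names(occasions)))
  grid <- expand.grid(transect = seq_len(n_transects),
                      occasion = seq_len(nrow(occasions)),
                      site = names(sites), stringsAsFactors = FALSE)
  data.frame(site = grid$site,
             shelf = unname(sites[grid$site]),
             year = occasions$year[grid$occasion],
             month = occasions$month[grid$occasion],
             transect = grid$transect)
}

#' Generate a synthetic colony observation table
#'
#' Draws one row per coral colony for every stratum of a survey design:
#' planar areas from per-taxon, per-habitat skew-normal size models on
#' log-area; bleached and partial-mortality flags from size-dependent
#' logistic models; and a partially-captured flag under which the recorded
#' area is a uniform fraction in [0.3, 1) of the true area, mimicking
#' colonies extending beyond the photo frame.
#'
#' Counts per stratum are fixed at each size model's \code{n_per_stratum}
#' (so planted totals are exact); set \code{count_mode = "poisson"} to draw
#' Poisson counts with that mean instead.
#'
#' @param size_models list of \code{\link{solve_size_params}} models; each
#'   must carry \code{taxon} and \code{habitat} labels. Every design stratum
#'   must be covered by a model for its habitat.
#' @param condition_models either one \code{\link{condition_model}} applied
#'   to all taxa, or a named list keyed by taxon.
#' @param design stratum grid from \code{\link{survey_design}}.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @param count_mode "fixed" (default) or "poisson".
#' @return data.frame with columns site, shelf, year, month, transect, genus,
#'   area_cm2, bleached, partial_mortality, partially_captured.
#' @export
generate_colony_table <- function(size_models, condition_models, design,
                                  seed, count_mode = c("fixed", "poisson")) {
  count_mode <- match.arg(count_mode)
  if (missing(seed)) stop("a seed is required")
  if (inherits(size_models, "taxon_size_model"))
    size_models <- list(size_models)
  if (inherits(condition_models, "condition_model")) {
    taxa <- unique(vapply(size_models, `[[`, "", "taxon"))
    condition_models <- setNames(rep(list(condition_models), length(taxa)),
                                 taxa)
  }
  set.seed(as.integer(seed))

  schema <- data.frame(site = character(), shelf = character(),
                       year = integer(), month = integer(),
                       transect = integer(), genus = character(),
                       area_cm2 = numeric(), bleached = integer(),
                       partial_mortality = integer(),
                       partially_captured = integer())

  out <- vector("list", nrow(design) * length(size_models))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    habitat_models <- size_models[vapply(size_models, function(m)
      is.na(m$habitat) || m$habitat == row$shelf, TRUE)]
    if (length(habitat_models) == 0)
      stop("no size model covers stratum ", row$site, "/", row$shelf)
    for (m in habitat_models) {
      cm <- condition_models[[m$taxon]]
      if (is.null(cm))
        stop("no condition model configured for taxon ", m$taxon)
      n <- if (count_mode == "fixed") m$n_per_stratum else
        rpois(1, m$n_per_stratum)
      if (n == 0) next
      area_true <- draw_areas(n, m)
      log_area <- log(area_true)
      p_bleach <- plogis(cm$bleach_intercept + cm$bleach_slope * log_area)
      bleached <- rbinom(n, 1, p_bleach)
      p_pm <- plogis(cm$pm_intercept + cm$pm_slope * log_area +
                       cm$pm_bleached_boost * bleached)
      pm <- rbinom(n, 1, p_pm)
      pc <- rbinom(n, 1, cm$partial_capture_rate)
      area_obs <- area_true
      if (any(pc == 1)) {
        frac <- runif(sum(pc == 1), 0.3, 1)
        area_obs[pc == 1] <- area_true[pc == 1] * frac
      }
      k <- k + 1L
      out[[k]] <- data.frame(site = row$site, shelf = row$shelf,
                             year = row$year, month = row$month,
                             transect = row$transect, genus = m$taxon,
                             area_cm2 = area_obs, bleached = bleached,
                             partial_mortality = pm, partially_captured = pc)
    }
  }
  if (k == 0L) return(schema)
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
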