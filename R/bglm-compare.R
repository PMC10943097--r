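# LOOIC model comparison, collinearity screening, and the small-coral
# candidate model set.

#' Compare bglm fits by LOOIC model weights
#'
#' Computes LOOIC differences to the best model and pseudo-Bayesian model
#' averaging weights w_i proportional to exp(-delta_i / 2), normalised to
#' sum to 1 — the relative likelihood of each model within the set. All
#' fits must be to the identical response vector; fits flagged unconverged
#' are refused unless \code{force = TRUE}.
#'
#' @param fits list of \code{\link{bglm}} fits (named, or ids supplied).
#' @param ids optional model labels.
#' @param force compare despite convergence flags.
#' @return data.frame of class \code{bglm_comparison}: model, looic, se,
#'   delta_looic, weight, bayes_r2; ordered by weight.
#' @export
compare_models <- function(fits, ids = NULL, force = FALSE) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "bglm")))
  ids <- ids %||% names(fits) %||% paste0("model", seq_along(fits))
  y0 <- fits[[1]]$y
  same <- vapply(fits, function(f) length(f$y) == length(y0) &&
                   all(f$y == y0), TRUE)
  if (!all(same))
    stop("all models must be fitted to the identical response vector")
  if (!force && !all(vapply(fits, `[[`, TRUE, "converged")))
    stop("unconverged fit(s) in the set; refit or use force = TRUE")
  looic <- vapply(fits, function(f) f$loo$looic, numeric(1))
  se <- vapply(fits, function(f) f$loo$se, numeric(1))
  delta <- looic - min(looic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = ids, looic = looic, se = se,
                    delta_looic = delta, weight = w,
                    bayes_r2 = vapply(fits, function(f) f$bayes_r2$median,
                                      numeric(1)))
  out <- out[order(-out$weight), ]
  rownames(out) <- NULL
  class(out) <- c("bglm_comparison", "data.frame")
  out
}

#' @export
print.bglm_comparison <- function(x, digits = 3, ...) {
  cat("LOOIC model comparison (pseudo-BMA weights)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df)
  invisible(x)
}

#' Screen environmental predictors for collinearity
#'
#' Computes the pairwise Pearson correlation matrix of candidate predictors
#' and, for each pair with |r| above the threshold, retains the member
#' ranked higher in the priority list (default priority puts the 1 degC
#' cold-stress metric DCW1 above DCW0, matching the convention of keeping
#' the more sensitive cold-stress metric). Constant predictors have
#' undefined correlations and are flagged and excluded.
#'
#' @param env_table data.frame of numeric predictor columns (rows =
#'   site-years).
#' @param r_threshold absolute correlation above which a pair is collinear.
#' @param priority character vector; earlier entries win collinear pairs.
#'   Predictors not listed rank below all listed ones, ties broken by
#'   column order.
#' @return list: retained (character), dropped, flagged (constant columns),
#'   cor_matrix.
#' @export
collinearity_screen <- function(env_table, r_threshold = 0.8,
                                priority = c("DCW1", "DCW0", "SST_mean",
                                             "Chla_mean", "DHW0")) {
  stopifnot(is.data.frame(env_table), ncol(env_table) >= 2)
  if (nrow(env_table) < 3) stop("need at least 3 rows to estimate correlations")
  num <- vapply(env_table, is.numeric, TRUE)
  env_table <- env_table[num]
  const <- vapply(env_table, function(v) sd(v) == 0 || all(is.na(v)), TRUE)
  flagged <- names(env_table)[const]
  work <- env_table[!const]
  cm <- cor(work, use = "pairwise.complete.obs")
  rank_of <- function(nm) {
    i <- match(nm, priority)
    ifelse(is.na(i), length(priority) + match(nm, names(work)), i)
  }
  retained <- names(work)
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    off <- abs(sub); diag(off) <- 0
    if (all(off <= r_threshold, na.rm = TRUE)) break
    worst <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    drop_member <- pair[which.max(rank_of(pair))]
    retained <- setdiff(retained, drop_member)
  }
  list(retained = retained, dropped = setdiff(names(work), retained),
       flagged = flagged, cor_matrix = cm)
}

#' Candidate model formulas for small-coral abundance
#'
#' All additive subsets of the screened environmental predictors (plus the
#' intercept-only model) as negative-binomial count-model formulas for
#' per-site-year small-coral abundance. Four predictors give 16 candidate
#' models.
#'
#' @param predictors character vector of retained predictor names.
#' @param response response column name (default "n_small").
#' @return named list of formulas.
#' @export
small_coral_model_set <- function(predictors = c("SST_mean", "Chla_mean",
                                                 "DHW0", "DCW1"),
                                  response = "n_small") {
  stopifnot(length(predictors) >= 1)
  subsets <- unlist(lapply(0:length(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  specs <- lapply(subsets, function(ss) {
    rhs <- if (length(ss)) paste(ss, collapse = " + ") else "1"
    as.formula(paste(response, "~", rhs))
  })
  names(specs) <- vapply(subsets, function(ss)
    if (length(ss)) paste(ss, collapse = "+") else "intercept_only", "")
  specs
}

#' Fit and compare the small-coral candidate model set
#'
#' Joins annual environmental summaries to per-site-year small-coral counts
#' for one taxon, fits every candidate negative-binomial model and returns
#' the LOOIC comparison together with the fits.
#'
#' @param counts data.frame with columns site, year, n_small (counts pooled
#'   across transects per site-year).
#' @param env annual summaries from \code{\link{annual_summaries}} (site,
#'   year, SST/Chla means and stress maxima); column names are matched to
#'   predictor names SST_mean, Chla_mean, DHW0, DCW1.
#' @param settings \code{\link{mcmc_settings}}.
#' @param r_threshold collinearity threshold passed to the screen.
#' @return list: comparison (\code{bglm_comparison}), fits, screen, data.
#' @export
fit_small_coral_models <- function(counts, env, settings = mcmc_settings(),
                                   r_threshold = 0.8) {
  names(env)[names(env) == "dhw0_max"] <- "DHW0"
  names(env)[names(env) == "dcw1_maxmag"] <- "DCW1"
  names(env)[names(env) == "sst_mean"] <- "SST_mean"
  names(env)[names(env) == "chla_mean"] <- "Chla_mean"
  dat <- merge(counts, env, by = c("site", "year"))
  if (nrow(dat) == 0) stop("empty join between counts and env summaries")
  preds <- intersect(c("SST_mean", "Chla_mean", "DHW0", "DCW1"), names(dat))
  screen <- collinearity_screen(dat[preds], r_threshold = r_threshold)
  specs <- small_coral_model_set(screen$retained)
  fits <- lapply(seq_along(specs), function(i) {
    s <- settings
    s$seed <- derive_seed(settings$seed, i)
    bglm(specs[[i]], dat, family = "negbin", settings = s)
  })
  names(fits) <- names(specs)
  list(comparison = compare_models(fits, force = TRUE), fits = fits,
       screen = screen, data = dat)
}
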