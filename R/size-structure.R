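# Preprocessing, quintile size classes and size-frequency summaries.

CORAL_TAXA <- c("Acropora", "Pocillopora", "Turbinaria")

# survey-year grouping: P1 pre-bleaching, P2 bleaching year, P3 recovery
.period_map <- function(year) {
  p <- rep(NA_character_, length(year))
  p[year %in% c(2010L, 2012L)] <- "P1"
  p[year == 2016L] <- "P2"
  p[year %in% c(2018L, 2019L)] <- "P3"
  p
}

#' Preprocess a raw colony observation table
#'
#' Applies the analysis conventions for colony-level data: drops colonies
#' below the 0.8 cm^2 lower size cut-off (~ 1 cm diameter, the smallest size
#' that is captured consistently across surveys), assigns survey periods
#' (2010/2012 -> P1; 2016 -> P2; 2018/2019 -> P3), adds natural-log area,
#' and optionally removes partially captured colonies (the sensitivity mode;
#' by default they are retained because their observed areas are still
#' informative about abundance).
#'
#' @param raw data.frame with columns site, shelf, year, month, transect,
#'   genus, area_cm2, bleached, partial_mortality, partially_captured.
#' @param include_partially_captured if FALSE, drop colonies flagged
#'   partially captured.
#' @param taxa allowed genus labels.
#' @return the filtered table with added columns \code{period} and
#'   \code{log_area}.
#' @export
preprocess_colonies <- function(raw, include_partially_captured = TRUE,
                                taxa = CORAL_TAXA) {
  needed <- c("site", "shelf", "year", "month", "transect", "genus",
              "area_cm2", "bleached", "partial_mortality",
              "partially_captured")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_genus <- setdiff(unique(raw$genus), taxa)
  if (length(bad_genus))
    stop("unknown genus label(s): ", paste(bad_genus, collapse = ", "))
  if (nrow(raw) > 0 && any(raw$area_cm2 <= 0))
    stop("non-positive colony area in row(s): ",
         paste(utils::head(which(raw$area_cm2 <= 0), 10), collapse = ", "))
  period <- .period_map(raw$year)
  if (nrow(raw) > 0 && anyNA(period))
    stop("year(s) outside the survey-period mapping in row(s): ",
         paste(utils::head(which(is.na(period)), 10), collapse = ", "))
  out <- raw
  out$period <- period
  keep <- if (nrow(out)) out$area_cm2 >= 0.8 else logical(0)
  if (!include_partially_captured && nrow(out))
    keep <- keep & out$partially_captured == 0
  out <- out[keep, ]
  out$log_area <- log(out$area_cm2)
  rownames(out) <- NULL
  out
}

#' Quintile size-class scheme for one genus and habitat
#'
#' Size-class boundaries are the 20/40/60/80th percentiles of log-area
#' pooled across all years within a genus x habitat stratum (linear
#' interpolation between order statistics). The same boundaries are applied
#' to every year, so temporal change is measured against a fixed reference.
#' Classes: Q1 = small, Q2-Q4 = medium, Q5 = large. Bins are
#' left-closed/right-open; a value equal to a boundary goes to the upper
#' bin.
#'
#' @param table preprocessed colony table.
#' @param genus,habitat stratum selectors (habitat matches column
#'   \code{shelf}).
#' @return object of class \code{quintile_scheme}: genus, habitat,
#'   boundaries (4 ascending log-area cut points), n_pooled.
#' @export
quintile_scheme <- function(table, genus, habitat) {
  pool <- table$log_area[table$genus == genus & table$shelf == habitat]
  if (length(pool) < 5)
    stop("need at least 5 colonies pooled across years for ", genus, "/",
         habitat, "; got ", length(pool))
  b <- unname(quantile(pool, c(0.2, 0.4, 0.6, 0.8), type = 7))
  if (anyDuplicated(b))
    warning("degenerate quintile scheme for ", genus, "/", habitat,
            ": tied boundaries; classes will be unbalanced")
  structure(list(genus = genus, habitat = habitat, boundaries = b,
                 n_pooled = length(pool)),
            class = "quintile_scheme")
}

#' @export
print.quintile_scheme <- function(x, ...) {
  cat("Quintile size-class scheme:", x$genus, "/", x$habitat,
      sprintf("(n = %d pooled)\n", x$n_pooled))
  cat("log-area boundaries:", paste(sprintf("%.3f", x$boundaries),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Assign quintile and size class under a fixed scheme
#'
#' @param log_area numeric vector of log-areas.
#' @param scheme a \code{\link{quintile_scheme}}.
#' @return data.frame with columns \code{quintile} (1-5) and \code{class}
#'   ("small", "medium", "large").
#' @export
assign_size_class <- function(log_area, scheme) {
  stopifnot(inherits(scheme, "quintile_scheme"))
  q <- findInterval(log_area, scheme$boundaries) + 1L
  cls <- c("small", "medium", "medium", "medium", "large")[q]
  data.frame(quintile = q, class = factor(cls, levels =
                                            c("small", "medium", "large")))
}

# adjusted Fisher-Pearson sample skewness; NA below n = 3
.skewness <- function(x) {
  if (length(x) < 3 || sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}

#' Size-frequency summaries per stratum
#'
#' For each stratum (default genus x shelf x period): colony count, mean
#' area on the raw cm^2 scale, and — on the log-area scale — the coefficient
#' of variation (sigma/mu), adjusted Fisher-Pearson skewness, and the 20th
#' and 80th percentiles (the 1st/5th quintile boundaries of that stratum's
#' own distribution). CV and skewness are computed on log-area because the
#' size-frequency distribution is analysed on that scale; the mean is
#' reported in raw cm^2.
#'
#' @param table preprocessed colony table.
#' @param by character vector of stratum columns.
#' @return data.frame: stratum columns, n, mean_area, cv, skewness, q20,
#'   q80.
#' @export
summarize_sizes <- function(table, by = c("genus", "shelf", "period")) {
  stopifnot(all(by %in% names(table)), "log_area" %in% names(table))
  key <- interaction(table[by], drop = TRUE, sep = "\r")
  if (nrow(table) == 0)
    return(cbind(table[0, by, drop = FALSE],
                 data.frame(n = integer(), mean_area = numeric(),
                            cv = numeric(), skewness = numeric(),
                            q20 = numeric(), q80 = numeric())))
  rows <- lapply(levels(key), function(k) {
    i <- key == k
    la <- table$log_area[i]
    labels <- as.data.frame(table[which(i)[1], by, drop = FALSE])
    qq <- quantile(la, c(0.2, 0.8), type = 7)
    cbind(labels,
          data.frame(n = sum(i), mean_area = mean(table$area_cm2[i]),
                     cv = sd(la) / mean(la), skewness = .skewness(la),
                     q20 = unname(qq[1]), q80 = unname(qq[2])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of size distributions
#'
#' Two-sided KS test comparing the empirical distributions of log-area in
#' two groups; D is the supremum difference between the two ECDFs and the
#' p-value is asymptotic (groups are pooled across transects).
#'
#' @param a,b numeric vectors of log-areas (both nonempty).
#' @return object of class \code{ks_result}: D, p_value, n1, n2.
#' @export
ks_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  structure(list(D = unname(kt$statistic), p_value = unname(kt$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("2-sample KS: D = %.3f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$D, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' All pairwise KS comparisons over a grouping column
#'
#' @param table preprocessed colony table.
#' @param group column to compare across (e.g. "genus", "shelf", "period").
#' @return data.frame with one row per unordered pair: group_a, group_b, D,
#'   p_value, n1, n2.
#' @export
ks_table <- function(table, group = "genus") {
  levels <- sort(unique(as.character(table[[group]])))
  if (length(levels) < 2) stop("need at least two groups to compare")
  pairs <- utils::combn(levels, 2)
  rows <- apply(pairs, 2, function(pr) {
    r <- ks_compare(table$log_area[table[[group]] == pr[1]],
                    table$log_area[table[[group]] == pr[2]])
    data.frame(group_a = pr[1], group_b = pr[2], D = r$D,
               p_value = r$p_value, n1 = r$n1, n2 = r$n2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
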