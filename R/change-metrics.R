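# Bootstrap estimation of percentage change between survey periods.

#' Percentage change
#'
#' 100 * (after - before) / before. A zero baseline leaves the change
#' undefined: it is returned as NA with a warning rather than +/-Inf.
#'
#' @param before,after baseline and comparison values (counts or metrics).
#' @return percentage change, elementwise.
#' @export
percent_change <- function(before, after) {
  stopifnot(length(before) == length(after))
  if (any(before < 0, na.rm = TRUE)) stop("negative baseline value")
  out <- 100 * (after - before) / before
  if (any(before == 0, na.rm = TRUE)) {
    warning("zero baseline: percentage change undefined, returned NA")
    out[before == 0] <- NA_real_
  }
  out
}

#' Highest posterior density interval of a sample
#'
#' The shortest contiguous interval containing ceiling(mass * n) of the
#' sorted sample values — the sample HPD interval used to summarise
#' bootstrap replicate distributions and posterior draws.
#'
#' @param samples numeric vector (nonempty; NAs dropped).
#' @param mass interval mass in (0, 1); 0.66 and 0.95 are the conventional
#'   reporting levels here.
#' @return named numeric vector c(lower, upper).
#' @export
hpd <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop("empty sample set")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  m <- min(n, max(1L, ceiling(mass * n)))
  widths <- s[m:n] - s[seq_len(n - m + 1L)]
  j <- which.min(widths)
  c(lower = s[j], upper = s[j + m - 1L])
}

# per-replicate statistics of one period's colonies within a genus x habitat
# stratum: fixed-scheme class counts plus distribution metrics
.period_stats <- function(log_area, area, scheme) {
  cls <- assign_size_class(log_area, scheme)$class
  counts <- tabulate(cls, nbins = 3)
  qq <- quantile(log_area, c(0.2, 0.8), type = 7)
  c(small = counts[1], medium = counts[2], large = counts[3],
    mean = mean(area), cv = sd(log_area) / mean(log_area),
    q20 = unname(qq[1]), q80 = unname(qq[2]))
}

#' Bootstrap percentage changes in size-class abundance and size metrics
#'
#' For each genus x habitat stratum and period pair, estimates the
#' percentage change in the abundance of small (Q1), medium (Q2-Q4) and
#' large (Q5) colonies — classes fixed by the pooled quintile scheme — and
#' in the mean, CV and 20th/80th percentiles of colony size. Uncertainty
#' comes from a stratified nonparametric bootstrap: colonies are resampled
#' with replacement within site x period cells, all statistics are
#' recomputed per replicate with the fixed scheme, and the replicate
#' distribution of percentage changes is summarised by its median and 66%
#' and 95% HPD intervals.
#'
#' @param table preprocessed colony table.
#' @param schemes named list of \code{\link{quintile_scheme}} objects keyed
#'   "genus/habitat"; missing entries are computed from \code{table}.
#' @param period_pairs list of length-2 character vectors, e.g.
#'   \code{list(c("P1","P3"))}.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param unit resampling unit: "colony" (default) or "transect"
#'   (site x transect blocks resampled within site x period, a sensitivity
#'   mode).
#' @return data.frame of class \code{change_estimates}: genus, habitat,
#'   quantity, period_pair, before, after, point_pct, median_pct, hpd66/95
#'   bounds, n_boot.
#' @export
bootstrap_changes <- function(table, schemes = NULL,
                              period_pairs = list(c("P1", "P3")),
                              n_boot = 1000L, seed = 1L,
                              unit = c("colony", "transect")) {
  unit <- match.arg(unit)
  set.seed(as.integer(seed))
  strata <- unique(table[c("genus", "shelf")])
  quantities <- c("small", "medium", "large", "mean", "cv", "q20", "q80")
  out <- list()
  for (i in seq_len(nrow(strata))) {
    g <- strata$genus[i]; h <- strata$shelf[i]
    key <- paste(g, h, sep = "/")
    scheme <- schemes[[key]] %||% quintile_scheme(table, g, h)
    sub <- table[table$genus == g & table$shelf == h, ]
    for (pp in period_pairs) {
      a <- sub[sub$period == pp[1], ]
      b <- sub[sub$period == pp[2], ]
      pair_lab <- paste(pp, collapse = "-")
      if (nrow(a) == 0 || nrow(b) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          genus = g, habitat = h, quantity = quantities,
          period_pair = pair_lab, before = NA_real_, after = NA_real_,
          point_pct = NA_real_, median_pct = NA_real_,
          hpd66_lo = NA_real_, hpd66_hi = NA_real_,
          hpd95_lo = NA_real_, hpd95_hi = NA_real_, n_boot = 0L,
          missing = TRUE)
        next
      }
      stat_a <- .period_stats(a$log_area, a$area_cm2, scheme)
      stat_b <- .period_stats(b$log_area, b$area_cm2, scheme)
      point <- suppressWarnings(percent_change(stat_a, stat_b))
      reps <- .boot_replicates(a, b, scheme, n_boot, unit)
      med <- apply(reps, 2, median, na.rm = TRUE)
      h66 <- apply(reps, 2, function(x) if (all(is.na(x)))
        c(NA_real_, NA_real_) else hpd(x, 0.66))
      h95 <- apply(reps, 2, function(x) if (all(is.na(x)))
        c(NA_real_, NA_real_) else hpd(x, 0.95))
      out[[length(out) + 1L]] <- data.frame(
        genus = g, habitat = h, quantity = quantities,
        period_pair = pair_lab,
        before = unname(stat_a), after = unname(stat_b),
        point_pct = unname(point), median_pct = unname(med),
        hpd66_lo = h66[1, ], hpd66_hi = h66[2, ],
        hpd95_lo = h95[1, ], hpd95_hi = h95[2, ],
        n_boot = as.integer(n_boot), missing = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("change_estimates", "data.frame")
  res
}

# replicate matrix of percentage changes (n_boot x 7 quantities)
.boot_replicates <- function(a, b, scheme, n_boot, unit) {
  resample_idx <- function(df) {
    if (unit == "colony") {
      cell <- interaction(df$site, drop = TRUE)
      unlist(lapply(split(seq_len(nrow(df)), cell), function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
    } else {
      blk <- interaction(df$site, df$transect, drop = TRUE)
      split_ix <- split(seq_len(nrow(df)), blk)
      per_site <- split(seq_along(split_ix),
                        vapply(split_ix, function(ix)
                          as.character(df$site[ix[1]]), ""))
      unlist(lapply(per_site, function(bs)
        unlist(split_ix[bs[sample.int(length(bs), length(bs),
                                      replace = TRUE)]],
               use.names = FALSE)), use.names = FALSE)
    }
  }
  reps <- matrix(NA_real_, n_boot, 7,
                 dimnames = list(NULL, c("small", "medium", "large", "mean",
                                         "cv", "q20", "q80")))
  for (r in seq_len(n_boot)) {
    ia <- resample_idx(a); ib <- resample_idx(b)
    sa <- .period_stats(a$log_area[ia], a$area_cm2[ia], scheme)
    sb <- .period_stats(b$log_area[ib], b$area_cm2[ib], scheme)
    reps[r, ] <- suppressWarnings(percent_change(sa, sb))
  }
  reps
}
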