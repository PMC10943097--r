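# Skew-normal machinery for colony size models.
#
# Colony areas are modelled as exp(X) with X ~ SN(xi, omega, alpha) on the
# natural-log scale. The skew-normal admits closed forms for every quantity
# the solver needs: with delta = alpha / sqrt(1 + alpha^2) and b = sqrt(2/pi),
#   E[X]    = xi + omega * delta * b
#   Var[X]  = omega^2 * (1 - delta^2 * b^2)
#   skew[X] = (4 - pi)/2 * (delta b)^3 / (1 - delta^2 b^2)^(3/2)
#   E[e^X]  = 2 * exp(xi + omega^2/2) * pnorm(omega * delta)   (MGF at t = 1)
# so moment matching reduces to one closed-form inversion (skewness -> delta)
# and a single 1-D root find (raw-scale mean -> omega).

# maximum |skewness| attainable by a skew-normal (delta -> 1 limit)
.sn_max_skew <- function() {
  b <- sqrt(2 / pi)
  (4 - pi) / 2 * b^3 / (1 - b^2)^1.5
}

sn_moments <- function(xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u <- delta * sqrt(2 / pi)
  mean_log <- xi + omega * u
  sd_log <- omega * sqrt(1 - u^2)
  skew_log <- (4 - pi) / 2 * u^3 / (1 - u^2)^1.5
  mean_raw <- 2 * exp(xi + omega^2 / 2) * pnorm(omega * delta)
  list(mean_log = mean_log, sd_log = sd_log, skew_log = skew_log,
       mean_raw = mean_raw)
}

# skew-normal variates via the Azzalini two-normal representation
rsn <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z1 <- abs(rnorm(n))
  z2 <- rnorm(n)
  xi + omega * (delta * z1 + sqrt(1 - delta^2) * z2)
}

#' Solve a skew-normal size model from target moments
#'
#' Finds the skew-normal distribution on log-area whose implied raw-scale
#' mean area, log-scale coefficient of variation and log-scale skewness match
#' the given targets. Used to plant published size-structure summaries
#' (mean colony area in cm^2, CV and skewness of log-transformed area) in the
#' synthetic colony generator so that downstream summaries can recover them.
#'
#' The skewness target determines the shape parameter in closed form; the
#' remaining two targets are satisfied by solving one monotone equation for
#' the scale parameter numerically (to within 1e-9 on the log of the
#' raw-scale mean).
#'
#' @param target_mean_area desired raw-scale mean colony area (cm^2), > 0.8.
#' @param target_cv_log desired coefficient of variation sigma/mu of log-area
#'   (> 0; 0 gives the degenerate point-mass limit and requires zero skew).
#' @param target_skew_log desired skewness of log-area; must be strictly
#'   inside the skew-normal feasible range (about +/- 0.995).
#' @param taxon,habitat optional stratum labels stored on the model.
#' @param n_per_stratum expected colony count per site x survey stratum.
#' @return an object of class \code{taxon_size_model} with elements
#'   \code{xi}, \code{omega}, \code{alpha} (skew-normal parameters on
#'   log-area), the stratum labels and the targets.
#' @examples
#' m <- solve_size_params(66.42, 0.51, -0.03)
#' sn_params <- unclass(m)[c("xi", "omega", "alpha")]
#' @export
solve_size_params <- function(target_mean_area, target_cv_log,
                              target_skew_log,
                              taxon = NA_character_, habitat = NA_character_,
                              n_per_stratum = 100L) {
  stopifnot(is.numeric(target_mean_area), length(target_mean_area) == 1,
            is.numeric(target_cv_log), length(target_cv_log) == 1,
            is.numeric(target_skew_log), length(target_skew_log) == 1)
  if (target_mean_area <= 0.8)
    stop("target_mean_area must exceed the 0.8 cm^2 analysis cut-off")
  if (target_cv_log < 0)
    stop("target_cv_log must be >= 0")
  if (abs(target_skew_log) >= .sn_max_skew())
    stop("infeasible skewness target: |skewness| must be < ",
         format(.sn_max_skew(), digits = 6),
         " for a skew-normal; got ", target_skew_log)

  if (target_cv_log == 0) {
    # degenerate point mass at log(mean); only defined for zero skewness
    if (target_skew_log != 0)
      stop("zero log-scale CV implies a point mass; skewness target must be 0")
    out <- list(xi = log(target_mean_area), omega = 0, alpha = 0)
  } else {
    # closed-form inversion of the skewness formula for u = delta * sqrt(2/pi)
    g <- target_skew_log
    tt <- sign(g) * (2 * abs(g) / (4 - pi))^(1 / 3)
    u <- tt / sqrt(1 + tt^2)
    b <- sqrt(2 / pi)
    delta <- u / b
    k <- sqrt(1 - u^2)
    # for given omega: sd = omega*k, mean_log = sd/cv, xi = mean_log - omega*u
    log_target <- log(target_mean_area)
    fn <- function(omega) {
      xi <- omega * (k / target_cv_log - u)
      xi + omega^2 / 2 + log(2 * pnorm(omega * delta)) - log_target
    }
    lo <- 1e-12
    hi <- 1
    while (fn(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (fn(lo) > 0 || fn(hi) < 0)
      stop("could not bracket a scale solution for the given targets")
    omega <- uniroot(fn, c(lo, hi), tol = 1e-12)$root
    xi <- omega * (k / target_cv_log - u)
    alpha <- delta / sqrt(1 - delta^2)
    out <- list(xi = xi, omega = omega, alpha = alpha)
  }

  out$taxon <- taxon
  out$habitat <- habitat
  out$n_per_stratum <- as.integer(n_per_stratum)
  out$targets <- c(mean_area = target_mean_area, cv_log = target_cv_log,
                   skew_log = target_skew_log)
  class(out) <- "taxon_size_model"
  out
}

#' @export
print.taxon_size_model <- function(x, ...) {
  cat("Skew-normal colony size model on log-area\n")
  if (!is.na(x$taxon)) cat("  stratum: ", x$taxon, " / ", x$habitat, "\n",
                           sep = "")
  cat(sprintf("  xi = %.4f, omega = %.4f, alpha = %.4f\n",
              x$xi, x$omega, x$alpha))
  m <- sn_moments(x$xi, x$omega, x$alpha)
  cat(sprintf("  implied mean area %.2f cm^2, log-CV %.4f, log-skew %.4f\n",
              m$mean_raw, m$sd_log / m$mean_log, m$skew_log))
  invisible(x)
}

#' Draw colony areas from a size model
#'
#' @param n number of colonies.
#' @param model a \code{taxon_size_model}.
#' @return numeric vector of planar areas in cm^2 (strictly positive).
#' @export
draw_areas <- function(n, model) {
  stopifnot(inherits(model, "taxon_size_model"))
  if (model$omega == 0) return(rep(exp(model$xi), n))
  exp(rsn(n, model$xi, model$omega, model$alpha))
}
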