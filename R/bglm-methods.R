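# S3 methods for bglm fits.

#' @export
print.bglm <- function(x, ...) {
  cat("Bayesian GLM (", x$family, "), fitted with JAGS\n", sep = "")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d chains x %d iterations (warmup %d, thin %d): %d draws\n",
              x$settings$chains, x$settings$iterations, x$settings$warmup,
              x$settings$thin, nrow(x$draws)))
  cat(sprintf("  Bayes R2 = %.3f, LOOIC = %.1f (SE %.1f)%s\n",
              x$bayes_r2$median, x$loo$looic, x$loo$se,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.bglm <- function(object, ...) {
  tab <- data.frame(median = object$medians,
                    hpd95_lo = object$hpd95[, "lower"],
                    hpd95_hi = object$hpd95[, "upper"],
                    rhat = object$rhat[names(object$medians)])
  out <- list(family = object$family, formula = object$formula,
              coefficients = tab, bayes_r2 = object$bayes_r2$median,
              looic = object$loo$looic, looic_se = object$loo$se,
              converged = object$converged, ppc = object$ppc)
  class(out) <- "summary.bglm"
  out
}

#' @export
print.summary.bglm <- function(x, digits = 3, ...) {
  cat("Bayesian GLM (", x$family, "): ", deparse(x$formula), "\n\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("\nBayes R2 = %.3f; LOOIC = %.1f (SE %.1f); converged: %s\n",
              x$bayes_r2, x$looic, x$looic_se, x$converged))
  cat(sprintf("PPC tail probabilities: mean %.2f, sd %.2f\n",
              x$ppc$p_mean, x$ppc$p_sd))
  invisible(x)
}

#' @export
coef.bglm <- function(object, ...) {
  object$medians[colnames(object$X)]
}

#' Posterior predictions from a bglm fit
#'
#' Builds the design matrix for new covariate values (applying the stored
#' standardization), pushes every retained posterior draw through the
#' inverse link, and summarises each row's predictive distribution by its
#' posterior median and 95% HPD interval. Unknown factor levels are an
#' error; continuous covariates outside the range observed at fit time
#' trigger an extrapolation warning.
#'
#' @param object a \code{\link{bglm}} fit.
#' @param newdata data.frame of covariate values; defaults to the training
#'   data.
#' @param type "response" (inverse-link scale, default) or "link".
#' @param summary if FALSE, return the full draw matrix (rows = newdata
#'   rows, columns = draws).
#' @param ... unused.
#' @return data.frame (median, hpd95_lo, hpd95_hi) or a draw matrix.
#' @export
predict.bglm <- function(object, newdata = NULL, type = c("response", "link"),
                         summary = TRUE, ...) {
  type <- match.arg(type)
  tt <- delete.response(object$terms)
  if (is.null(newdata)) {
    Xn <- object$X
  } else {
    mf <- model.frame(tt, newdata, xlev = object$xlevels)
    Xn <- model.matrix(tt, mf)
    Xn <- Xn[, colnames(object$X), drop = FALSE]
    for (j in seq_len(ncol(object$X))) {
      nm <- colnames(object$X)[j]
      if (object$scale[j] != 1 || object$center[j] != 0) {
        rng <- range(object$X[, j])
        if (any(Xn[, j] < rng[1] | Xn[, j] > rng[2]))
          warning("extrapolating beyond the observed range of ", nm)
      }
    }
  }
  Xs <- sweep(sweep(Xn, 2, object$center, "-"), 2,
              ifelse(object$scale == 0, 1, object$scale), "/")
  eta <- Xs %*% t(object$draws[, colnames(object$X), drop = FALSE])
  out <- if (type == "link") eta else switch(object$family,
    gaussian = eta, bernoulli = plogis(eta), negbin = exp(eta))
  if (!summary) return(out)
  res <- t(apply(out, 1, function(v) c(median(v), hpd(v, 0.95))))
  res <- as.data.frame(res)
  names(res) <- c("median", "hpd95_lo", "hpd95_hi")
  rownames(res) <- NULL
  res
}

#' Posterior median probability with HPD interval at given covariates
#'
#' Convenience wrapper around \code{\link{predict.bglm}} for Bernoulli fits:
#' returns the posterior median response probability and its 95% HPD
#' interval at one or more covariate combinations.
#'
#' @param fit a converged Bernoulli \code{\link{bglm}} fit.
#' @param covariate_values data.frame of covariate values.
#' @return data.frame with columns median, hpd95_lo, hpd95_hi.
#' @export
predict_probability <- function(fit, covariate_values) {
  stopifnot(inherits(fit, "bglm"))
  if (fit$family != "bernoulli")
    stop("predict_probability is defined for bernoulli fits")
  if (!fit$converged)
    warning("fit is flagged unconverged; probabilities may be unreliable")
  predict(fit, newdata = covariate_values, type = "response")
}

#' @export
residuals.bglm <- function(object, ...) {
  fitted <- predict(object, type = "response")$median
  object$y - fitted
}

#' @export
simulate.bglm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$draws)
  idx <- sample.int(S, nsim, replace = nsim > S)
  eta <- .eta_draws(object, draw_idx = idx)
  aux <- .aux_draws(object)
  out <- matrix(NA_real_, length(object$y), nsim)
  for (k in seq_along(idx)) {
    s <- idx[k]
    out[, k] <- switch(object$family,
      gaussian = rnorm(length(object$y), eta[, k], aux[s]),
      bernoulli = rbinom(length(object$y), 1, plogis(eta[, k])),
      negbin = rnbinom(length(object$y), size = aux[s], mu = exp(eta[, k])))
  }
  as.data.frame(out)
}

#' @export
plot.bglm <- function(x, pars = NULL, ...) {
  pars <- pars %||% utils::head(colnames(x$draws), 4)
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  S <- nrow(x$draws) / x$settings$chains
  for (p in pars) {
    m <- matrix(x$draws[, p], ncol = x$settings$chains)
    graphics::matplot(m, type = "l", lty = 1, main = paste("trace:", p),
                      xlab = "", ylab = "")
    plot(stats::density(x$draws[, p]), main = paste("density:", p))
  }
  invisible(x)
}
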