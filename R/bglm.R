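# Bayesian GLMs (gaussian / Bernoulli / negative binomial) through JAGS.

#' MCMC settings for bglm
#'
#' Defaults follow the reporting convention used throughout the package:
#' three chains of 4000 iterations with a 200-iteration warmup and a
#' thinning rate of 5, retaining (4000 - 200) / 5 = 760 draws per chain,
#' 2280 in total.
#'
#' @param chains number of chains.
#' @param iterations total iterations per chain (warmup included).
#' @param warmup adaptation/burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param seed integer seed controlling chain RNGs.
#' @return object of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(chains = 3L, iterations = 4000L, warmup = 200L,
                          thin = 5L, seed = 1L) {
  stopifnot(warmup < iterations, chains >= 1, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed),
                 draws_per_chain = (as.integer(iterations) -
                                      as.integer(warmup)) %/% as.integer(thin)),
            class = "mcmc_settings")
}

#' Prior specification for bglm
#'
#' Weakly informative, conservative defaults: zero-centred normal priors
#' with SD 2.5 on coefficients of (internally standardized) predictors, SD 5
#' on the intercept, and half-Cauchy(0, 5) priors on the gaussian residual
#' SD and the negative-binomial dispersion.
#'
#' @param coef_sd prior SD for non-intercept coefficients.
#' @param intercept_sd prior SD for the intercept.
#' @param aux_scale half-Cauchy scale for sigma / dispersion.
#' @return object of class \code{bglm_priors}.
#' @export
bglm_priors <- function(coef_sd = 2.5, intercept_sd = 5, aux_scale = 5) {
  stopifnot(coef_sd > 0, intercept_sd > 0, aux_scale > 0)
  structure(list(coef_sd = coef_sd, intercept_sd = intercept_sd,
                 aux_scale = aux_scale), class = "bglm_priors")
}

.jags_template <- function(family, has_aux_prior) {
  likelihood <- switch(family,
    gaussian = "
  for (i in 1:N) { y[i] ~ dnorm(eta[i], tau) }
  tau <- pow(sigma, -2)
  sigma ~ dt(0, aux_prec, 1) T(0,)",
    bernoulli = "
  for (i in 1:N) { y[i] ~ dbern(p[i]); p[i] <- ilogit(eta[i]) }",
    negbin = "
  for (i in 1:N) {
    y[i] ~ dpois(lambda[i])
    lambda[i] <- mu[i] * g[i]
    g[i] ~ dgamma(r, r)
    mu[i] <- exp(eta[i])
  }
  r ~ dt(0, aux_prec, 1) T(0,)")
  paste0("model {\n",
         "  for (i in 1:N) { eta[i] <- inprod(X[i, ], beta) }\n",
         "  for (j in 1:P) { beta[j] ~ dnorm(0, beta_prec[j]) }\n",
         likelihood, "\n}\n")
}

# standardize continuous (non-dummy) design columns, leaving the intercept
.standardize_design <- function(X) {
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (colnames(X)[j] == "(Intercept)") next
    if (length(unique(v)) <= 2) next  # dummies and constants left alone
    ctr[j] <- mean(v); scl[j] <- sd(v)
    if (scl[j] == 0) scl[j] <- 1
    X[, j] <- (v - ctr[j]) / scl[j]
  }
  list(X = X, center = ctr, scale = scl)
}

#' Fit a Bayesian generalised linear model
#'
#' One fitting interface for the three model families used in the coral
#' demography analyses: gaussian (identity link) for mean colony size,
#' Bernoulli (logit link) for bleaching and partial-mortality incidence, and
#' negative binomial (log link, parameterised as a Poisson-gamma mixture)
#' for colony counts. Models are sampled with JAGS; continuous predictors
#' are standardized internally (coefficients are reported on the
#' standardized scale; \code{predict} undoes the scaling automatically).
#'
#' The returned fit carries posterior medians and 95% HPD intervals per
#' parameter, the Gelman-Rubin R-hat diagnostic, a Bayes R-squared, LOOIC
#' from truncated importance-sampling leave-one-out cross-validation, and a
#' posterior predictive check summary. Fits with any R-hat above 1.05 are
#' flagged unconverged and refused by \code{\link{compare_models}} unless
#' forced.
#'
#' @param formula model formula, e.g. \code{bleached ~ log_area * genus}.
#' @param data data.frame containing the response and predictors. Binary
#'   responses must be coded 0/1; count responses must be nonnegative
#'   integers.
#' @param family "gaussian", "bernoulli" or "negbin".
#' @param settings an \code{\link{mcmc_settings}} object.
#' @param priors a \code{\link{bglm_priors}} object.
#' @param standardize standardize continuous predictors (default TRUE).
#' @param quiet suppress JAGS progress output.
#' @return object of class \code{bglm}.
#' @examples
#' \donttest{
#' d <- data.frame(y = rbinom(200, 1, 0.3))
#' fit <- bglm(y ~ 1, d, family = "bernoulli",
#'             settings = mcmc_settings(chains = 2, iterations = 1000,
#'                                      warmup = 200))
#' coef(fit)
#' }
#' @export
bglm <- function(formula, data, family = c("gaussian", "bernoulli", "negbin"),
                 settings = mcmc_settings(), priors = bglm_priors(),
                 standardize = TRUE, quiet = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(settings, "mcmc_settings"),
            inherits(priors, "bglm_priors"))
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (family == "bernoulli" && !all(y %in% c(0, 1)))
    stop("bernoulli responses must be coded {0, 1}")
  if (family == "negbin" && (any(y < 0) || any(y != round(y))))
    stop("negbin responses must be nonnegative integers")
  std <- if (standardize) .standardize_design(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))

  P <- ncol(std$X)
  beta_sd <- ifelse(colnames(X) == "(Intercept)", priors$intercept_sd,
                    priors$coef_sd)
  jdata <- list(y = as.numeric(y), X = std$X, N = nrow(std$X), P = P,
                beta_prec = 1 / beta_sd^2)
  if (family != "bernoulli") jdata$aux_prec <- 1 / priors$aux_scale^2
  monitors <- c("beta", switch(family, gaussian = "sigma", negbin = "r",
                               bernoulli = NULL))

  inits <- lapply(seq_len(settings$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(settings$seed, k)))
  model_txt <- .jags_template(family, family != "bernoulli")
  run <- function() {
    # warmup iterations serve as the JAGS adaptation phase
    jm <- rjags::jags.model(textConnection(model_txt), data = jdata,
                            inits = inits, n.chains = settings$chains,
                            n.adapt = settings$warmup, quiet = TRUE)
    rjags::coda.samples(jm, monitors,
                        n.iter = settings$iterations - settings$warmup,
                        thin = settings$thin, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  # rename beta[j] to design column names
  draws <- do.call(rbind, lapply(samp, as.matrix))
  par_names <- colnames(draws)
  beta_idx <- grep("^beta(\\[|$)", par_names)
  if (length(beta_idx) > 1) {
    ord <- order(as.integer(sub("^beta\\[(\\d+)\\]$", "\\1",
                                par_names[beta_idx])))
    beta_idx <- beta_idx[ord]
  }
  new_names <- par_names
  new_names[beta_idx] <- colnames(X)
  colnames(draws) <- new_names
  samp_named <- coda::as.mcmc.list(lapply(samp, function(m) {
    mm <- as.matrix(m); colnames(mm) <- new_names
    coda::mcmc(mm, start = stats::start(m), thin = coda::thin(m))
  }))

  rhat <- tryCatch({
    gd <- coda::gelman.diag(samp_named, autoburnin = FALSE,
                            multivariate = FALSE)
    setNames(gd$psrf[, 1], rownames(gd$psrf))
  }, error = function(e) setNames(rep(NA_real_, length(new_names)),
                                  new_names))
  converged <- all(is.na(rhat) | rhat <= 1.05)
  if (!converged)
    warning("convergence flag: R-hat > 1.05 for ",
            paste(names(rhat)[!is.na(rhat) & rhat > 1.05], collapse = ", "))

  medians <- apply(draws, 2, median)
  hpd95 <- t(apply(draws, 2, hpd, mass = 0.95))

  fit <- structure(list(
    formula = formula, terms = attr(mf, "terms"), family = family,
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    y = as.numeric(y), X = X, X_std = std$X,
    center = std$center, scale = std$scale, standardize = standardize,
    draws = draws, samples = samp_named,
    medians = medians, hpd95 = hpd95, rhat = rhat, converged = converged,
    settings = settings, priors = priors), class = "bglm")
  fit$bayes_r2 <- .bayes_r2(fit)
  fit$loo <- .loo_tis(fit)
  fit$ppc <- .ppc_summary(fit)
  fit
}

# posterior linear predictor eta for a (standardized) design matrix,
# chunked over draws to bound memory; returns N x S matrix
.eta_draws <- function(fit, X_std = fit$X_std, draw_idx = NULL) {
  betas <- fit$draws[, colnames(fit$X), drop = FALSE]
  if (!is.null(draw_idx)) betas <- betas[draw_idx, , drop = FALSE]
  X_std %*% t(betas)
}

.aux_draws <- function(fit) {
  switch(fit$family,
         gaussian = fit$draws[, "sigma"],
         negbin = fit$draws[, "r"],
         bernoulli = NULL)
}

# Bayes R2 (Gelman et al. 2019): var(fitted) / (var(fitted) + expected
# residual variance), per posterior draw; summarised by its median.
.bayes_r2 <- function(fit) {
  S <- nrow(fit$draws)
  aux <- .aux_draws(fit)
  chunk <- 250L
  r2 <- numeric(S)
  for (s0 in seq(1L, S, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, S)
    eta <- .eta_draws(fit, draw_idx = idx)
    for (k in seq_along(idx)) {
      s <- idx[k]
      mu <- switch(fit$family, gaussian = eta[, k],
                   bernoulli = plogis(eta[, k]), negbin = exp(eta[, k]))
      var_fit <- var(mu)
      var_res <- switch(fit$family,
                        gaussian = aux[s]^2,
                        bernoulli = mean(mu * (1 - mu)),
                        negbin = mean(mu + mu^2 / aux[s]))
      r2[s] <- var_fit / (var_fit + var_res)
    }
  }
  list(draws = r2, median = median(r2), hpd95 = hpd(r2, 0.95))
}

# Truncated importance-sampling LOO (Ionides 2008 truncation at
# sqrt(S) * mean weight), computed from the pointwise log-likelihood.
.loo_tis <- function(fit) {
  S <- nrow(fit$draws)
  N <- length(fit$y)
  elpd_i <- numeric(N)
  lpd_i <- numeric(N)
  chunk_n <- max(1L, floor(2e6 / S))
  for (i0 in seq(1L, N, by = chunk_n)) {
    ii <- i0:min(i0 + chunk_n - 1L, N)
    # need loglik for these observations across all draws
    ll <- matrix(NA_real_, length(ii), S)
    draw_chunk <- 500L
    for (s0 in seq(1L, S, by = draw_chunk)) {
      sidx <- s0:min(s0 + draw_chunk - 1L, S)
      llc <- .loglik_chunk_obs(fit, ii, sidx)
      ll[, seq_along(sidx) + (s0 - 1L)] <- llc
    }
    for (k in seq_along(ii)) {
      l <- ll[k, ]
      mx <- max(l)
      lpd_i[ii[k]] <- mx + log(mean(exp(l - mx)))
      # IS weights proportional to 1 / p(y_i | theta_s)
      lw <- -l
      lw <- lw - max(lw)
      w <- exp(lw)
      w <- pmin(w, sqrt(S) * mean(w))   # truncation for stability
      w <- w / sum(w)
      elpd_i[ii[k]] <- mx + log(sum(w * exp(l - mx)))
    }
  }
  elpd <- sum(elpd_i)
  looic <- -2 * elpd
  se <- 2 * sqrt(N * var(elpd_i))
  list(elpd_loo = elpd, looic = looic, se = se,
       p_loo = sum(lpd_i) - elpd, pointwise = elpd_i)
}

# loglik for observation subset ii over draw subset sidx
.loglik_chunk_obs <- function(fit, ii, sidx) {
  eta <- fit$X_std[ii, , drop = FALSE] %*%
    t(fit$draws[sidx, colnames(fit$X), drop = FALSE])
  aux <- .aux_draws(fit)
  out <- matrix(NA_real_, length(ii), length(sidx))
  yy <- fit$y[ii]
  for (k in seq_along(sidx)) {
    s <- sidx[k]
    out[, k] <- switch(fit$family,
      gaussian = dnorm(yy, eta[, k], aux[s], log = TRUE),
      bernoulli = dbinom(yy, 1, plogis(eta[, k]), log = TRUE),
      negbin = dnbinom(yy, size = aux[s], mu = exp(eta[, k]), log = TRUE))
  }
  out
}

# posterior predictive check: replicated mean and SD vs observed
.ppc_summary <- function(fit, n_rep = 200L) {
  set.seed(derive_seed(fit$settings$seed, 999L))
  S <- nrow(fit$draws)
  idx <- unique(round(seq(1L, S, length.out = min(n_rep, S))))
  eta <- .eta_draws(fit, draw_idx = idx)
  aux <- .aux_draws(fit)
  rep_mean <- numeric(length(idx)); rep_sd <- numeric(length(idx))
  for (k in seq_along(idx)) {
    s <- idx[k]
    yrep <- switch(fit$family,
      gaussian = rnorm(length(fit$y), eta[, k], aux[s]),
      bernoulli = rbinom(length(fit$y), 1, plogis(eta[, k])),
      negbin = rnbinom(length(fit$y), size = aux[s], mu = exp(eta[, k])))
    rep_mean[k] <- mean(yrep); rep_sd[k] <- sd(yrep)
  }
  list(obs_mean = mean(fit$y), obs_sd = sd(fit$y),
       p_mean = mean(rep_mean >= mean(fit$y)),
       p_sd = mean(rep_sd >= sd(fit$y)))
}
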