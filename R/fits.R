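# JAGS model strings. Priors (configurable via prior_sd / shrinkage refits):
# beta ~ Normal(0, 10^2), NB dispersion r ~ Gamma(0.1, 0.1), beta-regression
# precision phi ~ Gamma(0.1, 0.1), sigma_b / sigma_e ~ half-Cauchy(5).
jags_model_string <- function(type, random_intercept) {
  ri_lik <- if (random_intercept) " + b[ind[i]]" else ""
  ri_block <- if (random_intercept) "
  for (j in 1:J) { b[j] ~ dnorm(0, tau_b) }
  sigma_b ~ dt(0, 0.04, 1)T(0,)
  tau_b <- pow(sigma_b, -2)" else ""
  lik <- switch(type,
    negbin = sprintf("
    y[i] ~ dnegbin(pp[i], r)
    pp[i] <- r / (r + mu[i])
    log(mu[i]) <- inprod(X[i,], beta)%s", ri_lik),
    lognormal = sprintf("
    y[i] ~ dnorm(mu[i], tau_e)
    mu[i] <- inprod(X[i,], beta)%s", ri_lik),
    beta = sprintf("
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
    logit(mu[i]) <- inprod(X[i,], beta)%s", ri_lik))
  disp <- switch(type,
    negbin = "r ~ dgamma(0.1, 0.1)",
    lognormal = "sigma_e ~ dt(0, 0.04, 1)T(0,)\n  tau_e <- pow(sigma_e, -2)",
    beta = "phi ~ dgamma(0.1, 0.1)")
  sprintf("model {
  for (i in 1:n) {%s
  }
  for (k in 1:K) { beta[k] ~ dnorm(0, prior_prec[k]) }
  %s%s
}", lik, disp, ri_block)
}

jags_monitors <- function(type, random_intercept) {
  c("beta", "deviance",
    switch(type, negbin = "r", lognormal = "sigma_e", beta = "phi"),
    if (random_intercept) c("b", "sigma_b"))
}

# run JAGS, returning combined draws, per-draw deviance, and diagnostics.
# Non-intercept covariates are centred internally to decorrelate them from
# the intercept (a pure sampling-efficiency reparameterisation); intercept
# draws are transformed back afterwards, so the reported posterior is that
# of the uncentred design.
run_jags <- function(type, d, prior_sd, mcmc, seed) {
  ri <- !is.null(d$ind)
  X_fit <- d$X
  xbar <- NULL
  if (colnames(X_fit)[1] == "(Intercept)" && ncol(X_fit) > 1) {
    xbar <- colMeans(X_fit[, -1, drop = FALSE])
    X_fit[, -1] <- sweep(X_fit[, -1, drop = FALSE], 2, xbar)
  }
  data_list <- list(y = d$y, X = X_fit, n = length(d$y), K = ncol(d$X),
                    prior_prec = 1 / prior_sd^2)
  if (ri) { data_list$ind <- d$ind; data_list$J <- d$J }
  rjags::load.module("dic", quiet = TRUE)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sub_seed(seed, ch))
  })
  jm <- rjags::jags.model(
    textConnection(jags_model_string(type, ri)), data = data_list,
    inits = inits, n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
    quiet = TRUE)
  n_burn <- ceiling(mcmc$n_iter * mcmc$burn_frac)
  if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, jags_monitors(type, ri),
                              n.iter = mcmc$n_iter - n_burn,
                              thin = mcmc$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  # coda names beta[1].. in X column order (bare "beta" when K = 1)
  bcols <- if (ncol(d$X) == 1) "beta" else
    paste0("beta[", seq_len(ncol(d$X)), "]")
  colnames(draws)[match(bcols, colnames(draws))] <- colnames(d$X)
  if (!is.null(xbar)) {   # undo the internal centring on the intercept
    draws[, "(Intercept)"] <- draws[, "(Intercept)"] -
      draws[, colnames(d$X)[-1], drop = FALSE] %*% xbar
  }
  rhat <- if (mcmc$n_chains >= 2) {
    keep <- !grepl("^(b\\[|deviance)", coda::varnames(samp))
    gd <- try(coda::gelman.diag(samp[, keep, drop = FALSE],
                                autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (inherits(gd, "try-error")) NULL else stats::setNames(
      gd$psrf[, 1], rownames(gd$psrf))
  } else NULL
  ess <- coda::effectiveSize(samp)
  fix_names <- function(v) {
    idx <- match(bcols, names(v))
    ok <- !is.na(idx)
    names(v)[idx[ok]] <- colnames(d$X)[ok]
    v
  }
  ess <- fix_names(ess)
  if (!is.null(rhat)) rhat <- fix_names(rhat)
  list(draws = draws, deviance = draws[, "deviance"],
       rhat = rhat, ess = ess)
}

post_median <- function(draws) apply(draws, 2, stats::median)

# model-specific log likelihood at given parameter values
loglik_at <- function(type, d, beta, disp, b) {
  eta <- drop(d$X %*% beta)
  if (!is.null(d$ind)) eta <- eta + b[d$ind]
  switch(type,
    negbin = sum(stats::dnbinom(d$y, size = disp, mu = exp(eta), log = TRUE)),
    lognormal = sum(stats::dnorm(d$y, eta, disp, log = TRUE)),
    beta = {
      mu <- stats::plogis(eta)
      sum(stats::dbeta(d$y, mu * disp, (1 - mu) * disp, log = TRUE))
    })
}

disp_name <- function(type) {
  switch(type, negbin = "r", lognormal = "sigma_e", beta = "phi")
}

make_posterior_fit <- function(type, design, data, d, prior_sd, mcmc, seed,
                               res) {
  draws <- res$draws
  coef_names <- colnames(d$X)
  med <- post_median(draws)
  summ <- data.frame(
    term = coef_names,
    median = unname(med[coef_names]),
    p_neg = vapply(coef_names, function(k) mean(draws[, k] < 0), 0),
    p_pos = vapply(coef_names, function(k) mean(draws[, k] > 0), 0),
    row.names = NULL)
  disp_med <- med[disp_name(type)]
  b_med <- if (!is.null(d$ind)) {
    vapply(seq_len(d$J), function(j) med[sprintf("b[%d]", j)], 0)
  } else NULL
  # fitted values and residuals at posterior medians (response model scale)
  eta <- drop(d$X %*% med[coef_names])
  if (!is.null(d$ind)) eta <- eta + b_med[d$ind]
  fitted <- switch(type, negbin = exp(eta), lognormal = eta,
                   beta = stats::plogis(eta))
  residuals <- data.frame(
    record = seq_along(d$y),
    observed = d$y, fitted = fitted, residual = d$y - fitted)
  if (!is.null(data$winter_range)) residuals$group <- data$winter_range
  if (!is.null(data$id)) residuals$id <- data$id
  # deviance summaries: pD = var(D)/2 (single-run form) and the plug-in form
  dev <- res$deviance
  mean_dev <- mean(dev)
  pd_var <- stats::var(dev) / 2
  b_mean <- if (!is.null(d$ind)) {
    vapply(seq_len(d$J), function(j) mean(draws[, sprintf("b[%d]", j)]), 0)
  } else NULL
  dev_at_mean <- -2 * loglik_at(type, d, colMeans(draws[, coef_names, drop = FALSE]),
                                mean(draws[, disp_name(type)]), b_mean)
  rhat <- res$rhat
  converged <- if (is.null(rhat)) NA else all(rhat < 1.05, na.rm = TRUE)
  structure(list(
    model = type, summary = summ, draws = draws,
    deviance = dev, dic = mean_dev + pd_var, pd = pd_var,
    dic_plugin = 2 * mean_dev - dev_at_mean,
    pd_plugin = mean_dev - dev_at_mean,
    residuals = residuals, rhat = rhat, ess = res$ess,
    converged = converged,
    design = design, data = data, d = d, prior_sd = prior_sd,
    mcmc = mcmc, seed = seed), class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit (%s): %d records, %d coefficients, DIC %.1f (pD %.1f)%s\n",
              x$model, nrow(x$residuals), nrow(x$summary), x$dic, x$pd,
              if (isFALSE(x$converged)) " [NOT CONVERGED]" else ""))
  print(within(x$summary, median <- round(median, 3)), row.names = FALSE)
  invisible(x)
}

fit_bayes <- function(type, design, data, mcmc, seed, prior_sd = NULL) {
  d <- build_design(design, data)
  K <- ncol(d$X)
  if (is.null(prior_sd)) prior_sd <- rep(10, K)
  if (length(prior_sd) == 1) prior_sd <- rep(prior_sd, K)
  res <- run_jags(type, d, prior_sd, mcmc, seed)
  make_posterior_fit(type, design, data, d, prior_sd, mcmc, seed, res)
}

#' Bayesian negative-binomial regression for migration timing
#'
#' Models earliest-corrected migration dates (counts of days since the
#' earliest migrant) as y_i ~ NegBin(mu_i, r) with log mu_i = x_i' beta.
#' Covariates follow the timing-model layout: standardized age, winter-range
#' dummies (NM reference) and mtDNA haplogroup dummies (haplogroup 1
#' reference). Priors: beta ~ Normal(0, 10^2), r ~ Gamma(0.1, 0.1).
#'
#' @param design a [design_spec()] (no random intercept; one record per
#'   animal).
#' @param data data frame with the response and covariate columns.
#' @param mcmc an [mcmc_settings()].
#' @param seed integer RNG seed (drives the JAGS chains).
#' @return object of class `posterior_fit`: coefficient summaries (median,
#'   P(coeff < 0), P(coeff > 0)), combined draws, per-draw deviance, DIC with
#'   pD = var(deviance)/2 plus the plug-in variant, residuals at posterior
#'   medians, R-hat and effective sample sizes.
#' @export
fit_negbin <- function(design, data, mcmc = mcmc_settings(), seed = 1L) {
  y <- data[[design$response]]
  if (any(is.na(y)) || any(y < 0) || any(y != round(y))) {
    stop("negative-binomial response must be non-negative integers")
  }
  fit_bayes("negbin", design, data, mcmc, seed)
}

#' Bayesian hierarchical log-normal mass model
#'
#' log(mass_ij) = x_ij' beta + b_i + eps_ij with a random intercept b_i ~
#' Normal(0, sigma_b^2) per individual (repeat captures) and eps ~ Normal(0,
#' sigma_e^2). Supports linear or quadratic standardized-age terms via the
#' design's `age_degree`. Priors: beta ~ Normal(0, 10^2), sigma_b, sigma_e ~
#' half-Cauchy(5).
#'
#' @inheritParams fit_negbin
#' @param design a [design_spec()] whose response is the (positive) mass
#'   column; the model log-transforms internally. Set `random_intercept =
#'   "id"` for repeat captures.
#' @return a `posterior_fit`; residuals and fitted values are on the log
#'   scale.
#' @export
fit_lognormal_mass <- function(design, data, mcmc = mcmc_settings(),
                               seed = 1L) {
  y <- data[[design$response]]
  if (any(is.na(y)) || any(y <= 0)) stop("mass must be positive")
  data2 <- data
  data2[[design$response]] <- log(y)
  fit_bayes("lognormal", design, data2, mcmc, seed)
}

#' Bayesian hierarchical beta regression for percent body fat
#'
#' fat_ij ~ Beta(mu_ij * phi, (1 - mu_ij) * phi) with logit mu_ij = x_ij'
#' beta + b_i. The study layout's covariates are the 17 single-locus
#' heterozygosity indicators, standardized age, a March-capture indicator
#' and winter-range dummies. Fat given in percent is divided by 100; exact
#' 0/1 values are pulled inside the open interval by the usual
#' (y*(n-1)+0.5)/n adjustment. Priors: beta ~ Normal(0, 10^2), phi ~
#' Gamma(0.1, 0.1), sigma_b ~ half-Cauchy(5).
#'
#' @inheritParams fit_negbin
#' @param design a [design_spec()]; set `random_intercept = "id"` for repeat
#'   captures.
#' @return a `posterior_fit`; fitted values are on the fat-fraction scale.
#' @export
fit_beta_fat <- function(design, data, mcmc = mcmc_settings(), seed = 1L) {
  y <- data[[design$response]]
  if (any(is.na(y))) stop("missing fat values")
  if (max(y) > 1.5) y <- y / 100   # percent scale -> fraction
  if (any(y < 0) || any(y > 1)) stop("fat values outside [0, 1]")
  if (any(y == 0 | y == 1)) {
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n
  }
  data2 <- data
  data2[[design$response]] <- y
  fit_bayes("beta", design, data2, mcmc, seed)
}

#' Deviance information criterion
#'
#' DIC = mean deviance + pD with pD = var(deviance)/2, the single-run
#' variance form; the Spiegelhalter plug-in estimate (mean deviance minus
#' deviance at posterior means) is also reported for transparency.
#'
#' @param fit a `posterior_fit`.
#' @return list with `dic`, `effective_n_params` (variance form), and the
#'   plug-in variants `dic_plugin`, `effective_n_params_plugin`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (length(fit$deviance) < 100) {
    warning("fewer than 100 retained draws; DIC is noisy")
  }
  list(dic = fit$dic, effective_n_params = fit$pd,
       dic_plugin = fit$dic_plugin,
       effective_n_params_plugin = fit$pd_plugin)
}

#' Refit with a shrinkage prior on the coefficients
#'
#' Refits the same likelihood with independent mean-0 normal priors of small
#' standard deviation on every non-intercept coefficient, shrinking
#' estimates toward 0 as a guard against false-positive single-locus
#' effects. With `prior_sd = "auto"` the prior SD is the standard deviation
#' of the original fit's non-intercept median coefficients.
#'
#' @param fit a completed `posterior_fit`.
#' @param prior_sd positive scalar, or `"auto"`.
#' @param seed RNG seed for the refit (defaults to the original seed + 1).
#' @return list with `fit` (the refitted `posterior_fit`), `prior_sd` used,
#'   and `comparison`: a table of terms flagged at >= 0.95 sign probability
#'   before and after shrinkage.
#' @export
shrinkage_refit <- function(fit, prior_sd = "auto", seed = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (identical(prior_sd, "auto")) {
    med <- fit$summary$median[fit$summary$term != "(Intercept)"]
    prior_sd <- stats::sd(med)
  }
  if (!is.numeric(prior_sd) || prior_sd <= 0) stop("prior_sd must be > 0")
  K <- nrow(fit$summary)
  sds <- rep(prior_sd, K)
  sds[fit$summary$term == "(Intercept)"] <- 10
  if (is.null(seed)) seed <- sub_seed(fit$seed, 97L)
  refit <- fit_bayes(fit$model, fit$design, fit$data, fit$mcmc, seed,
                     prior_sd = sds)
  flag <- function(s) pmax(s$p_neg, s$p_pos) >= 0.95 &
    s$term != "(Intercept)"
  comparison <- data.frame(term = fit$summary$term,
                           flagged = flag(fit$summary),
                           flagged_shrunk = flag(refit$summary))
  list(fit = refit, prior_sd = prior_sd, comparison = comparison)
}

#' Residual diagnostics table
#'
#' Observed minus posterior-median prediction against fitted values, with
#' group labels retained so group-wise residual patterns (e.g. one winter
#' range supplying the largest negative residuals) can be inspected.
#'
#' @param fit a `posterior_fit`.
#' @return data frame with columns `record`, `observed`, `fitted`,
#'   `residual`, plus `group`/`id` where available.
#' @export
residual_plot_data <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  fit$residuals
}

#' Predicted between-level difference in migration days
#'
#' For a negative-binomial timing fit, the model-predicted difference in
#' days between the reference level and another level of a dummy covariate,
#' holding all other covariates at reference values: exp(median intercept) -
#' exp(median intercept + median coefficient).
#'
#' @param fit a negative-binomial `posterior_fit`, or a named numeric vector
#'   of median coefficients containing `(Intercept)`.
#' @param level coefficient name of the non-reference level (e.g.
#'   `"haplogroup2"`).
#' @return list with `days` (rounded to the nearest whole day), `days_raw`,
#'   and `days_posterior` (posterior draws of the difference, when draws are
#'   available).
#' @export
predicted_day_difference <- function(fit, level) {
  if (inherits(fit, "posterior_fit")) {
    med <- stats::setNames(fit$summary$median, fit$summary$term)
    if (!level %in% names(med)) stop("unknown level: ", level)
    post <- exp(fit$draws[, "(Intercept)"]) -
      exp(fit$draws[, "(Intercept)"] + fit$draws[, level])
  } else {
    med <- fit
    if (!level %in% names(med)) stop("unknown level: ", level)
    post <- NULL
  }
  raw <- exp(med[["(Intercept)"]]) - exp(med[["(Intercept)"]] + med[[level]])
  list(days = round(raw), days_raw = raw, days_posterior = post)
}

#' Export a coefficient summary table
#'
#' @param fit a `posterior_fit`.
#' @param path optional CSV path; when given, the table is written there.
#' @return data frame with columns `covariate`, `median`, `p_negative`,
#'   `p_positive` (the standard coefficient-table layout).
#' @export
coef_table <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  out <- data.frame(covariate = fit$summary$term,
                    median = fit$summary$median,
                    p_negative = fit$summary$p_neg,
                    p_positive = fit$summary$p_pos)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
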