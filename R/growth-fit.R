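#' Assemble growth-model input from back-calculated pairs
#'
#' Turns a table of back-calculated (age, size) pairs into the longitudinal
#' observation set used for growth fitting: one observation per band reading,
#' optionally restricted to one sex. Residuals are modelled downstream as
#' i.i.d. Normal across observations; the pseudo-replication implied by
#' multiple bands per fish is deliberate (it mirrors standard practice for
#' back-calculated elasmobranch data) and is documented, not corrected.
#'
#' @param pairs data frame with columns `fish_id`, `sex`, `age`, `dw_back`
#'   (as produced by [back_calculate()]).
#' @param sex optional `"M"` or `"F"` to subset; `NULL` keeps all rows.
#' @return data frame with columns `fish_id`, `sex`, `age`, `dw`.
#' @export
build_growth_input <- function(pairs, sex = NULL) {
  stopifnot(all(c("fish_id", "sex", "age", "dw_back") %in% names(pairs)))
  out <- pairs
  if (!is.null(sex)) out <- out[out$sex == sex, , drop = FALSE]
  if (nrow(out) == 0) stop("no observations for requested sex")
  data.frame(fish_id = out$fish_id, sex = out$sex,
             age = out$age, dw = out$dw_back)
}

free_params <- function(family) {
  if (family == "vbgm2") c("linf", "k", "sigma") else c("linf", "k", "t0", "sigma")
}

jags_model_string <- function(family, priors, prior_only = FALSE) {
  mu <- switch(family,
    vbgm3    = "linf * (1 - exp(-k * (t[i] - t0)))",
    vbgm2    = "linf - (linf - dw0) * exp(-k * t[i])",
    gompertz = "linf * exp(-exp(-k * (t[i] - t0)))",
    logistic = "linf / (1 + exp(-k * (t[i] - t0)))")
  lik <- if (prior_only) "" else paste0(
    "  for (i in 1:n) {\n",
    "    mu[i] <- ", mu, "\n",
    "    y[i] ~ dnorm(mu[i], prec)\n",
    "  }\n")
  t0_line <- if (family == "vbgm2") "" else
    sprintf("  t0 ~ dnorm(0, %.10g)\n", 1 / priors$t0_sd^2)
  paste0(
    "model {\n", lik,
    sprintf("  linf ~ dnorm(0, %.10g) T(0,)\n", 1 / priors$linf_sd^2),
    sprintf("  k ~ dnorm(0, %.10g) T(0,)\n", 1 / priors$k_sd^2),
    t0_line,
    sprintf("  sigma ~ dt(0, %.10g, %g) T(0,)\n",
            1 / priors$sigma_scale^2, priors$sigma_df),
    "  prec <- 1 / (sigma * sigma)\n}\n")
}

#' Fit a growth model in a Bayesian framework
#'
#' Fits one of the four growth families to (age, size) observations by MCMC
#' (JAGS), with zero-truncated priors on the asymptotic size, growth
#' coefficient and residual SD (see [growth_priors()]). The default run uses
#' 4 chains with 1000 warm-up iterations discarded and 3000 retained each
#' (12,000 retained draws). Convergence is assessed by the potential scale
#' reduction factor (R-hat < 1.10 for every parameter) and effective sample
#' size (> 400 per parameter); failures are attached to the result and
#' raised as warnings, never silently passed.
#'
#' @param formula model formula `size ~ age`, e.g. `dw ~ age`.
#' @param data data frame holding the formula variables.
#' @param family one of [growth_families].
#' @param priors a [growth_priors()] object.
#' @param dw0 observed size-at-birth constant (mm), required for
#'   `family = "vbgm2"`. Defaults to the mean observed size at age 0 in
#'   `data` when available.
#' @param chains,warmup,iter,adapt MCMC run settings: number of chains,
#'   warm-up iterations discarded per chain, retained iterations per chain,
#'   and JAGS adaptation steps.
#' @param seed integer seed controlling all chain RNGs.
#' @param prior_only if `TRUE`, sample from the prior (no likelihood); used
#'   for prior predictive checks.
#' @param sex optional label ("M"/"F"/"pooled") carried into summaries.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `growth_fit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `residuals` and `logLik` methods.
#'   Components include the pooled posterior `draws` matrix, the per-chain
#'   `samples` (`coda::mcmc.list`), a `summary` table with posterior means,
#'   SDs, quantiles, R-hat and effective sample sizes, the point information
#'   criterion `aic` (computed at posterior means), `waic`, and `dw0_pred`,
#'   the predicted size-at-birth at posterior means.
#' @examples
#' \donttest{
#' obs <- sim_growth_obs(60, "logistic",
#'                       params = list(linf = 400, k = 0.45, t0 = -0.36),
#'                       sigma = 20, seed = 1)
#' fit <- growth_fit(dw ~ age, obs, family = "logistic",
#'                   chains = 2, warmup = 300, iter = 500, seed = 1)
#' coef(fit)
#' }
#' @export
growth_fit <- function(formula, data, family = growth_families,
                       priors = growth_priors(), dw0 = NULL,
                       chains = 4, warmup = 1000, iter = 3000, adapt = 1000,
                       seed = 1, prior_only = FALSE, sex = NULL,
                       quiet = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(priors, "growth_priors"), chains >= 1, iter >= 1)
  pars <- free_params(family)

  if (!prior_only) {
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    t <- mf[[2L]]
    if (length(y) < length(pars) + 1)
      stop("need at least ", length(pars) + 1, " observations")
    if (all(y <= 0))
      stop("all sizes are non-positive; incompatible with zero-truncated priors")
  } else {
    y <- numeric(0); t <- numeric(0)
  }

  if (family == "vbgm2" && is.null(dw0)) {
    if (prior_only) stop("'dw0' required for prior-only vbgm2 runs")
    age0 <- y[t < 1]
    if (length(age0) == 0)
      stop("no age-0 observations to set 'dw0'; supply it explicitly")
    dw0 <- mean(age0)
  }

  jdata <- if (prior_only) list() else list(n = length(y), t = t, y = y)
  if (family == "vbgm2") jdata$dw0 <- dw0

  init_one <- function(i) {
    ini <- list(
      linf  = if (prior_only) 350 * (0.8 + 0.1 * i) else
        max(y) * (0.95 + 0.05 * (i %% 3)),
      k     = 0.15 + 0.1 * (i %% 4),
      sigma = if (prior_only) 20 + 5 * i else max(stats::sd(y) / 2, 1),
      .RNG.name = "base::Wichmann-Hill",
      .RNG.seed = (abs(as.numeric(seed)) %% 2146483) * 1000 + i)
    if (family != "vbgm2") ini$t0 <- -0.5 + 0.25 * (i %% 3)
    ini
  }

  model <- jags_model_string(family, priors, prior_only)
  jm <- rjags::jags.model(textConnection(model), data = jdata,
                          inits = lapply(seq_len(chains), init_one),
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, pars, n.iter = iter,
                                 progress.bar = "none")

  draws <- as.matrix(samples)[, pars, drop = FALSE]
  rhat <- if (chains >= 2) {
    psrf <- coda::gelman.diag(samples, autoburnin = FALSE,
                              multivariate = FALSE)$psrf
    stats::setNames(psrf[pars, 1], pars)
  } else stats::setNames(rep(NA_real_, length(pars)), pars)
  ess <- coda::effectiveSize(samples)[pars]

  qs <- t(apply(draws, 2, stats::quantile,
                probs = c(0.025, 0.05, 0.5, 0.95, 0.975)))
  summ <- data.frame(mean = colMeans(draws),
                     sd = apply(draws, 2, stats::sd),
                     qs, rhat = rhat, ess = ess, check.names = FALSE)
  colnames(summ)[3:7] <- c("q2.5", "q5", "q50", "q95", "q97.5")

  est <- stats::setNames(summ$mean, pars)
  converged <- !prior_only && chains >= 2 && all(rhat < 1.10, na.rm = FALSE)
  ess_ok <- all(ess > 400)
  if (!prior_only && chains >= 2 && !converged)
    warning(sprintf("growth_fit (%s): R-hat >= 1.10 for: %s", family,
                    paste(pars[rhat >= 1.10], collapse = ", ")))

  pl <- c(as.list(est[setdiff(pars, "sigma")]),
          if (family == "vbgm2") list(dw0 = dw0))
  dw0_pred <- if (prior_only) NA_real_ else
    growth_curve_params(0, family, pl)
  loglik <- if (prior_only) NA_real_ else
    sum(stats::dnorm(y, growth_curve_params(t, family, pl), est["sigma"],
                     log = TRUE))
  p <- length(pars)
  aic <- 2 * p - 2 * loglik
  waic <- if (prior_only) NA_real_ else
    waic_from_draws(draws, family, t, y, dw0)

  structure(list(
    family = family, sex = sex, formula = formula,
    data = if (prior_only) NULL else data.frame(age = t, dw = y),
    priors = priors, dw0 = if (family == "vbgm2") dw0 else NULL,
    draws = draws, samples = samples, summary = summ,
    rhat = rhat, ess = ess, converged = converged, ess_ok = ess_ok,
    n_params = p, loglik = loglik, aic = aic, waic = waic,
    dw0_pred = dw0_pred, prior_only = prior_only,
    mcmc = list(chains = chains, warmup = warmup, iter = iter,
                adapt = adapt, seed = seed)),
    class = "growth_fit")
}

# WAIC from pointwise log-likelihoods; draws thinned to cap cost.
waic_from_draws <- function(draws, family, t, y, dw0, max_draws = 2000) {
  idx <- if (nrow(draws) > max_draws)
    round(seq(1, nrow(draws), length.out = max_draws)) else seq_len(nrow(draws))
  ll <- vapply(idx, function(s) {
    pl <- as.list(draws[s, ])
    if (family == "vbgm2") pl$dw0 <- dw0
    stats::dnorm(y, growth_curve_params(t, family, pl), draws[s, "sigma"],
                 log = TRUE)
  }, numeric(length(y)))           # n_obs x n_draws
  ll <- matrix(ll, nrow = length(y))
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, stats::var))
  -2 * (lppd - p_waic)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Bayesian growth fit: %s%s%s\n", x$family,
              if (!is.null(x$sex)) paste0(" (", x$sex, ")") else "",
              if (x$prior_only) " [prior only]" else ""))
  if (!x$prior_only)
    cat(sprintf("  n = %d observations; %d chains x %d retained draws\n",
                nrow(x$data), x$mcmc$chains, x$mcmc$iter))
  print(round(x$summary, 3))
  if (!x$prior_only) {
    cat(sprintf("  AIC (at posterior means) = %.2f; WAIC = %.2f\n",
                x$aic, x$waic))
    cat(sprintf("  predicted size-at-birth = %.1f mm; converged: %s\n",
                x$dw0_pred, x$converged))
  }
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- object$summary
  attr(out, "family") <- object$family
  attr(out, "converged") <- object$converged
  out
}

#' @export
coef.growth_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, rownames(object$summary))
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = nrow(object$data), class = "logLik")
}

#' @export
residuals.growth_fit <- function(object, ...) {
  if (object$prior_only) stop("no data in a prior-only fit")
  object$data$dw - fitted(object)
}

#' @export
fitted.growth_fit <- function(object, ...) {
  est <- coef(object)
  pl <- c(as.list(est[setdiff(names(est), "sigma")]),
          if (object$family == "vbgm2") list(dw0 = object$dw0))
  growth_curve_params(object$data$age, object$family, pl)
}

#' Predict size-at-age from a fitted growth model
#'
#' @param object a `growth_fit`.
#' @param newdata data frame with an `age` column (or a numeric age vector);
#'   defaults to the observed ages.
#' @param interval `"none"` for the posterior-mean curve only, `"credible"`
#'   for equal-tailed credible bands of the mean curve, `"prediction"` for
#'   posterior-predictive bands including residual noise.
#' @param level credible level for the bands.
#' @param max_draws cap on posterior draws used for bands.
#' @param ... unused.
#' @return numeric vector (`interval = "none"`) or data frame with columns
#'   `age`, `fit`, `lwr`, `upr`.
#' @export
predict.growth_fit <- function(object, newdata = NULL,
                               interval = c("none", "credible", "prediction"),
                               level = 0.95, max_draws = 4000, ...) {
  interval <- match.arg(interval)
  ages <- if (is.null(newdata)) object$data$age
          else if (is.numeric(newdata)) newdata else newdata$age
  est <- coef(object)
  pl <- c(as.list(est[setdiff(names(est), "sigma")]),
          if (object$family == "vbgm2") list(dw0 = object$dw0))
  fit <- growth_curve_params(ages, object$family, pl)
  if (interval == "none") return(fit)
  dr <- object$draws
  if (nrow(dr) > max_draws)
    dr <- dr[round(seq(1, nrow(dr), length.out = max_draws)), , drop = FALSE]
  curves <- apply(dr, 1, function(th) {
    th <- as.list(th)
    if (object$family == "vbgm2") th$dw0 <- object$dw0
    growth_curve_params(ages, object$family, th)
  })
  curves <- matrix(curves, nrow = length(ages))
  if (interval == "prediction") {
    set.seed(object$mcmc$seed + 7L)
    curves <- curves + matrix(stats::rnorm(length(curves), 0,
                                           rep(dr[, "sigma"],
                                               each = length(ages))),
                              nrow = length(ages))
  }
  a <- (1 - level) / 2
  data.frame(age = ages, fit = fit,
             lwr = apply(curves, 1, stats::quantile, a),
             upr = apply(curves, 1, stats::quantile, 1 - a))
}

#' Simulate from the posterior predictive of a growth fit
#'
#' Draws `nsim` replicate datasets at the observed ages, each using one
#' posterior draw of the parameters plus Normal residual noise.
#'
#' @param object a `growth_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated size vector each.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$prior_only) stop("no data in a prior-only fit")
  if (!is.null(seed)) set.seed(seed)
  ages <- object$data$age
  idx <- sample.int(nrow(object$draws), nsim, replace = nsim > nrow(object$draws))
  out <- vapply(idx, function(s) {
    th <- as.list(object$draws[s, ])
    if (object$family == "vbgm2") th$dw0 <- object$dw0
    mu <- growth_curve_params(ages, object$family, th)
    stats::rnorm(length(ages), mu, object$draws[s, "sigma"])
  }, numeric(length(ages)))
  out <- as.data.frame(matrix(out, nrow = length(ages)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted growth curve over the data
#'
#' Base-graphics plot of the observations with the posterior-mean curve and
#' an equal-tailed credible band.
#'
#' @param x a `growth_fit`.
#' @param level credible level for the band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.growth_fit <- function(x, level = 0.95, ...) {
  if (x$prior_only) stop("no data in a prior-only fit")
  ages <- seq(0, max(x$data$age) + 0.5, length.out = 100)
  pr <- predict(x, ages, interval = "credible", level = level)
  graphics::plot(x$data$age, x$data$dw, xlab = "Age (years)",
                 ylab = "Disc width (mm)",
                 main = sprintf("%s growth fit%s", x$family,
                                if (!is.null(x$sex)) paste0(" (", x$sex, ")")
                                else ""), ...)
  graphics::polygon(c(pr$age, rev(pr$age)), c(pr$lwr, rev(pr$upr)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pr$age, pr$fit, col = "steelblue", lwd = 2)
  invisible(x)
}
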