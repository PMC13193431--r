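#' Compare growth-model fits by information criterion
#'
#' Ranks a set of [growth_fit()] objects fitted to the same observations.
#' The primary criterion is a point AIC, `2p - 2*loglik` evaluated at the
#' posterior means (p = free parameter count including sigma); WAIC is
#' reported alongside as a fully Bayesian diagnostic. Akaike differences and
#' weights are computed on the primary criterion.
#'
#' @param ... `growth_fit` objects, or a single list of them.
#' @param check_data verify all fits share identical observations (criteria
#'   are only comparable on shared data).
#' @return a `growth_model_comparison` data frame ranked by ascending AIC,
#'   with columns `family`, `sex`, `n_params`, `loglik`, `aic`, `delta`,
#'   `weight`, `waic`, `converged`.
#' @seealso [akaike_weights()]
#' @export
compare_growth <- function(..., check_data = TRUE) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "growth_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "growth_fit")))
  if (any(vapply(fits, function(f) f$prior_only, TRUE)))
    stop("prior-only fits cannot be compared")
  if (check_data) {
    ref <- fits[[1]]$data
    same <- vapply(fits, function(f) {
      nrow(f$data) == nrow(ref) && isTRUE(all.equal(f$data, ref))
    }, TRUE)
    if (!all(same))
      stop("fits were made on different datasets; criteria not comparable")
  }
  aic <- vapply(fits, function(f) f$aic, 0)
  aw <- akaike_weights(aic)
  out <- data.frame(
    family = vapply(fits, function(f) f$family, ""),
    sex = vapply(fits, function(f) if (is.null(f$sex)) NA_character_
                 else f$sex, ""),
    n_params = vapply(fits, function(f) f$n_params, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = aic, delta = aw$delta, weight = aw$weight,
    waic = vapply(fits, function(f) f$waic, 0),
    converged = vapply(fits, function(f) isTRUE(f$converged), TRUE))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("growth_model_comparison", "data.frame")
  out
}

#' Akaike differences and weights
#'
#' @param aic numeric vector of AIC values.
#' @return data frame with `delta` (AIC - min AIC) and `weight`
#'   (`exp(-delta/2)` normalised to sum to 1).
#' @examples
#' akaike_weights(c(299.63, 353.16, 363.59))
#' @export
akaike_weights <- function(aic) {
  stopifnot(is.numeric(aic), all(is.finite(aic)))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  data.frame(delta = delta, weight = w / sum(w))
}

#' @export
print.growth_model_comparison <- function(x, ...) {
  cat("Growth model comparison (ranked by AIC at posterior means):\n")
  y <- as.data.frame(x)
  y$loglik <- round(y$loglik, 2); y$aic <- round(y$aic, 2)
  y$delta <- round(y$delta, 2); y$weight <- round(y$weight, 3)
  y$waic <- round(y$waic, 2)
  print(y)
  invisible(x)
}

#' Posterior sex contrast for growth parameters
#'
#' For each parameter shared by two fits of the same family, forms the
#' paired posterior difference (females minus males by convention), its
#' equal-tailed credible interval, and flags the parameter as significantly
#' different when the interval excludes zero. Draws are pooled across chains
#' and paired after an independent seeded shuffle of each posterior (the two
#' fits are independent, so pairing order only affects reproducibility).
#'
#' @param fit_f,fit_m `growth_fit` objects for the two groups (conventionally
#'   females and males); must share the model family.
#' @param level credible level (default 0.90).
#' @param seed integer seed for the pairing shuffle.
#' @return data frame with one row per shared parameter: posterior `mean`,
#'   `sd`, interval bounds `lwr`/`upr`, and `significant`.
#' @export
sex_difference <- function(fit_f, fit_m, level = 0.90, seed = 1) {
  stopifnot(inherits(fit_f, "growth_fit"), inherits(fit_m, "growth_fit"))
  if (fit_f$family != fit_m$family)
    stop("fits are from different families: ", fit_f$family, " vs ",
         fit_m$family)
  pars <- intersect(colnames(fit_f$draws), colnames(fit_m$draws))
  n <- min(nrow(fit_f$draws), nrow(fit_m$draws))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  i_f <- sample.int(nrow(fit_f$draws), n)
  i_m <- sample.int(nrow(fit_m$draws), n)
  a <- (1 - level) / 2
  rows <- lapply(pars, function(p) {
    d <- fit_f$draws[i_f, p] - fit_m$draws[i_m, p]
    ci <- stats::quantile(d, c(a, 1 - a))
    data.frame(param = p, mean = mean(d), sd = stats::sd(d),
               lwr = ci[[1]], upr = ci[[2]],
               significant = ci[[1]] > 0 || ci[[2]] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}
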