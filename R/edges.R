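#' Monthly opaque-edge frequency table
#'
#' Tallies readable vertebral edges by calendar month (pooling years):
#' trials `n` (opaque + translucent edges) and successes `k` (opaque).
#' Unreadable edges and birthmark-only fish are excluded, the latter because
#' the birthmark differs from regular growth band-pairs.
#'
#' @param x a `synthetic_dataset`, or a data frame with an `edge_type`
#'   column (`"opaque"`, `"translucent"`, `"unreadable"`,
#'   `"birthmark_only"`) and either a `capture_month` or ISO `capture_date`
#'   column.
#' @return data frame with columns `month` (1-12), `n`, `k`.
#' @export
aggregate_edges <- function(x) {
  if (inherits(x, "synthetic_dataset")) x <- x$fish
  stopifnot("edge_type" %in% names(x))
  month <- if ("capture_month" %in% names(x)) x$capture_month
           else as.integer(substr(x$capture_date, 6, 7))
  keep <- x$edge_type %in% c("opaque", "translucent")
  if (!any(keep)) stop("no readable edges after filtering")
  month <- month[keep]
  opaque <- x$edge_type[keep] == "opaque"
  data.frame(month = 1:12,
             n = as.integer(tabulate(month, 12)),
             k = as.integer(tabulate(month[opaque], 12)))
}

#' Opaque-edge probability under a periodicity hypothesis
#'
#' Link functions for the three band-deposition hypotheses, evaluated at
#' month midpoints (angle `2*pi*(m - 0.5)/12`):
#' \describe{
#'   \item{zero_peak}{constant probability `p` (no seasonal cycle).}
#'   \item{one_peak}{a peak-normalised von Mises bump,
#'     `A * exp(kappa * (cos(theta - mu) - 1))`: probability `A` at the peak
#'     month, decaying with the seasonal concentration `kappa` (annual
#'     cycle).}
#'   \item{two_peak}{two band-pairs per year: an equal-weight mixture of two
#'     von Mises components exactly half a year apart with shared `kappa`,
#'     peak-normalised and scaled by `A`. In closed form
#'     `A * cosh(kappa * cos(theta - mu1)) / cosh(kappa)` (biennial cycle).}
#' }
#' All links keep the probability in `[0, A]`, with `A` in (0, 1]. The
#' no-cycle model is nested in both peaked models via `kappa -> 0` with
#' `A = p`; the peaked models do not nest each other.
#'
#' @param month calendar month(s) 1-12 (fractional months allowed).
#' @param fit an `edge_model_fit` (from [fit_edge_model()]) or a list with
#'   elements `hypothesis` and `params`.
#' @return vector of opaque-edge probabilities.
#' @export
edge_probability <- function(month, fit) {
  hyp <- fit$hypothesis; p <- as.list(fit$params)
  th <- month_angle(month)
  switch(hyp,
    zero_peak = rep(p$p, length(month)),
    one_peak = {
      if (p$kappa < 0) stop("kappa must be non-negative")
      p$A * exp(p$kappa * (cos(th - p$mu) - 1))
    },
    two_peak = {
      if (p$kappa < 0) stop("kappa must be non-negative")
      p$A * cosh(p$kappa * cos(th - p$mu1)) / cosh(p$kappa)
    },
    stop("unknown hypothesis: ", hyp))
}

edge_loglik <- function(table, pi_m, eps = 1e-9) {
  pi_m <- pmin(pmax(pi_m, eps), 1 - eps)
  sum(table$k * log(pi_m) + (table$n - table$k) * log(1 - pi_m))
}

wrap_angle <- function(x) x %% (2 * pi)

#' Fit one band-periodicity hypothesis by maximum likelihood
#'
#' Maximises the binomial log-likelihood of the monthly opaque-edge counts
#' under the chosen link (see [edge_probability()]). The no-cycle model has
#' a closed-form MLE; the peaked models use derivative-free multi-start
#' local optimisation with peak-location starts at every month, plus a
#' start at the nested simpler model's solution so the fitted log-likelihood
#' can never fall below it.
#'
#' @param table an [aggregate_edges()] table.
#' @param hypothesis `"zero_peak"`, `"one_peak"` or `"two_peak"`.
#' @return list of class `edge_model_fit`: `hypothesis`, named `params`
#'   (angles wrapped to `[0, 2*pi)`; for `two_peak`, `mu1` in `[0, pi)` with
#'   `mu2 = mu1 + pi` reported alongside), `loglik`, `n_params` (1 or 3),
#'   `aic`, and `peak_month` (fitted peak timing in months, where
#'   applicable).
#' @export
fit_edge_model <- function(table,
                           hypothesis = c("zero_peak", "one_peak",
                                          "two_peak")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(all(c("month", "n", "k") %in% names(table)),
            sum(table$n) >= 1, all(table$k <= table$n), all(table$k >= 0))
  tab <- table[table$n > 0, , drop = FALSE]
  phat <- sum(tab$k) / sum(tab$n)

  done <- function(params, loglik, n_params, peak_month = NA_real_) {
    structure(list(hypothesis = hypothesis, params = params,
                   loglik = loglik, n_params = n_params,
                   aic = 2 * n_params - 2 * loglik,
                   peak_month = peak_month),
              class = "edge_model_fit")
  }

  if (hypothesis == "zero_peak") {
    return(done(c(p = phat), edge_loglik(tab, rep(phat, nrow(tab))), 1L))
  }

  A0 <- min(max(max(tab$k / tab$n), 0.05), 0.95)
  p0 <- min(max(phat, 1e-3), 1 - 1e-3)

  if (hypothesis == "one_peak") {
    # theta = (mu, log kappa, logit A)
    nll <- function(th) {
      f <- list(hypothesis = "one_peak",
                params = c(mu = th[1], kappa = exp(th[2]),
                           A = stats::plogis(th[3])))
      -edge_loglik(tab, edge_probability(tab$month, f))
    }
    starts <- c(lapply(1:12, function(m)
      c(month_angle(m), log(2), stats::qlogis(A0))),
      list(c(pi, log(1e-6), stats::qlogis(p0))))  # nested no-cycle start
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, nll, method = "Nelder-Mead",
                        control = list(maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    th <- best$par
    params <- c(mu = wrap_angle(th[1]), kappa = exp(th[2]),
                A = stats::plogis(th[3]))
    return(done(params, -best$value, 3L,
                peak_month = wrap_angle(th[1]) * 12 / (2 * pi) + 0.5))
  }

  # two_peak: theta = (mu1, log kappa, logit A); mu2 = mu1 + pi implied
  nll2 <- function(th) {
    f <- list(hypothesis = "two_peak",
              params = c(mu1 = th[1], kappa = exp(th[2]),
                         A = stats::plogis(th[3])))
    -edge_loglik(tab, edge_probability(tab$month, f))
  }
  starts <- c(lapply(1:6, function(m)
    c(month_angle(m), log(2), stats::qlogis(A0))),
    list(c(pi / 2, log(1e-6), stats::qlogis(p0))))  # nested no-cycle start
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll2, method = "Nelder-Mead",
                      control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- best$par
  mu1 <- wrap_angle(th[1]) %% pi  # half-year-apart peaks are exchangeable
  params <- c(mu1 = mu1, mu2 = mu1 + pi, kappa = exp(th[2]),
              A = stats::plogis(th[3]))
  done(params, -best$value, 3L, peak_month = mu1 * 12 / (2 * pi) + 0.5)
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat(sprintf("Edge periodicity fit: %s  (loglik %.2f, AIC %.2f)\n",
              x$hypothesis, x$loglik, x$aic))
  print(round(x$params, 4))
  invisible(x)
}

#' Select the band-periodicity hypothesis by AIC
#'
#' Fits the no-cycle, annual and biennial deposition models to a monthly
#' opaque-edge table and compares them by AIC differences and Akaike
#' weights.
#'
#' @param table an [aggregate_edges()] table.
#' @return a data frame of class `edge_model_comparison` with one row per
#'   hypothesis (`aic`, `delta`, `weight`, ranked by AIC) and the three
#'   fits in attribute `"fits"`.
#' @export
select_edge_model <- function(table) {
  hyps <- c("zero_peak", "one_peak", "two_peak")
  fits <- lapply(hyps, function(h) fit_edge_model(table, h))
  names(fits) <- hyps
  aic <- vapply(fits, function(f) f$aic, 0)
  aw <- akaike_weights(aic)
  out <- data.frame(hypothesis = hyps, n_params = vapply(fits, function(f)
    f$n_params, 0L), loglik = vapply(fits, function(f) f$loglik, 0),
    aic = aic, delta = aw$delta, weight = aw$weight)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "best") <- out$hypothesis[1]
  class(out) <- c("edge_model_comparison", "data.frame")
  out
}

#' @export
print.edge_model_comparison <- function(x, ...) {
  cat("Band-pair deposition periodicity (AIC model comparison):\n")
  y <- as.data.frame(x)
  y$loglik <- round(y$loglik, 2); y$aic <- round(y$aic, 2)
  y$delta <- round(y$delta, 2); y$weight <- round(y$weight, 3)
  print(y)
  cat("Best:", attr(x, "best"), "\n")
  invisible(x)
}
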