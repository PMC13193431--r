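#' Growth-curve families
#'
#' The four size-at-age functions commonly fitted to elasmobranch
#' back-calculated or observed size-at-age data. `"vbgm3"` is the classic
#' three-parameter von Bertalanffy model, `"vbgm2"` the two-parameter variant
#' anchored at an observed size-at-birth, and `"gompertz"` and `"logistic"`
#' the two sigmoid alternatives whose `t0` is the inflection age.
#'
#' @format Character vector of the four family names.
#' @export
growth_families <- c("vbgm2", "vbgm3", "gompertz", "logistic")

#' Evaluate a growth curve
#'
#' Predicted size (disc width, mm) at age `t` for one of the four growth
#' families:
#' \describe{
#'   \item{vbgm3}{\eqn{DW_t = DW_\infty (1 - e^{-k (t - t_0)})}}
#'   \item{vbgm2}{\eqn{DW_t = DW_\infty - (DW_\infty - DW_0) e^{-k t}};
#'     `dw0` is the observed size-at-birth and the curve passes through it
#'     exactly at `t = 0`.}
#'   \item{gompertz}{\eqn{DW_t = DW_\infty e^{-e^{-k (t - t_0)}}}}
#'   \item{logistic}{\eqn{DW_t = DW_\infty / (1 + e^{-k (t - t_0)})}}
#' }
#'
#' @param t numeric vector of ages (years; may be fractional).
#' @param family one of [growth_families].
#' @param linf asymptotic size \eqn{DW_\infty} (mm), must be positive.
#' @param k growth coefficient (per year), must be positive.
#' @param t0 age at size zero (vbgm3) or inflection age (gompertz, logistic);
#'   ignored by vbgm2.
#' @param dw0 size-at-birth (mm), required by vbgm2 only.
#' @return numeric vector of predicted sizes, same length as `t`.
#' @examples
#' growth_curve(0:10, "logistic", linf = 401.7, k = 0.45, t0 = -0.36)
#' @export
growth_curve <- function(t, family = growth_families, linf, k, t0 = NULL,
                         dw0 = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(t), linf > 0, k > 0)
  if (family == "vbgm2") {
    if (is.null(dw0)) stop("family 'vbgm2' requires 'dw0' (size-at-birth)")
    return(linf - (linf - dw0) * exp(-k * t))
  }
  if (is.null(t0)) stop(sprintf("family '%s' requires 't0'", family))
  switch(family,
    vbgm3    = linf * (1 - exp(-k * (t - t0))),
    gompertz = linf * exp(-exp(-k * (t - t0))),
    logistic = linf / (1 + exp(-k * (t - t0)))
  )
}

#' Evaluate a growth curve from a named parameter vector
#'
#' Convenience wrapper around [growth_curve()] taking parameters as a named
#' vector or list with elements `linf`, `k` and, as required by the family,
#' `t0` or `dw0`.
#'
#' @inheritParams growth_curve
#' @param params named numeric vector or list of parameters.
#' @return numeric vector of predicted sizes.
#' @export
growth_curve_params <- function(t, family, params) {
  params <- as.list(params)
  growth_curve(t, family,
               linf = params$linf, k = params$k,
               t0 = if (!is.null(params$t0)) params$t0,
               dw0 = if (!is.null(params$dw0)) params$dw0)
}

#' Theoretical longevity from the growth coefficient
#'
#' Ricker's theoretical longevity: the age at which a growth curve reaches
#' 95% of its asymptotic size, approximated as \eqn{5 \ln(2) / k}. Commonly
#' compared against the maximum observed age as a plausibility check on both
#' the ageing and the fitted growth coefficient.
#'
#' @param k growth coefficient (per year); must be positive.
#' @return longevity in years.
#' @examples
#' ricker_longevity(0.45) # ~7.7 years
#' @export
ricker_longevity <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("'k' must be positive")
  5 * log(2) / k
}
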