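#' Prior set for Bayesian growth fitting
#'
#' Weakly informative priors on the millimetre scale of medium-sized batoids:
#' half-Normal(0, 700) on the asymptotic size, half-Normal(0, 1) on the
#' growth coefficient, Normal(0, 8) on `t0` (untruncated: inflection and
#' zero-size ages are routinely negative), and a half-Student-t(3, 0, 40) on
#' the residual SD. `linf`, `k` and `sigma` are truncated at zero.
#'
#' @param linf_sd,k_sd,t0_sd standard deviations of the zero-mean Normal
#'   priors on \eqn{DW_\infty} (mm), `k` (per year) and `t0` (years).
#' @param sigma_df,sigma_scale degrees of freedom and scale of the
#'   half-Student-t prior on the residual SD (mm).
#' @return an object of class `growth_priors` (a named list).
#' @examples
#' growth_priors()
#' @export
growth_priors <- function(linf_sd = 700, k_sd = 1, t0_sd = 8,
                          sigma_df = 3, sigma_scale = 40) {
  stopifnot(linf_sd > 0, k_sd > 0, t0_sd > 0, sigma_df > 0, sigma_scale > 0)
  structure(list(linf_sd = linf_sd, k_sd = k_sd, t0_sd = t0_sd,
                 sigma_df = sigma_df, sigma_scale = sigma_scale),
            class = "growth_priors")
}

#' @export
print.growth_priors <- function(x, ...) {
  cat("Growth-model priors (truncated at zero unless noted):\n")
  cat(sprintf("  linf  ~ Normal(0, %g) T[0, Inf)\n", x$linf_sd))
  cat(sprintf("  k     ~ Normal(0, %g) T[0, Inf)\n", x$k_sd))
  cat(sprintf("  t0    ~ Normal(0, %g)  (untruncated)\n", x$t0_sd))
  cat(sprintf("  sigma ~ Student-t(%g, 0, %g) T[0, Inf)\n",
              x$sigma_df, x$sigma_scale))
  invisible(x)
}
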