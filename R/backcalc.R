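#' Disc width on vertebral radius regression
#'
#' Ordinary least squares of body size on centrum radius, `DW = a + b*VR`.
#' A tight linear relation is the evidence of proportionality between
#' somatic and vertebral growth that back-calculation relies on, and its
#' coefficients feed the body-proportional back-calculation.
#'
#' @param data data frame with columns `dw_mm` and `vr_mm`.
#' @return list of class `dwvr_fit`: `a` (intercept, mm), `b` (slope, mm per
#'   mm), `r2`, `n`, `residual_sd` (mm), and the underlying `lm` in `model`.
#' @export
fit_dw_vr <- function(data) {
  stopifnot(all(c("dw_mm", "vr_mm") %in% names(data)))
  data <- data[is.finite(data$dw_mm) & is.finite(data$vr_mm), ]
  if (nrow(data) < 3) stop("need at least 3 fish with DW and VR")
  if (stats::sd(data$vr_mm) == 0) stop("vertebral radius has zero variance")
  m <- stats::lm(dw_mm ~ vr_mm, data = data)
  structure(list(a = unname(stats::coef(m)[1]), b = unname(stats::coef(m)[2]),
                 r2 = summary(m)$r.squared, n = nrow(data),
                 residual_sd = summary(m)$sigma, model = m),
            class = "dwvr_fit")
}

#' @export
print.dwvr_fit <- function(x, ...) {
  cat(sprintf("DW-VR regression (n = %d): DW = %.2f + %.2f * VR,  r2 = %.3f, residual SD = %.1f mm\n",
              x$n, x$a, x$b, x$r2, x$residual_sd))
  invisible(x)
}

#' ANCOVA test of sex differences in the DW-VR relation
#'
#' Tests whether one regression line can be pooled across sexes by nested
#' F-tests: first the sex-by-VR interaction (separate slopes) against a
#' common slope, then the sex intercept given a common slope against a
#' single line. Pooling is recommended when both tests are non-significant
#' at `alpha`.
#'
#' @param data data frame with `dw_mm`, `vr_mm` and `sex` (`"M"`/`"F"`).
#' @param alpha significance level for the pooling decision.
#' @return list of class `ancova_sex`: `p_slope` (interaction p-value),
#'   `p_intercept` (sex effect given common slope), `pooled` flag, `alpha`,
#'   `n_by_sex`.
#' @export
ancova_sex <- function(data, alpha = 0.05) {
  stopifnot(all(c("dw_mm", "vr_mm", "sex") %in% names(data)))
  tab <- table(data$sex)
  if (length(tab) < 2 || any(tab < 3)) {
    warning("one sex absent or with < 3 fish; pooling forced")
    return(structure(list(p_slope = NA_real_, p_intercept = NA_real_,
                          pooled = TRUE, alpha = alpha,
                          n_by_sex = as.list(tab)),
                     class = "ancova_sex"))
  }
  m_full <- stats::lm(dw_mm ~ vr_mm * sex, data = data)
  m_add  <- stats::lm(dw_mm ~ vr_mm + sex, data = data)
  m_one  <- stats::lm(dw_mm ~ vr_mm, data = data)
  p_slope <- stats::anova(m_add, m_full)[2, "Pr(>F)"]
  p_int   <- stats::anova(m_one, m_add)[2, "Pr(>F)"]
  structure(list(p_slope = p_slope, p_intercept = p_int,
                 pooled = p_slope > alpha && p_int > alpha,
                 alpha = alpha, n_by_sex = as.list(tab)),
            class = "ancova_sex")
}

#' @export
print.ancova_sex <- function(x, ...) {
  cat(sprintf("ANCOVA by sex: interaction p = %.4f, intercept p = %.4f -> %s (alpha = %g)\n",
              x$p_slope, x$p_intercept,
              if (x$pooled) "pool sexes" else "fit sexes separately",
              x$alpha))
  invisible(x)
}

#' Back-calculate size-at-age by the body-proportional hypothesis
#'
#' Francis's linear body-proportional hypothesis (BPH): for a fish captured
#' at disc width \eqn{DW_c} with centrum radius \eqn{VR_c}, the size when
#' band `t` (radius \eqn{VR_t}) was deposited is
#' \deqn{DW_t = DW_c \frac{a + b\,VR_t}{a + b\,VR_c}}
#' with `a`, `b` the population DW-VR regression coefficients. One pair is
#' produced per band including the birthmark (age 0); at the vertebral edge
#' (`VR_t = VR_c`) the back-calculated size equals the capture size.
#'
#' Fish whose denominator `a + b*VR_c` is non-positive, or whose radii
#' exceed the centrum radius, are skipped with a warning.
#'
#' @param fish data frame in the ageing-table schema: `fish_id`, `sex`,
#'   `dw_mm`, `vr_mm` and `band_radii_mm` (";"-separated ascending radii
#'   including the birthmark, or a list column of numeric vectors).
#' @param fit a [fit_dw_vr()] result (or any list with elements `a`, `b`).
#' @return data frame with columns `fish_id`, `sex`, `age`, `dw_back`.
#' @export
back_calculate <- function(fish, fit) {
  stopifnot(all(c("fish_id", "sex", "dw_mm", "vr_mm", "band_radii_mm") %in%
                  names(fish)))
  a <- fit$a; b <- fit$b
  out <- vector("list", nrow(fish))
  skipped <- character(0)
  for (i in seq_len(nrow(fish))) {
    radii <- fish$band_radii_mm[[i]]
    if (is.character(radii)) radii <- split_radii(radii)
    vr <- fish$vr_mm[i]; dw <- fish$dw_mm[i]
    denom <- a + b * vr
    if (!is.finite(denom) || denom <= 0 || any(radii > vr * (1 + 1e-6))) {
      skipped <- c(skipped, fish$fish_id[i])
      next
    }
    out[[i]] <- data.frame(fish_id = fish$fish_id[i], sex = fish$sex[i],
                           age = seq_along(radii) - 1L,
                           dw_back = dw * (a + b * radii) / denom)
  }
  if (length(skipped) > 0)
    warning("skipped ", length(skipped), " fish with invalid geometry: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no fish could be back-calculated")
  rownames(res) <- NULL
  res
}

#' Observed versus back-calculated size-at-age summary
#'
#' Per sex and age: the number `n` and mean disc width of fish observed at
#' that age, next to the number `m` of band readings and mean
#' back-calculated disc width at that age. Because older bands are nested
#' within older fish, `m` is non-increasing in age within a sex.
#'
#' @param pairs back-calculated pairs from [back_calculate()].
#' @param observed data frame with `sex`, `age` (accepted integer age) and
#'   `dw_mm` per fish.
#' @return data frame with columns `sex`, `age`, `n`, `dw_avg`, `m`,
#'   `dw_back`.
#' @export
summarize_by_age <- function(pairs, observed) {
  stopifnot(nrow(pairs) > 0)
  bc <- stats::aggregate(dw_back ~ sex + age, pairs, mean)
  bc$m <- stats::aggregate(dw_back ~ sex + age, pairs, length)$dw_back
  if (!is.null(observed) && nrow(observed) > 0) {
    ob <- stats::aggregate(dw_mm ~ sex + age, observed, mean)
    ob$n <- stats::aggregate(dw_mm ~ sex + age, observed, length)$dw_mm
    out <- merge(bc, ob, by = c("sex", "age"), all = TRUE)
  } else {
    out <- bc; out$dw_mm <- NA_real_; out$n <- 0L
  }
  out$n[is.na(out$n)] <- 0L
  out <- out[order(out$sex, out$age),
             c("sex", "age", "n", "dw_mm", "m", "dw_back")]
  names(out)[c(4, 6)] <- c("dw_avg", "dw_back")
  rownames(out) <- NULL
  out
}
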