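#' @keywords internal
reads_matrix <- function(rm, min_reads = 2) {
  if (is.data.frame(rm)) {
    cols <- grep("^read[0-9]*$", names(rm), value = TRUE)
    if (length(cols) == 0) cols <- names(rm)[vapply(rm, is.numeric, TRUE)]
    rm <- as.matrix(rm[, sort(cols), drop = FALSE])
  }
  rm <- as.matrix(rm)
  if (ncol(rm) < min_reads)
    stop("need at least ", min_reads, " reading sessions per fish")
  if (any(rm < 0) || any(rm != round(rm)))
    stop("reads must be non-negative integer band counts")
  rm
}

#' Average percentage error of repeated age readings
#'
#' Beamish-Fournier APE: for each fish the mean absolute deviation of its
#' reads from their mean, relative to that mean, averaged over fish and
#' expressed in percent. Fish whose reads average zero (all readings age 0)
#' are excluded from the denominator since their relative error is
#' undefined.
#'
#' @param rm data frame or matrix of integer band counts, one row per fish,
#'   one column per reading session (columns `read1`, `read2`, ...).
#' @return APE in percent.
#' @examples
#' ape(data.frame(read1 = c(2, 5), read2 = c(3, 5))) # 10
#' @export
ape <- function(rm) {
  x <- reads_matrix(rm)
  xbar <- rowMeans(x)
  keep <- xbar > 0
  if (!any(keep))
    stop("APE undefined: every fish has mean read 0")
  per_fish <- rowMeans(abs(x[keep, , drop = FALSE] - xbar[keep])) / xbar[keep]
  100 * mean(per_fish)
}

#' Coefficient of variation of repeated age readings
#'
#' Chang's CV: the per-fish SD of reads relative to their mean, averaged
#' over fish, in percent. For two reading sessions `cv_reads` equals
#' `sqrt(2)` times [ape()] exactly.
#'
#' @inheritParams ape
#' @return CV in percent.
#' @examples
#' cv_reads(data.frame(read1 = c(2, 5), read2 = c(3, 5))) # 14.142
#' @export
cv_reads <- function(rm) {
  x <- reads_matrix(rm)
  xbar <- rowMeans(x)
  keep <- xbar > 0
  if (!any(keep))
    stop("CV undefined: every fish has mean read 0")
  per_fish <- apply(x[keep, , drop = FALSE], 1, stats::sd) / xbar[keep]
  100 * mean(per_fish)
}

#' Percent agreement between the first two readings
#'
#' @inheritParams ape
#' @param tolerance maximum absolute difference (years) still counted as
#'   agreement.
#' @return percent of fish whose first two reads differ by at most
#'   `tolerance`.
#' @export
percent_agreement <- function(rm, tolerance = 0) {
  stopifnot(tolerance >= 0)
  x <- reads_matrix(rm)
  100 * mean(abs(x[, 1] - x[, 2]) <= tolerance)
}

#' Age-bias table
#'
#' For each distinct reference age (the second reading session), the mean
#' nonreference age (first session) with a 95% t-interval and a two-sided
#' one-sample t-test of the nonreference reads against the reference value.
#' Rows with a single fish, or with zero variance among nonreference reads,
#' carry no test (`p_value` is `NA` and `note` says why).
#'
#' @inheritParams ape
#' @param conf_level confidence level of the interval.
#' @return data frame with one row per reference age: `reference_age`, `n`,
#'   `mean_nonref`, `ci_lwr`, `ci_upr`, `t_stat`, `p_value`, `note`.
#' @export
age_bias <- function(rm, conf_level = 0.95) {
  x <- reads_matrix(rm)
  nonref <- x[, 1]; ref <- x[, 2]
  rows <- lapply(sort(unique(ref)), function(r) {
    y <- nonref[ref == r]
    n <- length(y); m <- mean(y)
    if (n < 2) {
      return(data.frame(reference_age = r, n = n, mean_nonref = m,
                        ci_lwr = NA_real_, ci_upr = NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        note = "n = 1: no test"))
    }
    if (stats::sd(y) == 0) {
      return(data.frame(reference_age = r, n = n, mean_nonref = m,
                        ci_lwr = m, ci_upr = m,
                        t_stat = NA_real_, p_value = NA_real_,
                        note = "zero variance: t undefined"))
    }
    tt <- stats::t.test(y, mu = r, conf.level = conf_level)
    data.frame(reference_age = r, n = n, mean_nonref = m,
               ci_lwr = tt$conf.int[1], ci_upr = tt$conf.int[2],
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve disagreeing reads with a third reading
#'
#' Standard adjudication workflow: if the first two reads agree, that count
#' is accepted; if they disagree and a third read matches either, the third
#' read is accepted; otherwise the fish is excluded from age analyses.
#'
#' @param rm data frame with columns `read1`, `read2` and optionally
#'   `read3`.
#' @return integer vector of accepted ages, `NA` for excluded fish.
#' @export
adjudicate_reads <- function(rm) {
  stopifnot(all(c("read1", "read2") %in% names(rm)))
  r1 <- rm$read1; r2 <- rm$read2
  out <- ifelse(r1 == r2, r1, NA_integer_)
  if ("read3" %in% names(rm)) {
    r3 <- rm$read3
    fix <- is.na(out) & !is.na(r3) & (r3 == r1 | r3 == r2)
    out[fix] <- r3[fix]
  }
  as.integer(out)
}

#' Between-reading precision report
#'
#' Bundles [ape()], [cv_reads()] and percent agreement (exact and within
#' one year) for a set of repeated readings.
#'
#' @inheritParams ape
#' @return list of class `precision_report` with elements `ape_percent`,
#'   `cv_percent`, `pct_agree_exact`, `pct_agree_within_1`, `n_fish`.
#' @export
precision_report <- function(rm) {
  x <- reads_matrix(rm)
  structure(list(ape_percent = ape(x), cv_percent = cv_reads(x),
                 pct_agree_exact = percent_agreement(x, 0),
                 pct_agree_within_1 = percent_agreement(x, 1),
                 n_fish = nrow(x)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Ageing precision (n = %d fish):\n", x$n_fish))
  cat(sprintf("  APE %.2f%%  CV %.2f%%  agree %.1f%% exact, %.1f%% within 1 y\n",
              x$ape_percent, x$cv_percent, x$pct_agree_exact,
              x$pct_agree_within_1))
  invisible(x)
}
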