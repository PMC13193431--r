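#' Published dasyatid growth parameters
#'
#' Loads the bundled cross-species table of published growth parameter
#' estimates for dasyatid stingrays (species, region, model family, sex,
#' size-at-birth, asymptotic size, growth coefficient, inflection/zero-size
#' age, maximum observed age, sample size). Two Aegean Sea rows whose `k`
#' and size-at-birth estimates are implausible for medium-sized dasyatids
#' carry `excluded = TRUE` and are dropped by default in
#' [comparative_stats()].
#'
#' @param path optional path to a CSV in the same schema; defaults to the
#'   packaged table.
#' @return data frame of comparative records.
#' @export
dasyatid_growth <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dasyatid_growth_params.csv",
                        package = "rayage", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "size_class", "region", "model", "sex", "dw0_mm",
            "dwinf_mm", "k", "t0", "age_max", "n", "excluded")
  if (!all(need %in% names(out)))
    stop("comparative table missing columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out
}

spearman_test <- function(x, y) {
  n <- sum(stats::complete.cases(x, y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Cross-species comparative statistics
#'
#' Life-history relationships over the comparative growth table: (i) the
#' Spearman rank correlation between the growth coefficient `k` and the
#' asymptotic size, with a least-squares quadratic
#' `dwinf = c0 + c1*k + c2*k^2`; (ii) size-at-birth expressed as a fraction
#' of asymptotic size, its Spearman correlation with asymptotic size, and a
#' least-squares line. Ties get average ranks; Spearman p-values use the
#' t approximation (exact permutation when n <= 10).
#'
#' @param records comparative table (default [dasyatid_growth()]).
#' @param exclude_flagged drop rows with `excluded = TRUE` (default, the
#'   convention stated with the source plots).
#' @param drop_pooled_duplicates also drop pooled rows from studies that
#'   print sex-specific rows for the same species and region (the point-set
#'   convention is not fully documented; see [comparative_sensitivity()]).
#' @return list of class `comparative_stats`: `rho_k_dwinf`, `p_k_dwinf`,
#'   `quad_coef` (c0, c1, c2), `rho_dw0frac_dwinf`, `p_dw0frac_dwinf`,
#'   `line_coef` (intercept, slope), `n`.
#' @export
comparative_stats <- function(records = dasyatid_growth(),
                              exclude_flagged = TRUE,
                              drop_pooled_duplicates = FALSE) {
  r <- records
  if (exclude_flagged) r <- r[!r$excluded, , drop = FALSE]
  if (drop_pooled_duplicates) {
    keyed <- paste(r$species, r$region, r$source)
    sexed <- unique(keyed[r$sex %in% c("male", "female")])
    r <- r[!(r$sex == "pooled" & keyed %in% sexed), , drop = FALSE]
  }
  if (nrow(r) < 4) stop("need at least 4 usable records")
  s1 <- spearman_test(r$k, r$dwinf_mm)
  quad <- stats::lm(dwinf_mm ~ k + I(k^2), data = r)
  frac <- r$dw0_mm / r$dwinf_mm
  s2 <- spearman_test(frac, r$dwinf_mm)
  line <- stats::lm(frac ~ dwinf_mm, data = r)
  structure(list(rho_k_dwinf = s1$rho, p_k_dwinf = s1$p,
                 quad_coef = stats::setNames(stats::coef(quad),
                                             c("c0", "c1", "c2")),
                 rho_dw0frac_dwinf = s2$rho, p_dw0frac_dwinf = s2$p,
                 line_coef = stats::setNames(stats::coef(line),
                                             c("intercept", "slope")),
                 n = nrow(r)),
            class = "comparative_stats")
}

#' @export
print.comparative_stats <- function(x, ...) {
  cat(sprintf("Comparative life-history statistics (n = %d records):\n", x$n))
  cat(sprintf("  Spearman rho(k, DWinf) = %.3f (p = %.2g)\n",
              x$rho_k_dwinf, x$p_k_dwinf))
  cat(sprintf("  quadratic: DWinf = %.1f + %.1f k + %.1f k^2\n",
              x$quad_coef[1], x$quad_coef[2], x$quad_coef[3]))
  cat(sprintf("  Spearman rho(DW0/DWinf, DWinf) = %.3f (p = %.2g)\n",
              x$rho_dw0frac_dwinf, x$p_dw0frac_dwinf))
  cat(sprintf("  line: DW0/DWinf = %.3g %+.3g * DWinf\n",
              x$line_coef[1], x$line_coef[2]))
  invisible(x)
}

#' Sensitivity of comparative correlations to the row-set convention
#'
#' The published point set behind comparative plots is rarely fully
#' specified when studies print both pooled and sex-specific fits.
#' Recomputes the two Spearman correlations under the plausible row-set
#' conventions so their sensitivity is visible.
#'
#' @param records comparative table (default [dasyatid_growth()]).
#' @return data frame with one row per convention: `convention`, `n`,
#'   `rho_k_dwinf`, `rho_dw0frac_dwinf`.
#' @export
comparative_sensitivity <- function(records = dasyatid_growth()) {
  conv <- list(
    stated_exclusions = list(exclude_flagged = TRUE,
                             drop_pooled_duplicates = FALSE),
    drop_pooled_duplicates = list(exclude_flagged = TRUE,
                                  drop_pooled_duplicates = TRUE),
    all_rows = list(exclude_flagged = FALSE,
                    drop_pooled_duplicates = FALSE))
  rows <- lapply(names(conv), function(nm) {
    cs <- do.call(comparative_stats, c(list(records = records), conv[[nm]]))
    data.frame(convention = nm, n = cs$n,
               rho_k_dwinf = cs$rho_k_dwinf,
               rho_dw0frac_dwinf = cs$rho_dw0frac_dwinf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Theoretical versus observed longevity
#'
#' Pairs Ricker's theoretical longevity (age at 95% of asymptotic size,
#' `5*ln(2)/k`) with the maximum observed age.
#'
#' @param k growth coefficient(s), per year (conventionally from the
#'   best-fitting growth model).
#' @param observed_max maximum observed age(s), years.
#' @param label optional labels (e.g. sex).
#' @return data frame with `label`, `k`, `t95`, `observed_max`,
#'   `difference` (theoretical minus observed, years).
#' @export
longevity_table <- function(k, observed_max, label = NULL) {
  t95 <- ricker_longevity(k)
  data.frame(label = if (is.null(label)) seq_along(k) else label,
             k = k, t95 = t95, observed_max = observed_max,
             difference = t95 - observed_max)
}
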