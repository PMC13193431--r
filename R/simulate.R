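#' Derive a stage-specific RNG seed
#'
#' One base seed drives the whole generator; each stage draws from its own
#' stream keyed by a fixed label, so adding a stage never shifts the draws
#' of the others.
#'
#' @param seed integer base seed.
#' @param label character stage label.
#' @return integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, label) {
  m <- 2147483647
  h <- 0
  for (i in utf8ToInt(label)) h <- (h * 31 + i) %% m
  as.integer(((abs(as.numeric(seed)) %% m) * 48271 + h) %% m)
}

#' Configuration for the synthetic batoid population
#'
#' Defaults emulate a two-year monthly fishery sampling programme of a
#' sexually dimorphic medium-sized stingray: logistic growth with female
#' asymptotic size larger and growth coefficient lower than males, a common
#' linear disc-width/vertebral-radius proportionality, annual band
#' deposition peaking in austral spring-summer (December), ~12% one-year
#' read disagreement, and gillnet-like size-selective retention
#' concentrating catches around 300-450 mm disc width.
#'
#' @param n_fish number of fish retained.
#' @param sex_ratio fraction male in `[0, 1]`.
#' @param true_model growth family generating sizes (one of
#'   [growth_families]).
#' @param true_params named list with elements `M` and `F`, each a list with
#'   `linf` (mm), `k` (per year), `t0` (years) (and `dw0` for vbgm2).
#' @param growth_sd residual SD of capture size about the curve (mm).
#' @param vr_intercept,vr_slope coefficients of the linear relation
#'   `DW = a + b * VR` (mm, mm per mm) used to place vertebral radii.
#' @param vr_sd measurement SD of the centrum radius (mm).
#' @param deposition_mean_month calendar month (1-12) of peak opaque-band
#'   deposition.
#' @param deposition_concentration von Mises concentration of the seasonal
#'   deposition signal (>= 0).
#' @param edge_amplitude peak opaque-edge probability, in (0, 1].
#' @param read_error_prob probability a band count is misread by one year.
#' @param selectivity `NULL`, or a list with `mode` and `spread` (mm) giving
#'   a bell-shaped retention curve; fish are retained with probability
#'   `exp(-(DW - mode)^2 / (2 spread^2))` and resampled until `n_fish`.
#' @param sampling_months data frame with columns `year`, `month`; capture
#'   dates are drawn uniformly from its rows. Default: monthly May 2022
#'   through April 2024.
#' @param age_dist integer ages sampled uniformly (default 0-11).
#' @param seed integer seed controlling every stage.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 272,
                       sex_ratio = 201 / 272,
                       true_model = "logistic",
                       true_params = list(
                         M = list(linf = 401.70, k = 0.45, t0 = -0.36),
                         F = list(linf = 512.22, k = 0.29, t0 = 0.82)),
                       growth_sd = 20,
                       vr_intercept = 160, vr_slope = 105, vr_sd = 0.05,
                       deposition_mean_month = 12,
                       deposition_concentration = 2,
                       edge_amplitude = 0.9,
                       read_error_prob = 0.125,
                       selectivity = list(mode = 375, spread = 75),
                       sampling_months = NULL,
                       age_dist = 0:11,
                       seed = 1) {
  if (is.null(sampling_months)) {
    ym <- rbind(data.frame(year = 2022, month = 5:12),
                data.frame(year = 2023, month = 1:12),
                data.frame(year = 2024, month = 1:4))
    sampling_months <- ym
  }
  cfg <- structure(list(
    n_fish = n_fish, sex_ratio = sex_ratio, true_model = true_model,
    true_params = true_params, growth_sd = growth_sd,
    vr_intercept = vr_intercept, vr_slope = vr_slope, vr_sd = vr_sd,
    deposition_mean_month = deposition_mean_month,
    deposition_concentration = deposition_concentration,
    edge_amplitude = edge_amplitude, read_error_prob = read_error_prob,
    selectivity = selectivity, sampling_months = sampling_months,
    age_dist = age_dist, seed = seed), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_fish >= 1, sex_ratio >= 0, sex_ratio <= 1,
              true_model %in% growth_families,
              growth_sd >= 0, vr_sd >= 0, vr_slope > 0,
              deposition_mean_month >= 1, deposition_mean_month <= 12,
              deposition_concentration >= 0,
              edge_amplitude > 0, edge_amplitude <= 1,
              read_error_prob >= 0, read_error_prob <= 1,
              all(age_dist >= 0))
    for (s in c("M", "F")) {
      p <- true_params[[s]]
      stopifnot(p$linf > 0, p$k > 0)
      if (growth_curve_params(0, true_model, p) < 0)
        stop("growth curve negative at age 0 for sex ", s,
             "; inconsistent parameters")
    }
    if (!is.null(selectivity))
      stopifnot(selectivity$mode > 0, selectivity$spread > 0)
  })
  invisible(cfg)
}

#' Calendar month to circular angle
#'
#' Mid-month convention: month `m` maps to `2*pi*(m - 0.5)/12` radians, so
#' month 1 sits at mid-January and the circle closes after December.
#'
#' @param m calendar month(s), 1-12 (fractional allowed).
#' @return angle(s) in radians.
#' @export
month_angle <- function(m) 2 * pi * (m - 0.5) / 12

# seasonal opaque-edge probability used by the generator (annual-cycle link)
seasonal_edge_prob <- function(month, mean_month, kappa, amplitude) {
  mu <- month_angle(mean_month)
  amplitude * exp(kappa * (cos(month_angle(month) - mu) - 1))
}

#' Simulate a vertebral-band-aged population
#'
#' Generates `n_fish` specimens with known truth. Integer ages are drawn
#' uniformly from `age_dist`; capture size is the sex-specific growth curve
#' at (age + within-year fraction) plus Normal noise, the noise acting as a
#' persistent individual scaling so each fish's whole trajectory is
#' proportional to its realised size. The centrum radius follows the linear
#' DW-VR relation with measurement noise, and interior band radii are placed
#' so that exact body-proportional back-calculation with the true
#' coefficients returns the fish's true size at each band age. Edge type is
#' Bernoulli with a seasonally peaked probability; age-0 fish carry only the
#' birthmark. Deterministic given `cfg$seed`.
#'
#' The within-year age fraction is `((capture month - deposition month) mod
#' 12) / 12`, so growth is continuous between band deposition events.
#'
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_dataset` with components `fish` (one row
#'   per specimen, pipeline CSV schema: `fish_id`, `sex`, `capture_date`,
#'   `dw_mm`, `vr_mm`, `gear`, `region`, `edge_type`, `read1`,
#'   `band_radii_mm` as a ";"-joined ascending list including the birthmark),
#'   `truth` (per fish: `true_age`, `age_frac`, `scale`, and the true
#'   size-at-age trajectory as a list column `dw_at_age`), and `config`.
#' @export
simulate_population <- function(cfg) {
  validate_sim_config(cfg)
  a <- cfg$vr_intercept; b <- cfg$vr_slope
  sel_prob <- function(dw) {
    if (is.null(cfg$selectivity)) return(rep(1, length(dw)))
    exp(-(dw - cfg$selectivity$mode)^2 / (2 * cfg$selectivity$spread^2))
  }

  draw_batch <- function(n) {
    sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "M", "F")
    age <- sample(cfg$age_dist, n, replace = TRUE)
    mi <- sample.int(nrow(cfg$sampling_months), n, replace = TRUE)
    month <- cfg$sampling_months$month[mi]
    year <- cfg$sampling_months$year[mi]
    frac <- ((month - cfg$deposition_mean_month) %% 12) / 12
    mu <- vapply(seq_len(n), function(i)
      growth_curve_params(age[i] + frac[i], cfg$true_model,
                          cfg$true_params[[sex[i]]]), 0)
    dw <- mu + stats::rnorm(n, 0, cfg$growth_sd)
    data.frame(sex = sex, age = age, month = month, year = year,
               frac = frac, mu = mu, dw = dw)
  }

  set.seed(stage_seed(cfg$seed, "population"))
  pool <- draw_batch(cfg$n_fish)
  keep <- pool$dw > 0 & stats::runif(nrow(pool)) < sel_prob(pool$dw)
  pool <- pool[keep, , drop = FALSE]
  while (nrow(pool) < cfg$n_fish) {
    more <- draw_batch(cfg$n_fish)
    keep <- more$dw > 0 & stats::runif(nrow(more)) < sel_prob(more$dw)
    pool <- rbind(pool, more[keep, , drop = FALSE])
  }
  pool <- pool[seq_len(cfg$n_fish), , drop = FALSE]
  rownames(pool) <- NULL

  # persistent individual scaling: the whole trajectory is proportional to
  # the realised capture size, so band radii stay below the centrum radius
  scale <- pool$dw / pool$mu

  set.seed(stage_seed(cfg$seed, "vertebrae"))
  vr <- (pool$dw - a) / b + stats::rnorm(cfg$n_fish, 0, cfg$vr_sd)
  vr <- pmax(vr, 0.05)

  radii <- vector("list", cfg$n_fish)
  dw_at_age <- vector("list", cfg$n_fish)
  for (i in seq_len(cfg$n_fish)) {
    ages_i <- 0:pool$age[i]
    tr <- scale[i] * vapply(ages_i, function(tt)
      growth_curve_params(tt, cfg$true_model,
                          cfg$true_params[[pool$sex[i]]]), 0)
    dw_at_age[[i]] <- tr
    # invert the body-proportional relation at the true coefficients;
    # a band deposited in the capture month sits at the edge, so clamp
    # strictly inside the centrum radius
    radii[[i]] <- pmin(((tr / pool$dw[i]) * (a + b * vr[i]) - a) / b,
                       vr[i] * (1 - 1e-9))
  }

  set.seed(stage_seed(cfg$seed, "edges"))
  p_edge <- seasonal_edge_prob(pool$month, cfg$deposition_mean_month,
                               cfg$deposition_concentration,
                               cfg$edge_amplitude)
  edge <- ifelse(pool$age == 0, "birthmark_only",
                 ifelse(stats::runif(cfg$n_fish) < p_edge,
                        "opaque", "translucent"))

  fish <- data.frame(
    fish_id = sprintf("F%04d", seq_len(cfg$n_fish)),
    sex = pool$sex,
    capture_date = sprintf("%04d-%02d-15", pool$year, pool$month),
    dw_mm = pool$dw, vr_mm = vr,
    gear = "gillnet", region = "synthetic",
    edge_type = edge,
    read1 = pool$age,
    band_radii_mm = vapply(radii, function(r)
      paste(sprintf("%.12g", r), collapse = ";"), ""))

  truth <- data.frame(fish_id = fish$fish_id, true_age = pool$age,
                      age_frac = pool$frac, scale = scale)
  truth$dw_at_age <- dw_at_age
  truth$band_radii <- radii

  structure(list(fish = fish, truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ageing dataset: %d fish (%d M / %d F), ages %d-%d\n",
              nrow(x$fish), sum(x$fish$sex == "M"), sum(x$fish$sex == "F"),
              min(x$truth$true_age), max(x$truth$true_age)))
  cat(sprintf("  truth: %s growth, seed %d\n", x$config$true_model,
              x$config$seed))
  invisible(x)
}

#' Add a second (error-prone) reading session
#'
#' Appends a `read2` column: each second read equals the true band count
#' with probability `1 - error_prob`, otherwise differs by one year (plus or
#' minus with equal probability, floored at zero).
#'
#' @param ds a `synthetic_dataset` from [simulate_population()].
#' @param error_prob probability of a one-year read error.
#' @param seed integer seed (defaults to a stream derived from the
#'   generating seed).
#' @return the dataset with `fish$read2` added.
#' @export
simulate_double_reads <- function(ds, error_prob = ds$config$read_error_prob,
                                  seed = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"),
            error_prob >= 0, error_prob <= 1)
  if (is.null(seed)) seed <- stage_seed(ds$config$seed, "reads")
  set.seed(seed)
  n <- nrow(ds$fish)
  err <- stats::runif(n) < error_prob
  shift <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  ds$fish$read2 <- pmax(ds$truth$true_age + ifelse(err, shift, 0L), 0L)
  ds
}

#' Simulate direct size-at-age observations
#'
#' Draws `n` (age, size) observations from a growth curve with i.i.d.
#' Normal residuals: the generative model assumed by [growth_fit()]. Used
#' for parameter- and model-recovery experiments where the full population
#' generator is unnecessary.
#'
#' @param n number of observations.
#' @param family growth family (one of [growth_families]).
#' @param params named list of true parameters (`linf`, `k`, `t0`/`dw0`).
#' @param sigma residual SD (mm).
#' @param ages integer ages to sample uniformly (default 0-11).
#' @param seed integer seed.
#' @return data frame with columns `age` and `dw`.
#' @export
sim_growth_obs <- function(n, family, params, sigma, ages = 0:11, seed = 1) {
  set.seed(seed)
  age <- sample(ages, n, replace = TRUE)
  mu <- growth_curve_params(age, family, params)
  data.frame(age = age, dw = mu + stats::rnorm(n, 0, sigma))
}
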