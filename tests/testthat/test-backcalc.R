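test_that("the DW-VR regression recovers an exact line", {
  d <- data.frame(vr_mm = c(0.5, 1, 1.5, 2, 3), dw_mm = 100 + 500 * c(0.5, 1, 1.5, 2, 3))
  fit <- suppressWarnings(fit_dw_vr(d))
  expect_equal(fit$a, 100, tolerance = 1e-9)
  expect_equal(fit$b, 500, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_error(fit_dw_vr(d[1, ]), "at least 3")
  expect_error(fit_dw_vr(data.frame(vr_mm = c(1, 1, 1),
                                    dw_mm = c(2, 3, 4))), "zero variance")
})

test_that("regression coefficients recover the generator truth", {
  ds <- simulate_population(sim_config(n_fish = 250, seed = 17))
  fit <- fit_dw_vr(ds$fish)
  se <- summary(fit$model)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$a - 160), 3 * se[1])
  expect_lt(abs(fit$b - 105), 3 * se[2])
})

test_that("ANCOVA pools under a common line and splits under different
           slopes", {
  # H0: both sexes on the same line
  pooled <- 0
  for (r in 1:40) {
    set.seed(300 + r)
    n <- 120
    vr <- runif(n, 0.5, 3)
    d <- data.frame(vr_mm = vr, dw_mm = 160 + 105 * vr + rnorm(n, 0, 15),
                    sex = rep(c("M", "F"), length.out = n))
    pooled <- pooled + ancova_sex(d)$pooled
  }
  expect_gte(pooled / 40, 0.85)  # ~95% expected at alpha = 0.05
  # H1: clearly different slopes
  set.seed(9)
  vr <- runif(120, 0.5, 3)
  sex <- rep(c("M", "F"), 60)
  slope <- ifelse(sex == "M", 500, 800)
  d1 <- data.frame(vr_mm = vr, dw_mm = 100 + slope * vr + rnorm(120, 0, 10),
                   sex = sex)
  a1 <- ancova_sex(d1)
  expect_lt(a1$p_slope, 0.001)
  expect_false(a1$pooled)
  # one sex missing: pooling forced with a warning
  expect_warning(a0 <- ancova_sex(d1[d1$sex == "M", ]), "forced")
  expect_true(a0$pooled)
})

test_that("ANCOVA p-values are uniform under random sex labels", {
  set.seed(77)
  ps <- replicate(60, {
    n <- 80
    vr <- runif(n, 0.5, 3)
    d <- data.frame(vr_mm = vr, dw_mm = 160 + 105 * vr + rnorm(n, 0, 12),
                    sex = sample(c("M", "F"), n, replace = TRUE))
    ancova_sex(d)$p_slope
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("body-proportional back-calculation obeys its identities", {
  fit <- list(a = 100, b = 500)
  fish <- data.frame(fish_id = "A", sex = "M", dw_mm = 400, vr_mm = 2,
                     band_radii_mm = "0.5;1;2")
  bc <- back_calculate(fish, fit)
  expect_equal(bc$age, 0:2)
  # at the vertebral edge the back-calculated size is the capture size
  expect_equal(bc$dw_back[3], 400)
  # a = 0 reduces to pure proportionality: DW_c * VR_t / VR_c
  bc0 <- back_calculate(fish, list(a = 0, b = 500))
  expect_equal(bc0$dw_back, 400 * c(0.5, 1, 2) / 2)
  expect_equal(bc0$dw_back[2], 200)  # half the edge radius -> half the size
  # trajectories are monotone in age
  expect_true(all(diff(bc$dw_back) > 0))
})

test_that("back-calculation is scale equivariant", {
  ds <- simulate_population(sim_config(n_fish = 40, seed = 23))
  fit <- fit_dw_vr(ds$fish)
  pairs <- suppressWarnings(back_calculate(ds$fish, fit))
  scaled <- ds$fish
  scaled$dw_mm <- scaled$dw_mm * 2
  fit2 <- fit_dw_vr(scaled)
  expect_equal(fit2$a, 2 * fit$a, tolerance = 1e-8)
  expect_equal(fit2$b, 2 * fit$b, tolerance = 1e-8)
  pairs2 <- suppressWarnings(back_calculate(scaled, fit2))
  expect_equal(pairs2$dw_back, 2 * pairs$dw_back, tolerance = 1e-8)
})

test_that("invalid geometry is skipped with a warning, not dropped
           silently", {
  fish <- data.frame(fish_id = c("A", "B"), sex = "M", dw_mm = 400,
                     vr_mm = c(2, 2),
                     band_radii_mm = c("0.5;1;2", "0.5;3"))
  expect_warning(bc <- back_calculate(fish, list(a = 100, b = 500)),
                 "skipped 1 fish")
  expect_identical(unique(bc$fish_id), "A")
  # negative denominator
  expect_warning(
    expect_error(back_calculate(fish[1, ], list(a = -2000, b = 500)),
                 "no fish"))
})

test_that("size-at-age summaries count fish and readings correctly", {
  pairs <- data.frame(fish_id = "A", sex = "M", age = 0:2,
                      dw_back = c(210, 260, 300))
  obs <- data.frame(sex = "M", age = 2, dw_mm = 305)
  tab <- summarize_by_age(pairs, obs)
  expect_equal(tab$m, c(1, 1, 1))
  expect_equal(tab$n, c(0, 0, 1))
  expect_equal(tab$dw_back, c(210, 260, 300))
  expect_equal(tab$dw_avg[3], 305)
})

test_that("band readings per age are non-increasing and noise-free
           summaries agree with observation", {
  ds <- simulate_population(noisefree_config(n_fish = 40, seed = 13))
  fit <- suppressWarnings(fit_dw_vr(ds$fish))
  pairs <- back_calculate(ds$fish, fit)
  obs <- ds$fish
  obs$age <- ds$truth$true_age
  tab <- summarize_by_age(pairs, obs)
  for (s in unique(tab$sex)) {
    sub <- tab[tab$sex == s, ]
    expect_true(all(diff(sub$m) <= 0))
    # observed and back-calculated means coincide without noise
    here <- sub$n > 0
    expect_equal(sub$dw_avg[here], sub$dw_back[here], tolerance = 1e-6)
  }
})
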