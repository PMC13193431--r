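test_that("growth input pairs partition by sex", {
  pairs <- data.frame(fish_id = c("A", "A", "A", "B"),
                      sex = c("M", "M", "M", "F"),
                      age = c(0:2, 0), dw_back = c(210, 260, 300, 215))
  obs_m <- build_growth_input(pairs, "M")
  expect_equal(nrow(obs_m), 3)
  obs_all <- build_growth_input(pairs)
  expect_equal(nrow(obs_all), nrow(pairs))
  expect_equal(nrow(obs_m) + nrow(build_growth_input(pairs, "F")),
               nrow(obs_all))
  expect_error(build_growth_input(pairs[pairs$sex == "M", ], "F"),
               "no observations")
})

test_that("posterior recovers logistic truth within three posterior SDs", {
  obs <- sim_growth_obs(200, "logistic", logistic_truth_m, sigma = 20,
                        seed = 3)
  fit <- fit_small(obs, "logistic", seed = 5)
  truth <- c(linf = 401.70, k = 0.45, t0 = -0.36, sigma = 20)
  est <- coef(fit)
  for (p in names(truth)) {
    expect_lt(abs(est[[p]] - truth[[p]]), 3 * fit$summary[p, "sd"],
              label = p)
  }
  expect_true(all(is.finite(fit$rhat)))
  expect_true(fit$converged)
  expect_s3_class(summary(fit), "data.frame")
})

test_that("posterior draws respect the zero truncations", {
  obs <- sim_growth_obs(80, "logistic", logistic_truth_m, sigma = 20,
                        seed = 8)
  fit <- fit_small(obs, "logistic", seed = 9)
  expect_true(all(fit$draws[, "linf"] > 0))
  expect_true(all(fit$draws[, "k"] > 0))
  expect_true(all(fit$draws[, "sigma"] > 0))
  pf <- fit_small(obs, "logistic", seed = 10, prior_only = TRUE,
                  warmup = 200, iter = 1500)
  expect_true(all(pf$draws[, "linf"] > 0))
  expect_true(all(pf$draws[, "k"] > 0))
  expect_true(all(pf$draws[, "sigma"] > 0))
})

test_that("prior-only draws match the truncated-normal quantiles", {
  obs <- sim_growth_obs(40, "logistic", logistic_truth_m, sigma = 20,
                        seed = 2)
  pf <- fit_small(obs, "logistic", seed = 4, prior_only = TRUE,
                  warmup = 200, iter = 3000)
  probs <- c(0.25, 0.5, 0.75)
  q_hat <- unname(stats::quantile(pf$draws[, "linf"], probs))
  q_true <- stats::qnorm(0.5 + 0.5 * probs) * 700  # half-Normal(0, 700)
  expect_equal(q_hat, q_true, tolerance = 0.06)
  # t0 prior is untruncated Normal(0, 8)
  expect_gt(mean(pf$draws[, "t0"] < 0), 0.4)
})

test_that("posterior uncertainty shrinks as residual noise falls", {
  sds <- vapply(c(20, 10, 5), function(sig) {
    obs <- sim_growth_obs(150, "logistic", logistic_truth_m, sigma = sig,
                          seed = 12)
    fit_small(obs, "logistic", seed = 13)$summary["linf", "sd"]
  }, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("vbgm2 anchors at the observed size-at-birth", {
  obs <- sim_growth_obs(150, "vbgm2",
                        list(linf = 388.95, k = 0.45, dw0 = 212.53),
                        sigma = 15, seed = 21)
  fit <- fit_small(obs, "vbgm2", seed = 22)
  expect_equal(fit$dw0, mean(obs$dw[obs$age < 1]))
  expect_equal(fit$dw0_pred, fit$dw0)  # the curve passes through dw0 at 0
  expect_identical(rownames(fit$summary), c("linf", "k", "sigma"))
  # without age-0 observations dw0 must be supplied
  expect_error(growth_fit(dw ~ age, obs[obs$age > 0, ], family = "vbgm2",
                          chains = 2, warmup = 50, iter = 50, seed = 1),
               "age-0")
})

test_that("degenerate inputs are rejected", {
  obs <- sim_growth_obs(30, "logistic", logistic_truth_m, sigma = 20,
                        seed = 2)
  expect_error(growth_fit(dw ~ age, obs[1:3, ], family = "logistic"),
               "at least")
  neg <- obs; neg$dw <- -abs(neg$dw)
  expect_error(growth_fit(dw ~ age, neg, family = "logistic"),
               "non-positive")
})

test_that("prediction, residuals and simulation are coherent", {
  obs <- sim_growth_obs(120, "logistic", logistic_truth_m, sigma = 20,
                        seed = 6)
  fit <- fit_small(obs, "logistic", seed = 7)
  pr <- predict(fit, 0:5, interval = "credible")
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  expect_equal(pr$fit,
               growth_curve_params(0:5, "logistic",
                                   as.list(coef(fit))[c("linf", "k", "t0")]),
               tolerance = 1e-9)
  # prediction bands are wider than credible bands
  pp <- predict(fit, 0:5, interval = "prediction")
  expect_true(all(pp$upr - pp$lwr > pr$upr - pr$lwr))
  expect_equal(residuals(fit), obs$dw - fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(120L, 3L))
  expect_equal(logLik(fit)[[1]], fit$loglik)
})

test_that("model comparison is reproducible and guards its inputs", {
  obs <- sim_growth_obs(150, "logistic", logistic_truth_m, sigma = 20,
                        seed = 14)
  f1 <- fit_small(obs, "logistic", seed = 15)
  f1b <- fit_small(obs, "logistic", seed = 15)
  expect_identical(f1$aic, f1b$aic)  # same data, seed, settings
  f2 <- fit_small(obs, "gompertz", seed = 15)
  cmp <- compare_growth(f1, f2)
  expect_equal(cmp$delta[1], 0)
  expect_equal(sum(cmp$weight), 1)
  expect_equal(cmp$aic, 2 * cmp$n_params - 2 * cmp$loglik, tolerance = 1e-9)
  # different datasets are not comparable
  other <- sim_growth_obs(150, "logistic", logistic_truth_m, sigma = 20,
                          seed = 99)
  f3 <- fit_small(other, "logistic", seed = 15)
  expect_error(compare_growth(f1, f3), "different datasets")
  expect_error(compare_growth(f1), "length")
})

test_that("posterior sex contrasts flag real dimorphism and nothing
           else", {
  obs_m <- sim_growth_obs(150, "logistic", logistic_truth_m, sigma = 20,
                          seed = 16)
  fit_m <- fit_small(obs_m, "logistic", seed = 17, sex = "M")
  # identical posteriors: no parameter flagged
  d0 <- sex_difference(fit_m, fit_m, seed = 3)
  expect_false(any(d0$significant))
  expect_true(all(d0$lwr <= 0 & d0$upr >= 0))
  # posterior shifted by 10 SDs: flagged
  shifted <- fit_m
  shifted$draws[, "linf"] <- shifted$draws[, "linf"] +
    10 * stats::sd(shifted$draws[, "linf"])
  d1 <- sex_difference(shifted, fit_m, seed = 3)
  expect_true(d1$significant[d1$param == "linf"])
  # contrasts are seeded-reproducible
  expect_identical(sex_difference(fit_m, fit_m, seed = 5),
                   sex_difference(fit_m, fit_m, seed = 5))
  fit_g <- fit_small(obs_m, "gompertz", seed = 17)
  expect_error(sex_difference(fit_m, fit_g), "different families")
})
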