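test_that("APE, CV and agreement match hand-computed values", {
  # fish A reads (2,3): mean 2.5, per-fish APE 20%, CV 28.284%
  # fish B reads (5,5): 0 for both; dataset means 10% and 14.142%
  expect_equal(ape(reads_toy), 10, tolerance = 1e-9)
  expect_equal(cv_reads(reads_toy), 100 * sqrt(2) / 2 / 5, tolerance = 1e-9)
  expect_equal(percent_agreement(reads_toy, 0), 50)
  expect_equal(percent_agreement(reads_toy, 1), 100)
  ident <- data.frame(read1 = c(1, 4, 7), read2 = c(1, 4, 7))
  expect_equal(ape(ident), 0)
  expect_equal(cv_reads(ident), 0)
})

test_that("CV equals sqrt(2) x APE for two reading sessions", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    r1 <- sample(0:11, n, replace = TRUE)
    rm <- data.frame(read1 = r1,
                     read2 = pmax(r1 + sample(-1:1, n, replace = TRUE), 0))
    if (all(rowMeans(rm) == 0)) next
    expect_equal(cv_reads(rm), sqrt(2) * ape(rm), tolerance = 1e-12)
  }
})

test_that("precision statistics are invariant to fish order and improve
           with perfect reads", {
  set.seed(3)
  rm <- data.frame(read1 = sample(0:10, 30, replace = TRUE))
  rm$read2 <- pmax(rm$read1 + sample(-1:1, 30, replace = TRUE), 0)
  perm <- rm[sample(nrow(rm)), ]
  expect_equal(ape(perm), ape(rm))
  expect_equal(cv_reads(perm), cv_reads(rm))
  expect_equal(percent_agreement(perm, 0), percent_agreement(rm, 0))
  # adding a fish with identical reads can only lower APE/CV
  more <- rbind(rm, data.frame(read1 = 6, read2 = 6))
  expect_lte(ape(more), ape(rm))
  expect_lte(cv_reads(more), cv_reads(rm))
})

test_that("degenerate read sets are signalled", {
  allzero <- data.frame(read1 = c(0, 0), read2 = c(0, 0))
  expect_error(ape(allzero), "mean read 0")
  expect_error(cv_reads(allzero), "mean read 0")
  expect_error(ape(data.frame(read1 = 1:3)), "at least 2")
  expect_error(ape(data.frame(read1 = c(-1, 2), read2 = c(1, 2))))
  # zero-mean fish are excluded from APE/CV but counted in agreement
  mixed <- data.frame(read1 = c(0, 2), read2 = c(0, 3))
  expect_equal(ape(mixed), 20)
  expect_equal(percent_agreement(mixed, 0), 50)
})

test_that("age-bias rows carry the right tests and flags", {
  # ref age 4 with nonref {3,4,5,4}: mean 4, t = 0, p = 1
  rm <- data.frame(read1 = c(3, 4, 5, 4), read2 = c(4, 4, 4, 4))
  ab <- age_bias(rm)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$mean_nonref, 4)
  expect_equal(ab$t_stat, 0)
  expect_equal(ab$p_value, 1)
  expect_true(ab$ci_lwr <= 4 && ab$ci_upr >= 4)
  # identical reads: zero variance, no test, note says why
  same <- data.frame(read1 = c(2, 2, 5), read2 = c(2, 2, 5))
  ab2 <- age_bias(same)
  expect_true(all(is.na(ab2$p_value)))
  expect_match(ab2$note[1], "zero variance")
  # single fish at a reference age: no test
  ab3 <- age_bias(data.frame(read1 = c(1, 3, 4), read2 = c(2, 2, 7)))
  expect_true(all(is.na(ab3$p_value[ab3$n == 1])))
})

test_that("unbiased read error yields near-nominal age-bias rejections", {
  set.seed(11)
  sig <- 0; rows <- 0
  for (r in 1:60) {
    true_age <- sample(1:10, 120, replace = TRUE)
    err <- stats::rbinom(120, 1, 0.2) * sample(c(-1, 1), 120, replace = TRUE)
    ab <- age_bias(data.frame(read1 = pmax(true_age + err, 0),
                              read2 = true_age))
    ok <- !is.na(ab$p_value)
    sig <- sig + sum(ab$p_value[ok] < 0.05)
    rows <- rows + sum(ok)
  }
  # discreteness makes the one-sample t slightly conservative; the
  # rejection rate should sit near (and not above ~2x) the nominal 5%
  expect_gt(rows, 300)
  expect_lt(sig / rows, 0.10)
})

test_that("third-read adjudication resolves or excludes disagreements", {
  rm <- data.frame(read1 = c(3, 3, 3, 5), read2 = c(3, 4, 4, 6),
                   read3 = c(NA, 4, 5, 9))
  expect_identical(adjudicate_reads(rm), c(3L, 4L, NA_integer_, NA_integer_))
  # without a third read, only agreements are accepted
  expect_identical(adjudicate_reads(rm[, 1:2]),
                   c(3L, NA_integer_, NA_integer_, NA_integer_))
})

test_that("the precision report bundles all statistics", {
  pr <- precision_report(reads_toy)
  expect_s3_class(pr, "precision_report")
  expect_equal(pr$ape_percent, 10, tolerance = 1e-9)
  expect_equal(pr$pct_agree_within_1, 100)
  expect_equal(pr$n_fish, 2)
  expect_output(print(pr), "APE 10.00%")
})
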