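test_that("compute_hscore covers the range and the reported cut value", {
  expect_equal(compute_hscore(3, 100)$h, 300)
  expect_equal(compute_hscore(0, 80)$h, 0)
  expect_equal(compute_hscore(2, 49)$h, 98)
  expect_error(compute_hscore(4, 50), "intensity")
  expect_error(compute_hscore(2, 101), "pct_positive")
})

test_that("hf_quantile implements the median-unbiased definition", {
  # h = (4 + 1/3) * 0.25 + 1/3 = 1.41667 -> between x(1)=1 and x(2)=2
  expect_equal(hf_quantile(c(1, 2, 3, 4), 0.25),
               1 + ((4 + 1 / 3) * 0.25 + 1 / 3 - 1) * 1, tolerance = 1e-12)
  expect_equal(hf_quantile(rep(7, 5), 0.33), 7)
  expect_equal(hf_quantile(c(3, 1, 9), 0), 1)
  expect_equal(hf_quantile(c(3, 1, 9), 1), 9)
  expect_error(hf_quantile(numeric(), 0.5), "empty")
  # equals the sample median for odd n, and stats::quantile type 8
  set.seed(16)
  for (i in 1:10) {
    x <- rnorm(2 * sample(3:15, 1) + 1)
    expect_equal(hf_quantile(x, 0.5), median(x), tolerance = 1e-12)
    for (p in c(0.1, 0.25, 0.5, 0.9))
      expect_equal(hf_quantile(x, p),
                   unname(stats::quantile(x, p, type = 8)),
                   tolerance = 1e-12)
  }
})

test_that("dichotomize_first_quartile puts the boundary in the low group", {
  d <- dichotomize_first_quartile(c(0, 98, 150, 300))
  expect_equal(levels(d$group), c("low", "high"))
  expect_equal(d$cut, hf_quantile(c(0, 98, 150, 300), 0.25))
  # a score exactly at the cut is labelled low
  sc <- c(10, 98, 98, 200, 250, 300, 120, 98)
  d2 <- dichotomize_first_quartile(sc)
  expect_true(all(d2$group[sc <= d2$cut] == "low"))
  expect_warning(dichotomize_first_quartile(rep(5, 6)), "degenerate")
  expect_error(dichotomize_first_quartile(1:3), ">= 4")
  set.seed(17)
  h <- sample(0:300, 104, replace = TRUE)
  d3 <- dichotomize_first_quartile(h)
  expect_lte(abs(sum(d3$group == "low") - 26), 3)  # quartile arithmetic
})

test_that("km_estimate reproduces hand products and honours censoring", {
  rec <- survival_records(c("a", "b", "c"), c(1, 2, 3), c(TRUE, FALSE, TRUE))
  km <- km_estimate(rec)
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  # all censored: no event rows, survival stays 1 throughout
  expect_equal(nrow(km_estimate(
    survival_records(letters[1:4], 1:4, rep(FALSE, 4)))), 0L)
  expect_error(km_estimate(survival_records("a", -1, TRUE)), "positive")
  expect_true(all(diff(km$survival) <= 0))
})

test_that("km equals 1 - ECDF without censoring and matches survfit", {
  skip_if_not_installed("survival")
  set.seed(18)
  tm <- round(rexp(20, 0.1), 3)
  rec <- survival_records(sprintf("s%02d", 1:20), tm, rep(TRUE, 20))
  km <- km_estimate(rec)
  ec <- stats::ecdf(tm)
  expect_equal(km$survival, 1 - ec(km$time), tolerance = 1e-12)
  # oracle: survival::survfit with log-log CI
  rec2 <- random_surv(40, beta = 0.5)
  km2 <- km_estimate(rec2)
  sf <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = rec2, conf.type = "log-log")
  sm <- summary(sf, times = km2$time)
  expect_equal(km2$survival, sm$surv, tolerance = 1e-9)
  expect_equal(km2$ci_low, sm$lower, tolerance = 1e-6)
  expect_equal(km2$ci_high, sm$upper, tolerance = 1e-6)
  expect_true(all(km2$ci_low <= km2$survival & km2$survival <= km2$ci_high,
                  na.rm = TRUE))
})

test_that("logrank_test: symmetry, oracle agreement", {
  skip_if_not_installed("survival")
  set.seed(19)
  rec <- random_surv(30, beta = 1)
  lr_same <- logrank_test(rec, rec)
  expect_equal(lr_same$chi2, 0, tolerance = 1e-12)
  expect_equal(lr_same$p, 1)
  set.seed(19)
  for (i in 1:10) {
    r <- random_surv(60, beta = 0.8)
    lr <- logrank_test(r[r$x == 0, ], r[r$x == 1, ])
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ x, data = r)
    expect_equal(lr$chi2, sd_$chisq, tolerance = 1e-9)
  }
  expect_error(logrank_test(rec[0, ], rec), "empty")
})

test_that("optimal_cutpoint scans inside the range and bounds its p", {
  set.seed(20)
  # two distinct score values: the only candidate cut is the lower value
  rec <- random_surv(40, beta = 1.5)
  sc <- ifelse(rec$x == 1, 0.8, 0.2)
  oc <- optimal_cutpoint(sc, rec, range = c(0.05, 0.95))
  expect_equal(oc$cut, 0.2)
  expect_error(optimal_cutpoint(rep(1, 40), rec), "constant")
  expect_error(optimal_cutpoint(sc, rec, range = c(0, 0.9)), "range")
  # naive p is never above the permutation-adjusted p
  for (s in 1:4) {
    sp <- synthetic_spec(seed = s, hr = 2)
    sv <- gen_survival(40, sp, score_link = "step")
    oc2 <- optimal_cutpoint(sv$scores, sv$records, n_perm = 49, seed = s)
    expect_lte(oc2$p_naive, oc2$p_adjusted + 1e-12)
  }
})

test_that("cox_ph matches survival::coxph with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(22)
  for (i in 1:8) {
    rec <- random_surv(80, beta = 0.7)
    rec$time <- round(rec$time, 0) + 0.5   # force ties
    rec$z <- rnorm(80)
    fit <- cox_ph(rec, c("x", "z"))
    ref <- survival::coxph(survival::Surv(time, event) ~ x + z, data = rec,
                           ties = "efron")
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("cox_ph symmetry, score/log-rank identity, degenerate input", {
  # identical event patterns in both groups -> beta = 0
  base <- survival_records(sprintf("a%d", 1:6), c(1, 2, 3, 4, 5, 6),
                           c(1, 1, 0, 1, 0, 1))
  both <- rbind(base, base)
  both$subject_id <- sprintf("s%d", 1:12)
  both$g <- rep(c(0, 1), each = 6)
  fit <- cox_ph(both, "g")
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_error(cox_ph(transform(base, k = 1), "k"), "constant")
  # score test == log-rank chi2 for a binary covariate without ties
  set.seed(23)
  for (i in 1:10) {
    rec <- random_surv(50, beta = 0.5)
    fit <- cox_ph(rec, "x")
    lr <- logrank_test(rec[rec$x == 0, ], rec[rec$x == 1, ])
    expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-6)
  }
})
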