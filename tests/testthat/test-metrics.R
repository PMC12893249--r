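test_that("detection metrics agree with brute-force confusion counting", {
  ## hand-checked example
  pred <- c(rep(1, 9), rep(0, 1), rep(0, 90), rep(1, 10))
  truth <- c(rep(1, 10), rep(0, 100))
  dm <- detection_metrics(pred, truth)
  expect_equal(dm$sensitivity, 0.9)
  expect_equal(dm$specificity, 0.9)
  expect_equal(dm$npv, 90 / 91)
  ## randomized equivalence against an independent counting loop
  set.seed(8)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    pr <- sample(0:1, n, replace = TRUE)
    tr <- sample(0:1, n, replace = TRUE)
    dm <- detection_metrics(pr, tr)
    tp <- fp <- tn <- fn <- 0
    for (j in seq_len(n)) {
      if (pr[j] == 1 && tr[j] == 1) tp <- tp + 1
      if (pr[j] == 1 && tr[j] == 0) fp <- fp + 1
      if (pr[j] == 0 && tr[j] == 0) tn <- tn + 1
      if (pr[j] == 0 && tr[j] == 1) fn <- fn + 1
    }
    expect_equal(c(dm$tp, dm$fp, dm$tn, dm$fn), c(tp, fp, tn, fn))
    if (tp + fn > 0) expect_equal(dm$sensitivity, tp / (tp + fn))
    else expect_true(is.na(dm$sensitivity))
  }
  ## degenerate cases: flagged missing, never silently zero
  expect_true(is.na(detection_metrics(c(0, 0), c(0, 0))$sensitivity))
  d2 <- detection_metrics(c(0, 0, 0), c(1, 0, 0))
  expect_equal(d2$sensitivity, 0)
  expect_equal(d2$specificity, 1)
  perfect <- detection_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
})

test_that("false-positive rate per minute divides correctly", {
  expect_equal(fp_rate_per_min(0, 20), 0)
  expect_equal(fp_rate_per_min(56, 20), 2.8)
  expect_equal(fp_rate_per_min(10, 4), 2.5)
  expect_error(fp_rate_per_min(1, 0), class = "spikeloop_invalid_configuration")
})

test_that("RT prolongation is the difference of state means", {
  expect_equal(delta_rt(c(600, 620), c(600, 620)), 0)
  ## session-level worked example: mean normal 587.7, mean IED 607.7
  expect_equal(delta_rt(c(607.7), c(587.7)), 20.0)
  expect_true(is.na(delta_rt(numeric(0), c(500))))
  expect_equal(delta_rt(c(NA, 650), c(550, NA)), 100)
})

test_that("crash probabilities reproduce the published worked examples", {
  ## 5 crashes among 17 bursts -> 29.4%; adjusted by 1.9% baseline -> 27.5
  cp <- crash_probabilities(5, 17, 2, 106)
  expect_equal(round(cp$p_ied_pct, 1), 29.4)
  expect_equal(round(cp$p_ied_pct - 1.9, 1), 27.5)
  ## zero crashes everywhere
  cp0 <- crash_probabilities(0, 10, 0, 50)
  expect_equal(cp0$p_ied_pct, 0)
  expect_equal(cp0$p_normal_pct, 0)
  expect_equal(cp0$p_due_ied_pct, 0)
  ## negative adjusted probability is preserved (0% IED vs 2.9% normal)
  cpn <- crash_probabilities(0, 11, 1, 34.5)
  expect_lt(cpn$p_due_ied_pct, 0)
  expect_equal(round(cpn$p_due_ied_pct, 1), -2.9)
  ## adjustment identity: p_due + p_normal == p_ied
  set.seed(3)
  for (i in 1:50) {
    cpx <- crash_probabilities(sample(0:5, 1), sample(1:50, 1),
                               sample(0:5, 1), sample(1:50, 1))
    expect_equal(cpx$p_due_ied_pct + cpx$p_normal_pct, cpx$p_ied_pct)
  }
  expect_true(is.na(crash_probabilities(0, 0, 0, 10)$p_ied_pct))
})

test_that("risk curve passes through its anchors and increases", {
  expect_equal(cumulative_crash_risk(100), 20, tolerance = 1e-6)
  expect_equal(cumulative_crash_risk(150), 50, tolerance = 1e-6)
  grid <- seq(0, 300, by = 5)
  risks <- cumulative_crash_risk(grid)
  expect_true(all(diff(risks) > 0))
  expect_lt(cumulative_crash_risk(0), 5)
  expect_error(cumulative_crash_risk(100, params = list()),
               class = "spikeloop_invalid_configuration")
  ## custom anchors are honored
  rc <- risk_curve(cbind(c(50, 100), c(0.1, 0.4)))
  expect_equal(cumulative_crash_risk(50, rc), 10, tolerance = 1e-6)
})

test_that("cognitive-probe percentages reproduce the published cells", {
  ## 1 incorrect / 12 bursts -> 8.3%
  ip <- iart_probabilities(1, 1, 12, 0, 0, 33)
  expect_equal(round(ip$p_incorrect_ied_pct, 1), 8.3)
  expect_equal(round(ip$p_incorrect_due_ied_pct, 1), 8.3)
  ## 2 incorrect / 28 bursts -> 7.1%
  ip2 <- iart_probabilities(2, 0, 28, 0, 0, 32)
  expect_equal(round(ip2$p_incorrect_ied_pct, 1), 7.1)
  ip0 <- iart_probabilities(0, 0, 10, 0, 0, 10)
  expect_true(all(unlist(ip0) == 0))
  expect_true(is.na(iart_probabilities(1, 0, 0, 0, 0, 10)$p_incorrect_ied_pct))
})

test_that("R-squared matches closed forms and the null distribution", {
  x <- 1:10
  expect_equal(correlate_r2(x, 2 * x), 1)
  expect_true(is.na(correlate_r2(x, rep(1, 10))))
  expect_error(correlate_r2(1:2, 1:2), class = "spikeloop_input")
  ## pairwise-complete deletion
  expect_equal(correlate_r2(c(x, NA), c(2 * x, 5)), 1)
  ## independent pairs: mean R^2 ~ 1/(n-1)
  set.seed(12)
  r2 <- replicate(1000, correlate_r2(rnorm(18), rnorm(18)))
  expect_equal(mean(r2), 1 / 17, tolerance = 0.15)
})

test_that("paired Wilcoxon uses the exact distribution for small n", {
  a <- 1:10 + 1
  b <- 1:10
  w <- paired_wilcoxon(a + (1:10) / 100, b)  # untied positive differences
  expect_equal(w$p_value, 2 / 2^10, tolerance = 1e-10)
  expect_equal(w$statistic, 55)
  ## all-zero differences -> missing
  w0 <- paired_wilcoxon(1:5, 1:5)
  expect_true(is.na(w0$p_value))
  ## exact enumeration oracle at n = 6: all 2^6 sign patterns
  d <- c(1.2, 2.3, 0.7, 3.1, 1.9, 0.4)
  v_obs <- sum(rank(abs(d))[d > 0])
  signs <- expand.grid(rep(list(c(-1, 1)), 6))
  v_all <- apply(signs, 1, function(s) sum(rank(abs(d))[s > 0]))
  p_exact <- mean(v_all >= v_obs) * 2  # one-sided doubled, all positive here
  w6 <- paired_wilcoxon(d + 10, rep(10, 6))
  expect_equal(w6$p_value, min(1, p_exact), tolerance = 1e-10)
})

test_that("signed-rank test holds its nominal size under the null", {
  set.seed(14)
  rej <- replicate(2000, {
    a <- rnorm(12)
    b <- rnorm(12)
    paired_wilcoxon(a, b)$p_value < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.35)
})

test_that("median CI reproduces the order-statistic construction", {
  ## n = 18 -> 5th and 14th order statistics
  x <- c(4.7, 10.4, 18.3, 20.0, 20.3, 29.5, 32.3, 36.9, 39.2, 48.3, 56.5,
         59.7, 60.7, 64.7, 71.4, 78.4, 105.1, 135.1)
  ci <- median_ci(x)
  expect_equal(unname(ci["median"]), 43.75)
  expect_equal(unname(ci["ci_low"]), 20.3)
  expect_equal(unname(ci["ci_high"]), 64.7)
  ## coverage sanity: l chosen so pbinom(l-1, n, .5) <= .025
  for (n in c(6, 10, 13, 14, 18, 19, 25)) {
    xs <- sort(rnorm(n))
    ci <- median_ci(xs)
    l <- match(ci["ci_low"], xs)
    expect_lte(stats::pbinom(l - 1, n, 0.5), 0.025)
    expect_gt(stats::pbinom(l, n, 0.5), 0.025)
  }
  expect_true(is.na(median_ci(rnorm(4))["ci_low"]))
})

test_that("delta-RT recovery is unbiased at the tested magnitudes", {
  rec <- delta_rt_recovery(deltas = c(20, 60), n_trials = 100, n_seeds = 8,
                           seed = 2)
  expect_true(all(abs(rec$bias_ms) < 12))
  expect_true(all(rec$rmse_ms < 25))
})
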