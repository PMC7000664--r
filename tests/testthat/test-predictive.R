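poor_marker <- function() binary_marker(
  "toy-poor", function(d) d$flag == 1, "predicts_event")

pv_cohort <- function(time, event, flag = 1) {
  n <- length(time)
  data.frame(flag = rep_len(flag, n),
             os_time = time, os_event = event,
             pfs_time = time, pfs_event = event)
}

test_that("with no censoring before t, PPV(t) is the binomial proportion", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    t <- stats::rexp(n, 0.15)
    co <- pv_cohort(t, rep(1, n))
    h <- stats::runif(1, 1, 15)
    if (!any(t >= h)) next
    pv <- time_dependent_ppv(co, poor_marker(), h)
    expect_equal(pv$value, mean(t <= h), tolerance = 1e-12)
  }
})

test_that("degenerate inputs yield inestimable results, not crashes", {
  co <- pv_cohort(c(1, 2, 3), c(1, 1, 1))
  # everyone positive, horizon beyond last event, all events observed
  pv <- time_dependent_ppv(co, poor_marker(), 10)
  expect_equal(pv$value, 1)
  # empty positive set
  co0 <- pv_cohort(c(1, 2), c(1, 1), flag = 0)
  pv0 <- time_dependent_ppv(co0, poor_marker(), 6)
  expect_false(pv0$estimable)
  expect_match(pv0$reason, "empty")
  # censored before horizon with S still positive: nobody at risk
  co1 <- pv_cohort(c(1, 2), c(0, 0))
  pv1 <- time_dependent_ppv(co1, poor_marker(), 6)
  expect_false(pv1$estimable)
  expect_match(pv1$reason, "at risk")
  expect_error(time_dependent_ppv(co, poor_marker(), -1), "positive")
})

test_that("NPV is the within-group survival; PPV + NPV complement", {
  co <- pv_cohort(c(2, 4, 6, 8), c(1, 0, 1, 0))
  good <- binary_marker("toy-good", function(d) d$flag == 1,
                        "predicts_survival")
  npv <- time_dependent_npv(co, good, 5)
  ppv <- time_dependent_ppv(co, poor_marker(), 5)
  expect_equal(npv$value + ppv$value, 1, tolerance = 1e-12)
  # zero events: NPV 1 before last censoring
  co2 <- pv_cohort(c(5, 7, 9), c(0, 0, 0))
  expect_equal(time_dependent_npv(co2, good, 4)$value, 1)
})

test_that("closed-form exponential truth is recovered at n = 2000", {
  set.seed(71)
  s <- sim_exp_censored(2000, 4.5, cens_range = c(12, 26))
  pv <- time_dependent_ppv(pv_cohort(s$time, s$event), poor_marker(), 12)
  expect_lt(abs(pv$value - (1 - exp(-12 * log(2) / 4.5))), 0.03)
  expect_true(pv$ci_lower <= pv$value && pv$value <= pv$ci_upper)
  s2 <- sim_exp_censored(2000, 23, cens_range = c(12, 26))
  good <- binary_marker("g", function(d) d$flag == 1, "predicts_survival")
  npv <- time_dependent_npv(pv_cohort(s2$time, s2$event), good, 12)
  expect_lt(abs(npv$value - exp(-12 * log(2) / 23)), 0.03)
})

test_that("PPV is non-decreasing in the horizon", {
  set.seed(81)
  s <- sim_exp_censored(300, 8)
  co <- pv_cohort(s$time, s$event)
  vals <- vapply(c(3, 6, 9, 12, 18), function(h)
    time_dependent_ppv(co, poor_marker(), h)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("fast product-limit evaluator agrees with survfit", {
  set.seed(91)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    t <- round(stats::rexp(n, 0.2), sample(0:1, 1))
    e <- stats::rbinom(n, 1, 0.7)
    h <- stats::runif(1, 0.5, 10)
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    sm <- summary(fit, times = h, extend = TRUE)
    ours <- isend:::.km_surv_at(t, e, h)
    if (sm$n.risk < 1 && min(fit$surv) > 0) {
      expect_true(is.na(ours))
    } else {
      expect_equal(ours, sm$surv, tolerance = 1e-12)
    }
  }
})

test_that("comparing a marker with itself gives difference 0, p ~ 1", {
  set.seed(103)
  s <- sim_exp_censored(120, 6)
  co <- pv_cohort(s$time, s$event)
  cm <- compare_markers(co, poor_marker(), poor_marker(), 6,
                        B = 200, seed = 5)
  expect_equal(cm$difference, 0)
  expect_equal(cm$p_value, 1)
})

test_that("marker comparison is symmetric and seed-reproducible", {
  set.seed(107)
  n <- 150
  co <- pv_cohort(c(stats::rexp(75, log(2) / 4), stats::rexp(75, log(2) / 12)),
                  rep(1, n), flag = rep(c(1, 0), each = 75))
  other <- binary_marker("neg", function(d) d$flag == 0, "predicts_event")
  ab <- compare_markers(co, poor_marker(), other, 6, B = 300, seed = 11)
  ba <- compare_markers(co, other, poor_marker(), 6, B = 300, seed = 11)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  again <- compare_markers(co, poor_marker(), other, 6, B = 300, seed = 11)
  expect_identical(ab$p_value, again$p_value)
  expect_identical(ab$se_boot, again$se_boot)
  # the bootstrap restores the caller's RNG state
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(compare_markers(co, poor_marker(), other, 6,
                                         B = 50, seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("comparison table spans horizons and records estimability", {
  set.seed(113)
  n <- 160
  co <- pv_cohort(c(stats::rexp(80, log(2) / 4), stats::rexp(80, log(2) / 14)),
                  rep(1, n), flag = rep(c(1, 0), each = 80))
  other <- binary_marker("neg", function(d) d$flag == 0, "predicts_event")
  tab <- compare_markers_table(co, poor_marker(), other,
                               horizons = c(6, 12), B = 200, seed = 2)
  expect_equal(tab$horizon, c(6, 12))
  expect_true(all(tab$estimable))
  expect_equal(tab$difference, tab$value_a - tab$value_b, tolerance = 1e-12)
})
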