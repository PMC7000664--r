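# Independent oracles used below:
#  - hand product-limit arithmetic on tiny datasets,
#  - 1 - ECDF identity on censoring-free data,
#  - exhaustive label-permutation for the log-rank test,
#  - a written-out Cox partial likelihood maximised by stats::optimize.

test_that("KM on censoring-free data equals 1 - ECDF (property, 1000 cases)", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    t <- round(stats::rexp(n, 0.1), sample(0:2, 1))  # induces ties
    cv <- km_curve(t, rep(1, n))
    ecdf_t <- stats::ecdf(t)
    expect_equal(cv$surv, 1 - ecdf_t(cv$time), tolerance = 1e-12)
  }
})

test_that("product-limit arithmetic matches hand computation with censoring", {
  # times {1, 2+, 3}: S = 2/3 after t=1, then 2/3 * (1 - 1/1) = 0 after t=3
  cv <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv$time, c(1, 3))
  expect_equal(cv$surv, c(2 / 3, 0))
  expect_equal(cv$n_risk, c(3, 1))
  # no-censoring staircase {1..5}
  cv2 <- km_curve(1:5, rep(1, 5))
  expect_equal(cv2$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(median_survival(cv2)$median, 3)
  # all censored: S identically 1, zero event rows, median not reached
  cv3 <- km_curve(c(1, 2), c(0, 0))
  expect_equal(nrow(cv3), 0)
  expect_true(is.na(median_survival(cv3)$median))
  # ties: events processed before censorings at the same time
  cv4 <- km_curve(c(2, 2, 2, 5), c(1, 1, 0, 1))
  expect_equal(cv4$surv[1], 1 - 2 / 4)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("Greenwood variance matches the written-out formula", {
  set.seed(5)
  s <- sim_exp_censored(60, 10)
  cv <- km_curve(s$time, s$event)
  gw <- cv$surv^2 * cumsum(cv$n_event /
                             (cv$n_risk * (cv$n_risk - cv$n_event)))
  expect_equal(cv$greenwood_var, gw, tolerance = 1e-10)
  # bands contain the point estimate
  expect_true(all(cv$lower <= cv$surv + 1e-12 & cv$surv <= cv$upper + 1e-12))
})

test_that("median estimate recovers the generating exponential median", {
  set.seed(31)
  s <- sim_exp_censored(5000, 4.5, cens_range = c(4, 40))  # ~20% censoring
  m <- median_survival(km_curve(s$time, s$event))
  expect_gt(m$median, 4.2)
  expect_lt(m$median, 4.8)
  expect_true(m$ci_lower <= m$median && m$median <= m$ci_upper)
})

test_that("reverse KM recovers the follow-up distribution", {
  # all events observed: no censoring 'events' for the reversed curve
  m0 <- reverse_km_followup(1:5, rep(1, 5))
  expect_true(is.na(m0$median))
  # all censored: plain KM median of the times
  m1 <- reverse_km_followup(c(1, 2, 3), c(0, 0, 0))
  expect_equal(m1$median, 2)
  # rare events, administrative censoring uniform(12, 24): median ~ 18
  set.seed(77)
  n <- 3000
  ev_t <- stats::rexp(n, log(2) / 200)     # rare deaths
  cs_t <- stats::runif(n, 12, 24)
  m2 <- reverse_km_followup(pmin(ev_t, cs_t), as.integer(ev_t <= cs_t))
  expect_true(m2$ci_lower <= 18 && 18 <= m2$ci_upper)
  expect_equal(m2$median, 18, tolerance = 0.05)
})

test_that("log-rank: identical groups give statistic 0, p = 1", {
  t <- c(1, 3, 5, 7); e <- c(1, 1, 0, 1)
  lr <- log_rank(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1)
  expect_error(log_rank(t, e, rep("a", 4)), "2 non-empty")
})

# log-rank numerator/statistic from the written-out formula
logrank_stat_2g <- function(time, event, g1) {
  dt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (d in dt) {
    n <- sum(time >= d); n1 <- sum(time >= d & g1)
    dtot <- sum(time == d & event == 1)
    d1 <- sum(time == d & event == 1 & g1)
    o_minus_e <- o_minus_e + (d1 - dtot * n1 / n)
    if (n > 1)
      v <- v + dtot * (n1 / n) * (1 - n1 / n) * (n - dtot) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("log-rank agrees with a hand implementation and a permutation oracle", {
  set.seed(55)
  t <- c(2, 4, 4, 7, 9, 12, 13, 20)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g <- rep(c(TRUE, FALSE), 4)
  lr <- log_rank(t, e, ifelse(g, "a", "b"))
  expect_equal(lr$statistic, logrank_stat_2g(t, e, g), tolerance = 1e-8)
  # exhaustive permutation of labels: all C(8,4) = 70 assignments
  combs <- utils::combn(8, 4)
  perm_stats <- apply(combs, 2, function(idx) {
    gi <- seq_len(8) %in% idx
    logrank_stat_2g(t, e, gi)
  })
  p_perm <- mean(perm_stats >= lr$statistic - 1e-12)
  # asymptotic chi-square p vs exact permutation p: agreement is loose at
  # n = 8 (documented small-sample gap), but both must tell the same story
  expect_lt(abs(lr$p_value - p_perm), 0.15)
  expect_equal(lr$p_value > 0.05, p_perm > 0.05)
})

test_that("log-rank is invariant to group relabeling and time shifts", {
  set.seed(9)
  s <- sim_exp_censored(40, 8)
  g <- rep(c("x", "y"), 20)
  a <- log_rank(s$time, s$event, g)
  b <- log_rank(s$time, s$event, ifelse(g == "x", "y", "x"))
  d <- log_rank(s$time + 7, s$event, g)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$statistic, d$statistic, tolerance = 1e-10)
})

test_that("log-rank has full power at the published median separation", {
  set.seed(13)
  meds <- c(23, 13.4, 4.5)
  t <- unlist(lapply(meds, function(m) stats::rexp(150, log(2) / m)))
  cs <- stats::runif(450, 10, 26)
  lr <- log_rank(pmin(t, cs), as.integer(t <= cs),
                 rep(c("good", "int", "poor"), each = 150))
  expect_equal(lr$df, 2)
  expect_lt(lr$p_value, 1e-4)
  expect_equal(format_p(lr$p_value), "< 1e-04")
})

test_that("Cox coefficient matches a brute-force partial-likelihood maximiser", {
  # 6 patients, single binary covariate, no ties
  t <- c(1, 3, 4, 6, 8, 10)
  e <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  # written-out log partial likelihood (Breslow = Efron without ties)
  pl <- function(beta) {
    ll <- 0
    for (i in which(e == 1)) {
      risk <- t >= t[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  oracle <- stats::optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  fit <- cox_ph(data.frame(x = x), t, e)
  expect_equal(fit$coef[1], oracle, tolerance = 1e-4)
  expect_equal(fit$hr[1], exp(fit$coef[1]))
  expect_equal(fit$ci_lower[1], exp(fit$coef[1] - qnorm(0.975) * fit$se[1]))
  # ascent property: solution beats the null
  expect_gte(attr(fit, "loglik"), attr(fit, "loglik0"))
  expect_true(attr(fit, "converged"))
})

test_that("constant covariates get coefficient 0 / HR 1, not silence", {
  t <- c(1, 3, 4, 6, 8, 10); e <- rep(1, 6)
  fit <- cox_ph(data.frame(zero = rep(0, 6), x = c(1, 0, 1, 1, 0, 0)), t, e)
  expect_equal(fit$coef[fit$term == "zero"], 0)
  expect_equal(fit$hr[fit$term == "zero"], 1)
  expect_match(paste(attr(fit, "flags"), collapse = ";"), "constant")
  expect_error(cox_ph(data.frame(x = c(NA, 1)), c(1, 2), c(1, 1)),
               "missing")
  expect_error(cox_ph(data.frame(x = c(0, 1)), c(1, 2), c(0, 0)),
               "at least one event")
})

test_that("complete separation is detected and flagged", {
  # covariate perfectly splits early events from late censorings
  t <- c(1, 2, 3, 50, 60, 70)
  e <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- suppressWarnings(cox_ph(data.frame(x = x), t, e))
  expect_match(paste(attr(fit, "flags"), collapse = ";"),
               "separation|converge")
})

test_that("Cox recovers generating hazard ratios (three binary covariates)", {
  set.seed(17)
  n <- 5000
  x1 <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rbinom(n, 1, 0.3)
  x3 <- stats::rbinom(n, 1, 0.2)
  true_hr <- c(1.2, 1.8, 1.8)
  rate <- (log(2) / 12) * true_hr[1]^x1 * true_hr[2]^x2 * true_hr[3]^x3
  t_ev <- stats::rexp(n, rate)
  cs <- stats::runif(n, 10, 26)
  fit <- cox_ph(data.frame(x1 = x1, x2 = x2, x3 = x3),
                pmin(t_ev, cs), as.integer(t_ev <= cs))
  expect_lt(max(abs(fit$hr - true_hr)), 0.15)
  # Wald p small for the strong effects
  expect_lt(fit$p_value[2], 1e-4)
})

test_that("km_by_group produces per-group medians and a joint test", {
  set.seed(23)
  t <- c(stats::rexp(80, log(2) / 20), stats::rexp(80, log(2) / 5))
  g <- rep(c("slow", "fast"), each = 80)
  res <- km_by_group(t, rep(1, 160), g)
  expect_setequal(res$medians$group, c("slow", "fast"))
  expect_lt(res$medians$median[res$medians$group == "fast"],
            res$medians$median[res$medians$group == "slow"])
  expect_lt(res$log_rank$p_value, 0.001)
})
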