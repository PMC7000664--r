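test_that("published cohort-comparison p-values reproduce from printed counts", {
  p <- function(m, excl = NULL) pearson_chi_square(m, exclude = excl)$p_value
  sex <- matrix(c(85, 74, 161, 119), 2,
                dimnames = list(c("male", "female"), c("tr", "va")))
  ecog <- matrix(c(125, 34, 232, 48), 2)
  path <- matrix(c(40, 119, 78, 202), 2)
  comp <- matrix(c(135, 24, 228, 52), 2)
  egfr <- matrix(c(0, 142, 17, 14, 237, 29), 3,
                 dimnames = list(c("unknown", "no", "yes"), c("tr", "va")))
  smoke <- matrix(c(2, 132, 25, 9, 220, 51), 3,
                  dimnames = list(c("unknown", "any", "never"), c("tr", "va")))
  expect_equal(round(p(sex), 4), 0.4123)
  expect_equal(round(p(ecog), 4), 0.2732)
  expect_equal(round(p(path), 4), 0.5397)
  expect_equal(round(p(comp), 4), 0.3547)
  expect_equal(round(p(egfr, "unknown"), 4), 0.9461)
  expect_equal(round(p(smoke, "unknown"), 2), 0.45)
  # including the unknown category would give a different answer (~0.34),
  # so exclusion is load-bearing, not cosmetic
  expect_false(round(p(smoke), 2) == 0.45)
})

test_that("chi-square basics: proportional table, invariances, margins", {
  prop <- matrix(c(10, 20, 20, 40), 2)
  r <- pearson_chi_square(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  m <- matrix(c(12, 5, 9, 14, 7, 3), 2)
  a <- pearson_chi_square(m)
  expect_equal(a$statistic, pearson_chi_square(t(m))$statistic)
  expect_equal(a$statistic,
               pearson_chi_square(m[, c(3, 1, 2)])$statistic)
  expect_equal(sum(a$expected), sum(m))
  expect_equal(a$df, 2)
  bad <- matrix(c(0, 5, 0, 7), 2, dimnames = list(c("z", "w"), NULL))
  expect_error(pearson_chi_square(bad), "zero margin.*z")
  expect_error(pearson_chi_square(matrix(c(1, 2), 1)), "at least 2")
})

test_that("rank-sum test matches exhaustive enumeration on a tiny case", {
  # oracle: enumerate all C(6,3) = 20 label assignments of {1..6}
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w_obs <- sum(rank(c(a, b))[1:3]) - 3 * 4 / 2   # Mann-Whitney U of sample a
  combs <- utils::combn(6, 3)
  pool <- c(a, b)
  u_all <- apply(combs, 2, function(idx)
    sum(rank(pool)[idx]) - 3 * 4 / 2)
  p_exact <- mean(abs(u_all - 4.5) >= abs(w_obs - 4.5))  # two-sided, U ~ sym at 4.5
  r <- wilcoxon_rank_sum(a, b)
  expect_equal(r$statistic, w_obs)
  expect_equal(r$p_value, p_exact)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
})

test_that("rank-sum edge cases and power", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r$p_value, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  set.seed(211)
  a <- stats::rnorm(200); b <- stats::rnorm(200, 1)   # 1-SD shift
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 0.001)
  # ties handled by mid-ranks + normal approximation
  rt <- wilcoxon_rank_sum(c(1, 1, 2, 2), c(2, 2, 3, 3))
  expect_false(rt$exact)
  expect_true(rt$p_value > 0 && rt$p_value < 1)
})

test_that("demographics fixture reproduces every published categorical cell", {
  fx <- make_table1_fixture()
  expect_equal(nrow(fx), 439)
  expect_equal(sum(fx$cohort == "training"), 159)
  expect_equal(sum(fx$cohort == "validation"), 280)
  expect_equal(sum(fx$sex == "male"), 246)
  expect_equal(sum(fx$sex == "female"), 193)
  h <- derive_haematology(fx)
  expect_equal(sum(h$composite_flag), 76)
  expect_equal(sum(h$composite_flag[fx$cohort == "training"]), 24)
  expect_equal(sum(h$composite_flag[fx$cohort == "validation"]), 52)
  expect_equal(sum(fx$smoking == "never"), 76)
  expect_equal(sum(fx$ecog >= 2), 82)
  expect_equal(sum(fx$histology == "squamous"), 118)
  expect_equal(sum(fx$egfr_alk == "yes"), 46)
  expect_equal(sum(fx$egfr_alk == "unknown"), 14)
})

test_that("table builder reproduces the published p-value column", {
  tab <- build_table1(make_table1_fixture())
  pv <- tab$categorical$p_value[!is.na(tab$categorical$p_value)]
  names(pv) <- unique(tab$categorical$variable)
  expect_equal(round(unname(pv["sex"]), 4), 0.4123)
  expect_equal(round(unname(pv["smoking"]), 2), 0.45)
  expect_equal(round(unname(pv["ecog_class"]), 4), 0.2732)
  expect_equal(round(unname(pv["histology"]), 4), 0.5397)
  expect_equal(round(unname(pv["egfr_alk"]), 4), 0.9461)
  expect_equal(round(unname(pv["composite"]), 4), 0.3547)
  expect_equal(unname(tab$n), c(439, 159, 280))
})

test_that("null calibration: identical cohorts rarely give extreme p-values", {
  # training/validation drawn from one distribution: categorical tests
  # should essentially never be extreme
  set.seed(307)
  n_extreme <- 0L
  for (i in 1:30) {
    co <- derive_haematology(
      generate_cohort(sim_config(n = 439, seed = 1000 + i)))
    tab <- build_table1(co)
    pv <- stats::na.omit(tab$categorical$p_value)
    if (any(pv < 0.001)) n_extreme <- n_extreme + 1L
  }
  expect_lte(n_extreme, 2)
})

test_that("single-cohort input yields pooled column only, no tests", {
  co <- derive_haematology(
    generate_cohort(sim_config(n = 200, seed = 19)))
  co$cohort <- "training"
  tab <- build_table1(co)
  expect_true(all(is.na(tab$categorical$p_value)))
  expect_true(all(is.na(tab$continuous$p_value)))
  expect_false("training_n" %in% names(tab$categorical))
})
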