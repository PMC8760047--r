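test_that("Welch t reproduces the published age comparison", {
  w <- welch_t(35.47, 12.63, 1601, 41.72, 12.66, 1134)
  expect_equal(bdbmi:::round_half_up(w$statistic, 2), 12.73)
  expect_equal(w$df_integer, 2436)
  expect_lt(w$p, 0.001)
})

test_that("Welch t degenerates to the Student df with equal variances and sizes", {
  w <- welch_t(10, 2, 30, 12, 2, 30)
  expect_equal(w$df, 58)
  # cross-check against the raw-data implementation on a simulated sample
  set.seed(1)
  x <- rnorm(25, 5, 2); y <- rnorm(35, 6, 3)
  w2 <- welch_t(mean(x), sd(x), 25, mean(y), sd(y), 35)
  ref <- t.test(y, x)
  expect_equal(w2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w2$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w2$p, ref$p.value, tolerance = 1e-10)
})

test_that("Welch t is antisymmetric under group swap; equal means give t = 0", {
  a <- welch_t(10, 2, 40, 12, 3, 50)
  b <- welch_t(12, 3, 50, 10, 2, 40)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p, b$p)
  expect_equal(welch_t(7, 1, 10, 7, 2, 12)$statistic, 0)
  expect_error(welch_t(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Pearson chi-square reproduces the published weight-category and sex tests", {
  weight <- rbind(control = c(1014, 437, 150), case = c(470, 399, 265))
  cw <- pearson_chi2(weight)
  # printed value 157.87; the counts give 157.8754
  expect_equal(cw$statistic, 157.87, tolerance = 0.01 / 157.87)
  expect_equal(cw$df, 2)
  expect_lt(cw$p, 0.001)
  sex <- rbind(control = c(916, 685), case = c(684, 450))
  cs <- pearson_chi2(sex)
  expect_equal(bdbmi:::round_half_up(cs$statistic, 2), 2.63)
  expect_equal(bdbmi:::round_half_up(cs$p, 3), 0.105)
})

test_that("chi-square matches the brute-force cell computation and is permutation invariant", {
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(sample(5:200, 4), 2, 2)
    expect_equal(pearson_chi2(tab)$statistic, chi2_bruteforce(tab),
                 tolerance = 1e-10)
    expect_equal(pearson_chi2(tab)$statistic,
                 pearson_chi2(tab[2:1, 2:1])$statistic, tolerance = 1e-12)
  }
  # independence built from the margins gives exactly zero
  ind <- outer(c(30, 70), c(20, 30, 50)) / 100
  expect_equal(pearson_chi2(ind)$statistic, 0, tolerance = 1e-12)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("BMI categorization uses inclusive WHO lower bounds", {
  expect_equal(unname(bmi_categorize(c(24.9, 25.0, 29.9, 30.0))), c(1L, 2L, 1L))
  expect_equal(unname(bmi_categorize(c(18, 20, 24))), c(3L, 0L, 0L))
  expect_error(bmi_categorize(c(22, -1)), "positive")
  # percentages of the published case counts
  counts <- c(normal = 470, overweight = 399, obese = 265)
  pct <- round(100 * counts / sum(counts), 2)
  expect_equal(unname(pct), c(41.45, 35.19, 23.37))
})

test_that("cohort_table1 summarises a generated cohort at subject level", {
  cohort <- generate_cohort(generator_config(n_sites = 4,
                                             subjects_per_site = 80,
                                             seed = 10))
  t1 <- cohort_table1(cohort)
  expect_setequal(t1$variable,
                  c("n", "age", "bmi", "weight_category", "sex_female"))
  n_row <- t1[t1$variable == "n", ]
  expect_equal(as.integer(n_row$control) + as.integer(n_row$case), 320L)
  expect_gt(t1$statistic[t1$variable == "bmi"], 0)  # cases heavier by design
})
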