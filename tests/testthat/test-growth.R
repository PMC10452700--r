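test_that("caliper volume reproduces the printed formula", {
  expect_equal(caliper_volume(2, 2), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(caliper_volume(6, 4), 20 * pi, tolerance = 1e-12)
  expect_equal(caliper_volume(0, 5), 0)
  expect_error(caliper_volume(-1, 2), ">= 0")
})

test_that("caliper volume is symmetric and cubic-homogeneous", {
  set.seed(2)
  L1 <- runif(200, 0, 20); L2 <- runif(200, 0, 20); k <- runif(200, 0.1, 3)
  expect_equal(caliper_volume(L1, L2), caliper_volume(L2, L1))
  expect_equal(caliper_volume(k * L1, k * L2), k^3 * caliper_volume(L1, L2))
})

test_that("percent change from baseline and its inverse round-trip", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 149.1), 49.1)
  expect_equal(percent_change(100, 67.8), -32.2)
  expect_error(percent_change(0, 1), "> 0")
  b <- 217.3
  pc <- percent_change(b, 350)
  expect_equal(b * (1 + pc / 100), 350, tolerance = 1e-9)
})

test_that("vehicle normalization divides by the vehicle-arm mean", {
  records <- data.frame(
    subject_id = rep(c("v1", "v2", "t1"), each = 2),
    arm = rep(c("vehicle", "vehicle", "treated"), each = 2),
    day = rep(c(0L, 6L), 3),
    L1 = 5, L2 = 5,
    volume = c(100, 140, 100, 160, 100, 125))
  tab <- cohort_table(records)
  norm <- normalize_to_vehicle(tab, "vehicle", day = 6L)
  # vehicle mean pct change = (40 + 60)/2 = 50; treated 25 -> 0.5
  expect_equal(norm$normalized[norm$subject_id == "t1"], 0.5)
  expect_equal(mean(norm$normalized[norm$arm == "vehicle"]), 1)

  flat <- records; flat$volume <- 100
  expect_error(normalize_to_vehicle(cohort_table(flat), "vehicle", 6L),
               "degenerate")
})

test_that("cohort_table enforces arm membership and per-day uniqueness", {
  rec <- data.frame(subject_id = "a", arm = "x", day = 0L, L1 = 2, L2 = 2)
  expect_error(cohort_table(rec, arms = "y"), "arm")
  dup <- rbind(rec, rec)
  expect_error(cohort_table(dup), "at most once per day")
  tab <- cohort_table(rec)
  expect_equal(tab$volume, caliper_volume(2, 2))
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_identical(mw$method, "exact")

  same <- mann_whitney(c(2, 5, 9), c(9, 2, 5))
  expect_equal(same$p_value, 1)

  set.seed(77)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    a <- runif(n1); b <- runif(n2)
    mw <- mann_whitney(a, b)
    oracle <- enum_mann_whitney(a, b)
    expect_equal(mw$U, oracle$U)
    expect_equal(mw$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximate branch matches the textbook formula", {
  set.seed(31)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  mw <- mann_whitney(a, b)
  expect_identical(mw$method, "normal_approx")
  expect_equal(mw$p_value, normal_mann_whitney_p(a, b), tolerance = 0.005)

  # ties force the approximation even in small samples
  tied <- mann_whitney(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_identical(tied$method, "normal_approx")
  expect_equal(tied$p_value,
               normal_mann_whitney_p(c(1, 2, 2, 3), c(2, 3, 4, 4)),
               tolerance = 0.005)
})

test_that("Grubbs test flags the extreme studentized deviate", {
  expect_true(is.na(grubbs_outlier(c(1, 2, 3))$outlier_index))

  g <- grubbs_outlier(c(1, 1, 1, 1, 10))
  expect_equal(g$outlier_index, 5L)
  expect_equal(g$G, 7.2 / sd(c(1, 1, 1, 1, 10)), tolerance = 1e-9)
  expect_equal(g$critical_value, 1.715, tolerance = 0.005)

  expect_error(grubbs_outlier(c(1, 2)), "at least 3")
  expect_error(grubbs_outlier(c(2, 2, 2, 2)), "zero sample SD")
})

test_that("Grubbs critical values reproduce published table entries", {
  gcrit <- function(n, alpha = 0.05) {
    t <- qt(1 - alpha / (2 * n), n - 2)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
  }
  # published two-sided alpha = 0.05 values
  expect_equal(gcrit(5), 1.715, tolerance = 0.005)
  expect_equal(gcrit(10), 2.290, tolerance = 0.005)
  expect_equal(grubbs_outlier(rnorm(10))$critical_value, gcrit(10),
               tolerance = 1e-9)
})

test_that("growth report summarizes arms and compares them pairwise", {
  tab <- generate_growth_cohort(seed = 10)
  rep <- growth_report(tab)
  expect_setequal(unique(rep$summary$arm),
                  c("vehicle", "trastuzumab", "niraparib", "combination"))
  expect_equal(nrow(rep$comparisons), 6 * 6)  # 6 days x C(4,2) pairs
  expect_true(all(rep$comparisons$p_value >= 0 & rep$comparisons$p_value <= 1))

  single <- generate_growth_cohort(
    seed = 1, arms = data.frame(name = "only", mean_pct_change = 5,
                                sd_pct_change = 2))
  rep1 <- growth_report(single)
  expect_equal(nrow(rep1$comparisons), 0L)
  expect_gt(nrow(rep1$summary), 0L)
})

test_that("identical arms rarely differ; opposite arms separate by endpoint", {
  null_arms <- data.frame(name = c("a", "b"), mean_pct_change = c(10, 10),
                          sd_pct_change = c(10, 10))
  false_pos <- 0L; n_null <- 100L
  for (s in seq_len(n_null)) {
    tab <- generate_growth_cohort(seed = s, arms = null_arms,
                                  n_assessments = 3)
    rep <- growth_report(tab)
    final <- rep$comparisons[rep$comparisons$day == max(rep$comparisons$day), ]
    if (any(final$p_value < 0.05)) false_pos <- false_pos + 1L
  }
  expect_lte(false_pos / n_null, 0.10)

  effect_arms <- data.frame(name = c("vehicle", "combination"),
                            mean_pct_change = c(50, -10),
                            sd_pct_change = c(10, 10))
  hits <- 0L; n_eff <- 50L
  for (s in seq_len(n_eff)) {
    tab <- generate_growth_cohort(seed = 1000 + s, arms = effect_arms,
                                  n_assessments = 3)
    rep <- growth_report(tab)
    final <- rep$comparisons[rep$comparisons$day == max(rep$comparisons$day), ]
    if (all(final$p_value < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / n_eff, 0.90)
})

test_that("outlier screening drops a planted extreme point", {
  records <- data.frame(
    subject_id = rep(sprintf("s%d", 1:5), each = 2),
    arm = "a", day = rep(c(0L, 3L), 5), L1 = 3, L2 = 3,
    volume = c(100, 110, 100, 112, 100, 108, 100, 111, 100, 400))
  tab <- cohort_table(records)
  plain <- growth_report(tab)
  screened <- growth_report(tab, screen_outliers = TRUE)
  expect_equal(plain$summary$n, 5L)
  expect_equal(screened$summary$n, 4L)
  expect_lt(screened$summary$mean_pct_change, plain$summary$mean_pct_change)
})
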