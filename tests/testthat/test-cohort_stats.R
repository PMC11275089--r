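test_that("t tail probabilities are symmetric, monotone and validated", {
  expect_error(p_from_t(1, df = 0.5), "df")
  expect_equal(p_from_t(0, 24), 1)
  ts <- seq(0.2, 6, by = 0.4)
  for (df in c(1, 5, 24, 100)) {
    expect_equal(p_from_t(-ts, df), p_from_t(ts, df))
    expect_true(all(diff(p_from_t(ts, df)) < 0))
  }
})

test_that("t tail probabilities match numeric integration of the density", {
  for (df in c(1, 5, 24, 100)) {
    for (t in c(0, 0.5, 1, 2, 3, 6)) {
      expect_equal(p_from_t(t, df), oracle_p_from_t(t, df),
                   tolerance = 1e-6)
    }
  }
})

test_that("paired t test matches hand arithmetic and is shift invariant", {
  res <- paired_t(c(1, 2, 3, 4), c(1.5, 2.5, 2.5, 4.5))
  expect_equal(res$statistic, 1.0, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_two_sided, p_from_t(1, 3), tolerance = 1e-12)
  expect_false(res$significant)

  expect_error(paired_t(1:4, (1:4) + 2), "zero variance")
  expect_error(paired_t(1:4, 1:5), "equal length")

  set.seed(17)
  pre <- rnorm(20)
  post <- pre + rnorm(20, 0.3)
  r1 <- paired_t(pre, post)
  r2 <- paired_t(pre + 100, post + 100)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$p_two_sided, r2$p_two_sided, tolerance = 1e-9)
})

test_that("normality screen flags heavy departures and passes clean normals", {
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
  # perfectly linear normal-quantile sample scores W near 1
  q <- qnorm(((1:25) - 0.5) / 25)
  res <- shapiro_wilk(q)
  expect_gt(res$statistic, 0.99)
  # exponential samples are rejected in the large majority of seeds
  rejections <- vapply(1:40, function(s) {
    set.seed(s)
    shapiro_wilk(rexp(25))$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("rank-sum test returns exact enumeration results without ties", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_two_sided, 2 / 6, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # exchangeable inputs give p at (or within correction of) 1
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 0.9)
})

test_that("exact rank-sum branch equals exhaustive labeling enumeration", {
  set.seed(53)
  for (na in 1:7) {
    for (nb in 1:(8 - na)) {
      a <- rnorm(na)
      b <- rnorm(nb)
      got <- mann_whitney_u(a, b)
      expect_equal(got$p_two_sided, oracle_mw_exact(a, b),
                   tolerance = 1e-12,
                   label = sprintf("p for na=%d nb=%d", na, nb))
    }
  }
})

test_that("age imbalance between the arms is detected in nearly every cohort", {
  cfg <- cohort_config(seed = 1)
  hits <- vapply(1:100, function(i) {
    set.seed(6000 + i)
    a <- sample_baseline(cfg, "active", 25)$age
    p <- sample_baseline(cfg, "placebo", 25)$age
    mann_whitney_u(a, p)$p_two_sided < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("chi-square test matches hand-computed expectations", {
  null_tab <- matrix(c(10, 10, 10, 10), 2)
  res0 <- chi_square_test(null_tab)
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p_two_sided, 1)

  res <- chi_square_test(matrix(c(20, 5, 5, 20), 2))
  expect_equal(unname(res$statistic), 18) # 4 * (7.5^2 / 12.5)
  expect_equal(unname(res$df), 1)

  expect_error(chi_square_test(matrix(c(3, 4), 1)), "2 x 2")
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "expected")

  # invariance to row/column permutation
  set.seed(61)
  tab <- matrix(rpois(12, 8) + 1, 3, 4)
  perm <- chi_square_test(tab[c(2, 3, 1), c(4, 1, 3, 2)])
  expect_equal(perm$statistic, chi_square_test(tab)$statistic,
               tolerance = 1e-12)
})

test_that("p-value rendering follows report precision", {
  expect_equal(format_p(0.5874), "0.587")
  expect_equal(format_p(0.0010656), "0.0011")
  expect_equal(format_p(c(0.026, 0.0028)), c("0.026", "0.0028"))
})

test_that("baseline table assembles group summaries with the right tests", {
  cohort <- generate_cohort(cohort_config(seed = 12))
  bt <- baseline_table(cohort)
  expect_equal(bt$variable,
               c("bmi", "disease_duration", "mmse", "led", "age", "hy"))
  expect_equal(bt$test, c(rep("Mann-Whitney U", 5), "chi-square"))
  expect_true(all(bt$active_q25 <= bt$active_q75))
  expect_true(all(bt$placebo_q25 <= bt$placebo_q75))
  gc_ <- attr(bt, "gender_counts")
  expect_equal(gc_$male + gc_$female, c(25, 25))
  # the designed age imbalance dominates the baseline comparison
  expect_lt(bt$p_value[bt$variable == "age"], 0.01)

  # two identical arms: every between-group p is ~1
  half <- cohort[cohort$group == "active", ]
  twin <- rbind(half, transform(half, group = "placebo"))
  bt2 <- baseline_table(twin)
  expect_true(all(bt2$p_value > 0.9))

  expect_error(baseline_table(half), "both arms")
})

test_that("outcome report covers both arms, excludes P4 and flags at 0.05", {
  cohort <- generate_cohort(cohort_config(seed = 12))
  ot <- outcome_report(cohort)
  expect_setequal(unique(ot$group), c("active", "placebo"))
  params <- unique(ot$parameter)
  expect_false("p4" %in% params)
  expect_true("bbs" %in% params)
  expect_equal(sum(ot$parameter == "bbs"), 2)
  expect_equal(nrow(ot), 2 * 11)
  expect_equal(ot$significant, ot$p_value < 0.05)
  expect_equal(unique(ot$df), 24)
  expect_true(all(is.na(ot$shapiro_W[ot$parameter == "bbs"])))
  expect_true(all(ot$shapiro_W[ot$parameter != "bbs"] > 0 &
                    ot$shapiro_W[ot$parameter != "bbs"] <= 1))

  # Holm adjustment never lowers a p-value
  oth <- outcome_report(cohort, adjust = "holm")
  expect_true(all(oth$p_value >= ot$p_value - 1e-12))

  # normality screen can be switched to the raw pre/post values
  otp <- outcome_report(cohort, shapiro_on = "pre")
  expect_false(isTRUE(all.equal(otp$shapiro_W, ot$shapiro_W)))

  expect_error(outcome_report(cohort[cohort$group == "active", ]),
               "both arms")
})

test_that("report files are written as CSV plus aligned text", {
  cohort <- generate_cohort(cohort_config(seed = 12))
  bt <- baseline_table(cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(bt, path)
  expect_true(file.exists(path))
  txt <- sub("\\.csv$", ".txt", path)
  expect_true(file.exists(txt))
  expect_true(any(grepl("Gender", readLines(txt))))
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
})
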