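#' Test result container
#'
#' The atom of every report table: a named statistic, optional degrees of
#' freedom, a two-sided p-value and the significance flag at alpha = 0.05.
#'
#' @param test_name Character label of the test.
#' @param statistic Test statistic.
#' @param df Degrees of freedom, or `NA` where not applicable.
#' @param p_two_sided Two-sided p-value in \[0, 1\].
#' @return List of class `test_result` with fields `test_name`,
#'   `statistic`, `df`, `p_two_sided`, `significant`.
#' @export
test_result <- function(test_name, statistic, df = NA_real_, p_two_sided) {
  if (!is.numeric(p_two_sided) || length(p_two_sided) != 1L ||
      is.na(p_two_sided) || p_two_sided < 0 || p_two_sided > 1)
    stop("test_result: p_two_sided must be a single value in [0, 1]")
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_two_sided = unname(p_two_sided),
                 significant = p_two_sided < 0.05),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", format(x$df)) else "",
      ", p = ", format_p(x$p_two_sided),
      if (x$significant) " (significant at 0.05)" else "", "\n", sep = "")
  invisible(x)
}

#' Two-sided p-value from a t statistic
#'
#' `p = 2 * P(T_df > |t|)`: symmetric in the sign of `t` and strictly
#' decreasing in `|t|`.
#'
#' @param t t statistic (vectorized).
#' @param df Degrees of freedom, >= 1.
#' @return Two-sided p-value(s).
#' @examples
#' p_from_t(-3.72, 24) # 0.0011 to 4 decimals
#' @export
p_from_t <- function(t, df) {
  if (!is.numeric(df) || any(df < 1)) stop("p_from_t: df must be >= 1")
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("p_from_t: t must be finite numeric")
  2 * pt(-abs(t), df)
}

#' Paired t test on pre/post measurements
#'
#' Differences are `d = post - pre`; `t = mean(d) / (sd(d) / sqrt(n))`
#' with `df = n - 1` and a two-sided p.
#'
#' @param pre_values,post_values Numeric vectors of equal length n >= 2.
#' @return A [test_result()].
#' @examples
#' paired_t(c(1, 2, 3, 4), c(1.5, 2.5, 2.5, 4.5)) # t = 1, df = 3
#' @export
paired_t <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values))
    stop("paired_t: pre and post must have equal length")
  n <- length(pre_values)
  if (n < 2) stop("paired_t: need at least 2 pairs")
  d <- post_values - pre_values
  if (sd(d) == 0)
    stop("paired_t: degenerate input, differences have zero variance")
  ht <- t.test(post_values, pre_values, paired = TRUE)
  test_result("paired t-test", statistic = ht$statistic,
              df = ht$parameter, p_two_sided = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Delegates to the Royston-approximation routine of [stats::shapiro.test()]
#' after input validation.
#'
#' @param sample Numeric vector with 3 <= n <= 5000 and non-zero range.
#' @return A [test_result()] with the W statistic (`df = NA`).
#' @export
shapiro_wilk <- function(sample) {
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop("shapiro_wilk: sample size must be in [3, 5000]")
  if (!is.numeric(sample) || any(!is.finite(sample)))
    stop("shapiro_wilk: sample must be finite numeric")
  ht <- shapiro.test(sample)
  test_result("Shapiro-Wilk", statistic = ht$statistic,
              p_two_sided = ht$p.value)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Reports the U statistic of the first sample with mid-rank tie handling.
#' The p-value is exact when `n_a + n_b <= 12` and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A [test_result()].
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("mann_whitney_u: both samples must be non-empty")
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(c(a, b))))
    stop("mann_whitney_u: samples must be finite numeric")
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b) <= 12) && !ties
  ht <- wilcox.test(a, b, exact = use_exact, correct = TRUE)
  test_result("Mann-Whitney U", statistic = ht$statistic,
              p_two_sided = min(ht$p.value, 1))
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with `df = (r - 1) * (c - 1)` and no continuity
#' correction.
#'
#' @param contingency_table Matrix of non-negative counts with at least two
#'   rows and two columns; every expected count must be positive.
#' @return A [test_result()].
#' @examples
#' chi_square_test(matrix(c(20, 5, 5, 20), 2)) # statistic 18, df 1
#' @export
chi_square_test <- function(contingency_table) {
  tab <- as.matrix(contingency_table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("chi_square_test: need at least a 2 x 2 table")
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("chi_square_test: counts must be non-negative and finite")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("chi_square_test: zero expected count; merge sparse categories ",
         "before testing")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  test_result("chi-square", statistic = ht$statistic, df = ht$parameter,
              p_two_sided = ht$p.value)
}

#' Render a p-value at report precision
#'
#' Three decimals, four when p < 0.01 (the precision used by the emulated
#' study's report tables).
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.01, formatC(p, digits = 4, format = "f"),
         formatC(p, digits = 3, format = "f"))
}

# ---------------------------------------------------------------------------
# Report tables

#' Between-group baseline comparison table
#'
#' One row per baseline variable with the seven summary columns per arm
#' (mean, SD, min, max, 25th and 75th percentile) and the between-group
#' p-value: Mann-Whitney U for the continuous variables, chi-square over
#' the stage distribution for H&Y. Gender counts are attached as the
#' attribute `"gender_counts"` and printed as a header line.
#'
#' @param cohort Cohort data frame (schema of [read_cohort_csv()]).
#' @return Data frame of class `baseline_table`.
#' @export
baseline_table <- function(cohort) {
  groups <- split(cohort, cohort$group)
  if (!all(c("active", "placebo") %in% names(groups)))
    stop("baseline_table: cohort must contain both arms")
  act <- groups$active
  plc <- groups$placebo
  cont_vars <- c("bmi", "disease_duration", "mmse", "led", "age")
  summarize <- function(x, prefix) {
    q <- quantile(x, c(0.25, 0.75))
    out <- data.frame(mean(x), sd(x), min(x), max(x), q[[1]], q[[2]])
    names(out) <- paste0(prefix, c("mean", "sd", "min", "max", "q25", "q75"))
    out
  }
  rows <- lapply(cont_vars, function(v) {
    res <- mann_whitney_u(act[[v]], plc[[v]])
    cbind(data.frame(variable = v),
          summarize(act[[v]], "active_"), summarize(plc[[v]], "placebo_"),
          data.frame(test = res$test_name, p_value = res$p_two_sided))
  })
  levels_hy <- sort(unique(cohort$hy))
  tab <- rbind(table(factor(act$hy, levels = levels_hy)),
               table(factor(plc$hy, levels = levels_hy)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  res_hy <- chi_square_test(tab)
  rows[[length(rows) + 1]] <- cbind(
    data.frame(variable = "hy"),
    summarize(act$hy, "active_"), summarize(plc$hy, "placebo_"),
    data.frame(test = res_hy$test_name, p_value = res_hy$p_two_sided))
  out <- do.call(rbind, rows)
  attr(out, "gender_counts") <- data.frame(
    group = c("active", "placebo"),
    male = c(sum(act$gender == "M"), sum(plc$gender == "M")),
    female = c(sum(act$gender == "F"), sum(plc$gender == "F")))
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' @export
print.baseline_table <- function(x, ...) {
  gc_ <- attr(x, "gender_counts")
  cat(sprintf("Gender: active %d M / %d F; placebo %d M / %d F\n",
              gc_$male[1], gc_$female[1], gc_$male[2], gc_$female[2]))
  df <- as.data.frame(x)
  df$p_value <- format_p(df$p_value)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

# Outcomes analysed in the pre/post report: P4 (the composite fall-risk
# index) is generated but excluded from the statistical tables.
.report_parameters <- function() paste0("p", c(1:3, 5:11))

#' Pre/post outcome report
#'
#' Per arm and per instrumented TUG parameter (P1-P3, P5-P11; P4 is
#' excluded from the report tables): Shapiro-Wilk normality screening and
#' the paired t test, plus the BBS paired-t row. By default the normality
#' screen is applied to the paired differences (the quantity the t test
#' assumes normal); `shapiro_on` switches it to the pre or post values.
#'
#' @param cohort Cohort data frame.
#' @param shapiro_on One of `"difference"`, `"pre"`, `"post"`.
#' @param adjust `"none"` (default, matching the uncorrected report
#'   tables) or `"holm"` to adjust the paired-t p-values per arm.
#' @return Data frame of class `outcome_table` with columns `group`,
#'   `parameter`, `shapiro_W`, `shapiro_p`, `t_statistic`, `df`, `p_value`,
#'   `p_rendered`, `significant`.
#' @export
outcome_report <- function(cohort,
                           shapiro_on = c("difference", "pre", "post"),
                           adjust = c("none", "holm")) {
  shapiro_on <- match.arg(shapiro_on)
  adjust <- match.arg(adjust)
  groups <- split(cohort, cohort$group)
  if (!all(c("active", "placebo") %in% names(groups)))
    stop("outcome_report: cohort must contain both arms")
  one_arm <- function(g) {
    dat <- groups[[g]]
    params <- c(.report_parameters(), "bbs")
    rows <- lapply(params, function(pp) {
      pre <- dat[[paste0(pp, "_t0")]]
      post <- dat[[paste0(pp, "_t1")]]
      tt <- paired_t(pre, post)
      if (pp == "bbs") {
        sw <- list(statistic = NA_real_, p_two_sided = NA_real_)
      } else {
        x <- switch(shapiro_on, difference = post - pre, pre = pre,
                    post = post)
        sw <- shapiro_wilk(x)
      }
      data.frame(group = g, parameter = pp, shapiro_W = sw$statistic,
                 shapiro_p = sw$p_two_sided, t_statistic = tt$statistic,
                 df = tt$df, p_value = tt$p_two_sided)
    })
    arm <- do.call(rbind, rows)
    if (adjust == "holm") {
      arm$p_value <- stats::p.adjust(arm$p_value, method = "holm")
    }
    arm
  }
  out <- rbind(one_arm("active"), one_arm("placebo"))
  out$p_rendered <- format_p(out$p_value)
  out$significant <- out$p_value < 0.05
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Write a report table as CSV and as aligned plain text
#'
#' @param report A `baseline_table` or `outcome_table` data frame.
#' @param path Output CSV path; the plain-text rendering goes to the same
#'   path with extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  write.csv(df, path, row.names = FALSE)
  txt_path <- sub("\\.csv$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(path)
}
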