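#' Small-sample bias factor of the t statistic
#'
#' For paired differences that are i.i.d. normal with standardized effect
#' size dz, the paired t statistic follows a noncentral t distribution with
#' noncentrality dz * sqrt(n), whose mean is `ncp * c4(df)` with
#' `c4(df) = sqrt(df / 2) * Gamma((df - 1) / 2) / Gamma(df / 2)`
#' (about 1.033 at df = 24). Effect-size calibration and recovery use this
#' factor so that configured effects reproduce target t statistics in
#' expectation rather than overshooting them by ~3%.
#'
#' @param df Degrees of freedom, > 2 for a finite mean.
#' @return The multiplicative bias factor (> 1).
#' @examples
#' t_bias_factor(24)
#' @export
t_bias_factor <- function(df) {
  if (!is.numeric(df) || any(df <= 2))
    stop("t_bias_factor: df must be > 2")
  sqrt(df / 2) * exp(lgamma((df - 1) / 2) - lgamma(df / 2))
}

#' Back-derive a paired effect size from a target t statistic
#'
#' Inverts the mean relation of the noncentral t distribution:
#' `dz = t / (sqrt(n) * c4(n - 1))` so that cohorts generated with this dz
#' yield a replicate-mean paired t equal to `t`. With
#' `bias_correct = FALSE` the naive first-order relation `dz = t / sqrt(n)`
#' is used instead.
#'
#' @param t Target paired t statistic.
#' @param n Number of pairs.
#' @param bias_correct Apply the exact-mean correction (default `TRUE`).
#' @return Standardized paired effect size (mean difference / SD of
#'   differences).
#' @examples
#' dz_from_t(3.72, 25)        # ~0.720
#' dz_from_t(3.72, 25, FALSE) # 0.744
#' @export
dz_from_t <- function(t, n, bias_correct = TRUE) {
  if (!is.numeric(n) || n < 4) stop("dz_from_t: n must be >= 4")
  t / sqrt(n) / (if (bias_correct) t_bias_factor(n - 1) else 1)
}

#' Estimate a standardized paired effect size from differences
#'
#' `mean(d) / sd(d)`, with the matching Hedges-type small-sample correction
#' (division by `c4(n - 1)`) by default, so that the estimator is unbiased
#' for the configured dz under normality.
#'
#' @param d Numeric vector of paired differences, length >= 4.
#' @param bias_correct Apply the small-sample correction (default `TRUE`).
#' @return Estimated dz.
#' @export
dz_estimate <- function(d, bias_correct = TRUE) {
  n <- length(d)
  if (n < 4) stop("dz_estimate: need at least 4 differences")
  raw <- mean(d) / sd(d)
  if (bias_correct) raw / t_bias_factor(n - 1) else raw
}

# ---------------------------------------------------------------------------
# Baseline distributions

#' Default baseline distributions of the two study arms
#'
#' Per-arm summary parameters (mean, SD, min, max) of the baseline
#' variables of the emulated two-arm Parkinson's-disease study: age (years),
#' BMI (kg/m2), disease duration (years), MMSE (0-30), daily levodopa
#' equivalent dose (mg) and Hoehn & Yahr stage, plus the male proportion.
#' The arms deliberately differ in age (active mean 77.56 vs placebo 67.15
#' years): the emulated study randomized into age-imbalanced arms and the
#' generator reproduces that imbalance by default.
#'
#' @param balanced_age If `TRUE`, both arms draw age from the pooled
#'   distribution (matched arms for sensitivity runs).
#' @return Nested list of class `baseline_distributions`:
#'   `$active` / `$placebo`, each with per-variable `c(mean, sd, min, max)`
#'   vectors, `male_prop`, and `hy` (mean plus discrete support).
#' @export
baseline_distributions <- function(balanced_age = FALSE) {
  v <- function(mean, sd, min, max) c(mean = mean, sd = sd, min = min,
                                      max = max)
  active <- list(
    age = v(77.56, 5.85, 64, 91),
    bmi = v(23.78, 3.99, 17.83, 33.33),
    disease_duration = v(14.18, 6.31, 5, 27),
    mmse = v(25.86, 1.25, 24, 27.5),
    led = v(631.6, 160.4, 380, 890),
    hy = list(mean = 2.98, support = c(2, 2.5, 3, 3.5, 4)),
    male_prop = 12 / 25
  )
  placebo <- list(
    age = v(67.15, 7.00, 56, 83),
    bmi = v(23.54, 4.75, 14.33, 35.22),
    disease_duration = v(14.50, 4.72, 7, 25),
    mmse = v(25.45, 1.06, 23.5, 27.4),
    led = v(613.1, 140.4, 390, 890),
    hy = list(mean = 3.15, support = c(2, 2.5, 3, 3.5, 4)),
    male_prop = 14 / 25
  )
  if (balanced_age) {
    pooled <- v((77.56 + 67.15) / 2, sqrt((5.85^2 + 7.00^2) / 2), 56, 91)
    active$age <- pooled
    placebo$age <- pooled
  }
  structure(list(active = active, placebo = placebo),
            class = "baseline_distributions")
}

#' Probabilities over the Hoehn & Yahr support matching a target mean
#'
#' Solves a one-parameter exponential tilt of the uniform distribution over
#' the discrete support so that the expected stage equals `target_mean`.
#'
#' @param target_mean Target mean stage; must lie strictly inside the
#'   support range.
#' @param support Discrete stage values (default half-steps 2 to 4).
#' @return Probability vector over `support` (sums to 1, mean equals
#'   `target_mean` to numerical accuracy).
#' @export
hy_probabilities <- function(target_mean, support = c(2, 2.5, 3, 3.5, 4)) {
  if (target_mean <= min(support) || target_mean >= max(support))
    stop("hy_probabilities: target mean must lie inside the support range")
  key <- paste("hy", target_mean, paste(support, collapse = ","), sep = "|")
  hit <- .root_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(theta) {
    w <- exp(theta * (support - mean(support)))
    sum(support * w) / sum(w) - target_mean
  }
  theta <- uniroot(f, c(-60, 60), tol = 1e-12)$root
  w <- exp(theta * (support - mean(support)))
  .root_cache[[key]] <- w / sum(w)
}

# Root solves below are deterministic in their arguments; cache them so
# replicate cohort generation does not re-solve identical problems.
.root_cache <- new.env(parent = emptyenv())

# Latent location for a truncated normal so that the truncated mean equals
# the target (truncation to [lo, hi] otherwise biases the mean).
.trunc_location <- function(target, sd, lo, hi) {
  key <- paste("tl", target, sd, lo, hi, sep = "|")
  hit <- .root_cache[[key]]
  if (!is.null(hit)) return(hit)
  .root_cache[[key]] <- .trunc_location_solve(target, sd, lo, hi)
}

.trunc_location_solve <- function(target, sd, lo, hi) {
  if (lo > hi) stop("infeasible truncation bounds: min > max")
  if (lo == hi) return(lo)
  if (target < lo || target > hi)
    stop("infeasible truncation bounds: mean outside [min, max]")
  if (sd == 0) return(target)
  tmean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    if (z < 1e-12) return(if (mu < lo) lo else hi)  # far-out guard
    mu + sd * (dnorm(a) - dnorm(b)) / z
  }
  f <- function(mu) tmean(mu) - target
  for (w in c(6, 4, 3, 2, 1, 0.5) * sd) {
    flo <- f(lo - w)
    fhi <- f(hi + w)
    if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0)
      return(uniroot(f, c(lo - w, hi + w), tol = 1e-10)$root)
  }
  stop("infeasible truncation: target mean too close to a bound for sd = ",
       sd)
}

# Inverse-CDF sampler for a truncated normal (exact, vectorized).
.rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (lo == hi || sd == 0) return(rep(mu, n))
  a <- pnorm((lo - mu) / sd)
  b <- pnorm((hi - mu) / sd)
  qnorm(a + runif(n) * (b - a)) * sd + mu
}

# ---------------------------------------------------------------------------
# Effect model and outcome level defaults

#' Reference t statistics used to calibrate the default effect model
#'
#' The paired t statistics (df = 24) that the calibrated generator is
#' designed to reproduce in expectation: the Berg Balance Scale row of each
#' arm and the eleven instrumented TUG parameters of the active arm (the
#' placebo arm's TUG effects are null by design).
#'
#' @return Named list with `active` and `placebo` numeric vectors.
#' @export
reference_t_statistics <- function() {
  list(
    active = c(bbs = -3.72, p1 = 2.367, p2 = -3.326, p3 = -1.934, p4 = 0,
               p5 = -2.644, p6 = -2.439, p7 = -2.274, p8 = -1.111,
               p9 = -2.229, p10 = 2.853, p11 = 0.725),
    placebo = c(bbs = 0.55, p1 = 0, p2 = 0, p3 = 0, p4 = 0, p5 = 0, p6 = 0,
                p7 = 0, p8 = 0, p9 = 0, p10 = 0, p11 = 0)
  )
}

#' Default paired effect model
#'
#' One row per outcome (BBS and TUG parameters P1-P11) with the
#' standardized paired effect size per arm (`dz_active`, `dz_placebo`,
#' back-derived from [reference_t_statistics()] via [dz_from_t()]), the SD
#' of paired differences `sigma_d` in the outcome's units, and the
#' direction in which an improvement moves the score (+1 increases, e.g.
#' BBS; -1 decreases, e.g. test duration).
#'
#' `sigma_d` values are plausibility choices in the outcomes' units (they
#' are not published quantities); dz magnitudes are what pin the t
#' statistics, so `sigma_d` only sets the raw scale of the changes.
#'
#' @param n_pairs Number of pairs the calibration assumes (default 25).
#' @param bias_correct Passed to [dz_from_t()].
#' @return Data frame of class `effect_model` with columns `outcome`,
#'   `dz_active`, `dz_placebo`, `sigma_d`, `direction`.
#' @export
effect_model <- function(n_pairs = 25, bias_correct = TRUE) {
  ref <- reference_t_statistics()
  outcomes <- names(ref$active)
  sigma_d <- c(bbs = 5, p1 = 2, p2 = 0.25, p3 = 0.22, p4 = 0.3, p5 = 4,
               p6 = 3, p7 = 3.5, p8 = 2, p9 = 3, p10 = 0.5, p11 = 0.45)
  direction <- c(bbs = 1, p1 = -1, p2 = -1, p3 = -1, p4 = -1, p5 = -1,
                 p6 = 1, p7 = 1, p8 = -1, p9 = 1, p10 = 1, p11 = -1)
  em <- data.frame(
    outcome = outcomes,
    dz_active = abs(dz_from_t(ref$active, n_pairs, bias_correct))[outcomes],
    dz_placebo = abs(dz_from_t(ref$placebo, n_pairs, bias_correct))[outcomes],
    sigma_d = sigma_d[outcomes],
    direction = direction[outcomes],
    row.names = NULL
  )
  class(em) <- c("effect_model", "data.frame")
  em
}

#' Default pre-treatment (T0) outcome levels
#'
#' Mean and SD of each outcome before treatment. These are plausible
#' Parkinson's-disease ranges chosen for the synthetic cohorts (the
#' emulated study does not publish raw outcome levels): BBS around 36/56
#' (moderate balance impairment, consistent with the postural-instability
#' inclusion criterion and low enough that the 56-point ceiling clips
#' almost no post-treatment scores), TUG duration around 18 s, and so on.
#' Units follow the TUG parameter table (P2/P3 carried in m/s as printed
#' there).
#'
#' @return Data frame with columns `outcome`, `mean`, `sd`.
#' @export
t0_outcome_defaults <- function() {
  data.frame(
    outcome = c("bbs", paste0("p", 1:11)),
    mean = c(36, 18, 1.2, 1.1, 1.5, 25, 15, 22, 8, 18, 2.8, 2.5),
    sd = c(5, 5, 0.4, 0.35, 0.5, 8, 5, 7, 3, 6, 0.8, 0.7)
  )
}

#' Cohort generation configuration
#'
#' @param n_per_group Subjects per arm (default 25), >= 2.
#' @param seed Mandatory integer seed; cohort generation is fully
#'   deterministic given the configuration.
#' @param baselines A `baseline_distributions` object.
#' @param effects An `effect_model` data frame.
#' @param t0 Data frame of T0 outcome means/SDs as in
#'   [t0_outcome_defaults()].
#' @param balanced_age Draw age from a pooled distribution in both arms.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 25, seed,
                          baselines = baseline_distributions(balanced_age),
                          effects = effect_model(),
                          t0 = t0_outcome_defaults(),
                          balanced_age = FALSE) {
  if (missing(seed) || is.null(seed))
    stop("cohort_config: a seed is required (no silent nondeterminism)")
  if (!is.numeric(n_per_group) || n_per_group < 2 ||
      n_per_group != round(n_per_group))
    stop("cohort_config: n_per_group must be an integer >= 2")
  if (!inherits(baselines, "baseline_distributions"))
    stop("cohort_config: baselines must be a baseline_distributions object")
  need <- c("outcome", "dz_active", "dz_placebo", "sigma_d", "direction")
  if (!all(need %in% names(effects)))
    stop("cohort_config: effects must have columns ",
         paste(need, collapse = ", "))
  if (any(effects$sigma_d <= 0))
    stop("cohort_config: sigma_d must be > 0 for every outcome")
  if (!all(c("outcome", "mean", "sd") %in% names(t0)))
    stop("cohort_config: t0 must have columns outcome, mean, sd")
  if (!setequal(t0$outcome, effects$outcome))
    stop("cohort_config: t0 and effects must cover the same outcomes")
  structure(list(n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed), baselines = baselines,
                 effects = effects, t0 = t0, balanced_age = balanced_age),
            class = "cohort_config")
}

#' Sample baseline characteristics for one arm
#'
#' Continuous variables are drawn from normal distributions truncated to
#' the configured \[min, max\], with the latent location solved so that the
#' truncated mean equals the configured mean. H&Y stages are drawn from the
#' discrete support with exponential-tilt probabilities matching the
#' configured mean stage; gender is Bernoulli with the configured male
#' proportion. Uses the current RNG state.
#'
#' @param config A `cohort_config`.
#' @param group `"active"` or `"placebo"`.
#' @param n Number of subjects to draw (default 1).
#' @return Data frame with columns `gender`, `age`, `bmi`,
#'   `disease_duration`, `mmse`, `led`, `hy`.
#' @export
sample_baseline <- function(config, group = c("active", "placebo"), n = 1) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  b <- config$baselines[[group]]
  draw <- function(par) {
    mu <- .trunc_location(par[["mean"]], par[["sd"]], par[["min"]],
                          par[["max"]])
    .rtruncnorm(n, mu, par[["sd"]], par[["min"]], par[["max"]])
  }
  hy_p <- hy_probabilities(b$hy$mean, b$hy$support)
  data.frame(
    gender = ifelse(runif(n) < b$male_prop, "M", "F"),
    age = draw(b$age),
    bmi = draw(b$bmi),
    disease_duration = draw(b$disease_duration),
    mmse = draw(b$mmse),
    led = draw(b$led),
    hy = sample(b$hy$support, n, replace = TRUE, prob = hy_p)
  )
}

#' Sample pre/post outcomes for one arm
#'
#' T0 levels are drawn from the configured normal levels; the paired
#' difference of each outcome is drawn as
#' `D ~ N(dz * sigma_d, sigma_d)` for the arm's dz, and
#' `T1 = T0 + direction * D`. BBS values are clipped to \[0, 56\]; the
#' number of clipped values is attached as attribute `"bbs_clipped"`.
#'
#' @inheritParams sample_baseline
#' @return Data frame with columns `<outcome>_t0` and `<outcome>_t1` for
#'   BBS and P1-P11.
#' @export
sample_outcomes <- function(config, group = c("active", "placebo"), n = 1) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  em <- config$effects
  t0 <- config$t0
  dz_col <- if (group == "active") "dz_active" else "dz_placebo"
  out <- list()
  clipped <- 0L
  for (k in seq_len(nrow(em))) {
    oc <- em$outcome[k]
    lev <- t0[t0$outcome == oc, ]
    pre <- rnorm(n, lev$mean, lev$sd)
    d <- rnorm(n, em[[dz_col]][k] * em$sigma_d[k], em$sigma_d[k])
    post <- pre + em$direction[k] * d
    if (oc == "bbs") {
      pre_c <- pmin(pmax(pre, 0), 56)
      post_c <- pmin(pmax(post, 0), 56)
      clipped <- clipped + sum(pre_c != pre) + sum(post_c != post)
      pre <- pre_c
      post <- post_c
    }
    out[[paste0(oc, "_t0")]] <- pre
    out[[paste0(oc, "_t1")]] <- post
  }
  res <- as.data.frame(out)
  attr(res, "bbs_clipped") <- clipped
  res
}

#' Generate a full two-arm cohort
#'
#' Deterministic under the configuration's seed. Active subjects come
#' first, then placebo.
#'
#' @param config A `cohort_config`.
#' @return Data frame with one row per subject and the cohort CSV schema
#'   columns (see [write_cohort_csv()]); the number of clipped BBS values
#'   is attached as attribute `"bbs_clipped"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  arms <- lapply(c("active", "placebo"), function(g) {
    base <- sample_baseline(config, g, n)
    outc <- sample_outcomes(config, g, n)
    df <- cbind(data.frame(group = g), base, outc)
    attr(df, "bbs_clipped") <- attr(outc, "bbs_clipped")
    df
  })
  cohort <- do.call(rbind, arms)
  cohort <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(2 * n))),
                  cohort)
  cohort <- cohort[.cohort_schema()]
  attr(cohort, "bbs_clipped") <- sum(vapply(arms, function(a) {
    cl <- attr(a, "bbs_clipped")
    if (is.null(cl)) 0L else cl
  }, integer(1)))
  cohort
}

# Exact column order of the cohort CSV schema.
.cohort_schema <- function() {
  c("subject_id", "group", "gender", "age", "bmi", "disease_duration",
    "mmse", "led", "hy", "bbs_t0", "bbs_t1",
    paste0("p", 1:11, "_t0"), paste0("p", 1:11, "_t1"))
}

#' Write / read a cohort CSV
#'
#' The schema has the exact header order `subject_id, group, gender, age,
#' bmi, disease_duration, mmse, led, hy, bbs_t0, bbs_t1, p1_t0 ... p11_t0,
#' p1_t1 ... p11_t1`. Reading validates the header and every value;
#' format errors name the offending column and row.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the validated cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  schema <- .cohort_schema()
  missing_cols <- setdiff(schema, names(cohort))
  if (length(missing_cols) > 0)
    stop("write_cohort_csv: missing columns: ",
         paste(missing_cols, collapse = ", "))
  write.csv(cohort[schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("read_cohort_csv: no such file: ", path)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0)
    stop("read_cohort_csv: ", path, " is empty")
  df <- read.csv(path, stringsAsFactors = FALSE)
  schema <- .cohort_schema()
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols) > 0)
    stop("read_cohort_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), schema)
  if (length(extra) > 0)
    stop("read_cohort_csv: unexpected column(s): ",
         paste(extra, collapse = ", "))
  df <- df[schema]
  if (nrow(df) == 0) stop("read_cohort_csv: ", path, " has no rows")
  if (!all(df$group %in% c("active", "placebo"))) {
    bad <- which(!(df$group %in% c("active", "placebo")))[1]
    stop("read_cohort_csv: invalid value in column 'group', row ", bad)
  }
  if (!all(df$gender %in% c("M", "F"))) {
    bad <- which(!(df$gender %in% c("M", "F")))[1]
    stop("read_cohort_csv: invalid value in column 'gender', row ", bad)
  }
  num_cols <- setdiff(schema, c("subject_id", "group", "gender"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("read_cohort_csv: unparseable value in column '", cl, "', row ",
           bad)
    }
  }
  df
}
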