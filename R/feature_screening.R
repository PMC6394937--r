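#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a feature sample against a normal law with the
#' sample's own mean and standard deviation. Estimating the parameters from
#' the same sample makes the plain KS p-value anticonservative (the
#' Lilliefors situation); `lilliefors = TRUE` switches to the
#' Lilliefors-corrected test. A zero-variance sample is non-normal by
#' convention (p = 0).
#'
#' @param values Numeric sample, n >= 8.
#' @param lilliefors Use the Lilliefors correction (needs the `nortest`
#'   package).
#' @return The p-value.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 8L) {
    stop("normality check needs at least 8 values, got ", length(values),
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) return(0)
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors correction needs the 'nortest' package",
           call. = FALSE)
    }
    return(unname(nortest::lillie.test(values)$p.value))
  }
  suppressWarnings(
    unname(stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  )
}

#' Two-sample Student's t-test
#'
#' Pooled-variance (classic Student) two-sided test by default; Welch's
#' unequal-variance form by flag.
#'
#' @param x,y Numeric samples for the two classes.
#' @param welch Use the Welch form instead of pooled variance.
#' @return List with `statistic` (t) and `p_value`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Two-sample Mann-Whitney U-test
#'
#' Two-sided rank-sum test. The exact null distribution is used for small
#' tie-free samples (smaller group of 8 or fewer); otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples for the two classes.
#' @return List with `statistic` (U for the first sample) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && min(length(x), length(y)) <= 8L
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Univariate feature screening
#'
#' For each feature column the two class-conditional samples are checked for
#' normality with [ks_normality()]; the feature is compared between classes
#' with Student's t-test if both samples look normal at the 0.05 level,
#' otherwise with the Mann-Whitney U-test. Significance is declared at
#' `alpha`. No multiple-testing correction is applied — the report is a
#' transparent per-feature screen, and the classifier's feature selection
#' does not depend on it. Class medians and mean +/- SD are carried along
#' for reporting.
#'
#' @param table Feature table (see [extract_features()]).
#' @param alpha Significance level (default 0.05).
#' @param features Feature columns to screen; all by default.
#' @param lilliefors,welch Passed to [ks_normality()] / [two_sample_t()].
#' @return A data.frame (class `"screen_report"`) with one row per feature:
#'   normality p per class, chosen test, statistic, p-value, significance
#'   flag, and per-class medians and mean/SD.
#' @export
screen_features <- function(table, alpha = 0.05, features = NULL,
                            lilliefors = FALSE, welch = FALSE) {
  .check_feature_table(table, features)
  if (is.null(features)) features <- feature_columns(table)
  lab <- as.character(table$label)
  if (length(unique(lab)) < 2L) {
    stop("screening needs both classes present", call. = FALSE)
  }
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    if (anyNA(v)) {
      warning("feature ", f, " has undefined entries; cases dropped for ",
              "screening", call. = FALSE)
    }
    x <- v[lab == "tendinopathy" & !is.na(v)]
    y <- v[lab == "tear" & !is.na(v)]
    pnx <- ks_normality(x, lilliefors)
    pny <- ks_normality(y, lilliefors)
    if (pnx >= 0.05 && pny >= 0.05) {
      ht <- two_sample_t(x, y, welch)
      test <- "t"
    } else {
      ht <- mann_whitney_u(x, y)
      test <- "MannWhitneyU"
    }
    data.frame(
      feature = f,
      normal_p_tendinopathy = pnx, normal_p_tear = pny,
      test = test, statistic = ht$statistic, p_value = ht$p_value,
      significant = ht$p_value < alpha,
      median_tendinopathy = stats::median(x), median_tear = stats::median(y),
      mean_tendinopathy = mean(x), sd_tendinopathy = stats::sd(x),
      mean_tear = mean(y), sd_tear = stats::sd(y)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_report", "data.frame")
  out
}
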