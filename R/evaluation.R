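#' Confusion counts (positive class = tear)
#'
#' @param predicted,truth Character vectors (or factors) of
#'   `"tendinopathy"` / `"tear"` calls, same length.
#' @return List of class `"confusion_counts"` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("prediction/truth length mismatch", call. = FALSE)
  }
  ok <- c("tendinopathy", "tear")
  if (!all(predicted %in% ok) || !all(truth %in% ok)) {
    stop("labels must be 'tendinopathy' or 'tear'", call. = FALSE)
  }
  structure(
    list(TP = sum(predicted == "tear" & truth == "tear"),
         FP = sum(predicted == "tear" & truth == "tendinopathy"),
         TN = sum(predicted == "tendinopathy" & truth == "tendinopathy"),
         FN = sum(predicted == "tendinopathy" & truth == "tear")),
    class = "confusion_counts"
  )
}

#' Confusion counts from explicit cells
#' @param TP,FP,TN,FN Nonnegative integer cell counts.
#' @return A `"confusion_counts"` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  cells <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(cells), class = "confusion_counts")
}

#' The five diagnostic performance indices
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' PPV `TP/(TP+FP)` and NPV `TN/(TN+FN)`. Raw proportions are always kept;
#' the `*_pct` fields follow the display convention of truncating (flooring)
#' to whole percent, so 93/99 = 93.94% is displayed as 93. An empty
#' denominator yields the `NA` undefined sentinel.
#'
#' @param counts A `"confusion_counts"` object.
#' @return List of class `"performance_report"` with the five proportions,
#'   their truncated percent versions, and the counts.
#' @export
performance <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    n <- TP + FP + TN + FN
    prop <- list(
      accuracy = rat(TP + TN, n),
      sensitivity = rat(TP, TP + FN),
      specificity = rat(TN, TN + FP),
      ppv = rat(TP, TP + FP),
      npv = rat(TN, TN + FN)
    )
    pct <- lapply(prop, function(x) if (is.na(x)) NA_real_ else
      floor(100 * x))
    names(pct) <- paste0(names(prop), "_pct")
    structure(c(prop, pct, list(counts = counts)),
              class = "performance_report")
  })
}

#' @export
print.performance_report <- function(x, ...) {
  cc <- x$counts
  n <- cc$TP + cc$FP + cc$TN + cc$FN
  fmt <- function(name, pct, num, den) {
    cat(sprintf("  %-12s %s%% (%d/%d)\n", name,
                ifelse(is.na(pct), "--", pct), num, den))
  }
  cat("Performance (positive class = tear)\n")
  fmt("Accuracy", x$accuracy_pct, cc$TP + cc$TN, n)
  fmt("Sensitivity", x$sensitivity_pct, cc$TP, cc$TP + cc$FN)
  fmt("Specificity", x$specificity_pct, cc$TN, cc$TN + cc$FP)
  fmt("PPV", x$ppv_pct, cc$TP, cc$TP + cc$FP)
  fmt("NPV", x$npv_pct, cc$TN, cc$TN + cc$FN)
  invisible(x)
}

#' Empirical ROC curve and area under it
#'
#' Threshold sweep over the unique scores, from the strictest threshold at
#' (0, 0) to the loosest at (1, 1); the area (Az) is the trapezoidal rule,
#' so tied scores contribute half credit — identical to the normalized
#' Mann-Whitney all-pairs statistic.
#'
#' @param scores Numeric tear scores (higher = more tear-like).
#' @param truths `"tendinopathy"` / `"tear"` vector of the same length.
#' @return List with `points` (data.frame of `fpr`, `tpr`, ordered and
#'   non-decreasing, from (0,0) to (1,1)) and `az`.
#' @export
roc_and_az <- function(scores, truths) {
  truths <- as.character(truths)
  if (length(scores) != length(truths)) {
    stop("score/truth length mismatch", call. = FALSE)
  }
  pos <- truths == "tear"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  az <- sum((fpr[-1] - fpr[-length(fpr)]) *
            (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), az = az)
}

#' Exact McNemar comparison of two paired classifiers
#'
#' Compares two prediction vectors on the same cases through their paired
#' correctness: with `b` cases that only model A gets right and `c` that
#' only model B gets right, the two-sided exact binomial p-value of
#' `b` successes in `b + c` trials at p = 1/2 is returned (1 when there are
#' no discordant pairs).
#'
#' @param predsA,predsB Predicted label vectors for the two models.
#' @param truths True labels.
#' @return The p-value.
#' @export
compare_paired <- function(predsA, predsB, truths) {
  truths <- as.character(truths)
  okA <- as.character(predsA) == truths
  okB <- as.character(predsB) == truths
  b <- sum(okA & !okB)
  cc <- sum(!okA & okB)
  if (b + cc == 0L) return(1)
  stats::binom.test(b, b + cc, p = 0.5)$p.value
}

#' Table-style performance comparison report
#'
#' Runs [confusion()], [performance()] and [roc_and_az()] for one or more
#' prediction sets and lays the indices out side by side, as commonly
#' reported for intensity / texture / combined feature sets.
#'
#' @param predictions Named list of `"loocv_predictions"` data.frames.
#' @return A data.frame with one row per index (truncated percent, with raw
#'   fractions in attributes) and one column per model, plus an `az` row.
#' @export
performance_table <- function(predictions) {
  stopifnot(length(predictions) >= 1L, !is.null(names(predictions)))
  cols <- lapply(predictions, function(pr) {
    perf <- performance(confusion(pr$predicted, pr$truth))
    roc <- roc_and_az(pr$probability, pr$truth)
    c(Accuracy = perf$accuracy_pct, Sensitivity = perf$sensitivity_pct,
      Specificity = perf$specificity_pct, PPV = perf$ppv_pct,
      NPV = perf$npv_pct, Az = round(roc$az, 4))
  })
  as.data.frame(cols)
}
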