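# Confusion-matrix metrics and repeated-run statistics: the five-metric
# report (accuracy, macro specificity/recall/precision/F1), Student-t
# confidence intervals, and classical one-way ANOVA.

#' Five-metric report from a confusion matrix
#'
#' One-vs-rest per class c: TP = cm\[c,c\], FN = row sum - TP,
#' FP = column sum - TP, TN = total - TP - FN - FP; then
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' specificity = TN/(TN+FP), F1 = 2 P R / (P + R). Accuracy is
#' trace/total; macro values are unweighted class means. 0/0 ratios are
#' defined as 0 with a warning.
#'
#' @param cm K x K matrix, rows = true class, columns = predicted class,
#'   K >= 2, positive total.
#' @return A [MetricsReport-class].
#' @export
#' @examples
#' accuracy(metricsFromConfusion(matrix(c(8, 1, 2, 9), 2)))  # 0.85
metricsFromConfusion <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  stopIfNot(nrow(cm) == ncol(cm) && nrow(cm) >= 2,
            "invalid argument: confusion matrix must be square, K >= 2")
  total <- sum(cm)
  stopIfNot(total > 0, "invalid argument: empty confusion matrix")
  K <- nrow(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- sprintf("class%d", seq_len(K))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safeDiv <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning("0/0 in ", what, " for class(es) ",
              paste(classes[bad], collapse = ", "), "; defined as 0")
    out <- numeric(length(num))
    out[!bad] <- num[!bad] / den[!bad]
    out
  }
  recall <- safeDiv(tp, tp + fn, "recall")
  precision <- safeDiv(tp, tp + fp, "precision")
  specificity <- safeDiv(tn, tn + fp, "specificity")
  f1 <- safeDiv(2 * precision * recall, precision + recall, "F1")
  new("MetricsReport",
      accuracy = sum(tp) / total,
      macroSpecificity = mean(specificity),
      macroRecall = mean(recall),
      macroPrecision = mean(precision),
      macroF1 = mean(f1),
      perClass = data.frame(class = classes, specificity = specificity,
                            recall = recall, precision = precision, f1 = f1,
                            row.names = NULL),
      confusion = cm)
}

#' Student-t confidence interval of a mean
#'
#' mean +/- t_\{(1+level)/2, n-1\} sd / sqrt(n).
#'
#' @param values Numeric vector, n >= 2.
#' @param level Confidence level (default 0.95).
#' @return Named numeric (mean, lower, upper).
#' @export
#' @examples
#' meanCI(c(0, 2))  # mean 1, interval c(-11.706, 13.706)
meanCI <- function(values, level = 0.95) {
  n <- length(values)
  stopIfNot(n >= 2, "invalid argument: need at least 2 values for a CI")
  stopIfNot(level > 0 && level < 1, "invalid argument: level must be in (0,1)")
  m <- mean(values)
  half <- qt((1 + level) / 2, n - 1) * sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' One-way analysis of variance
#'
#' Classical decomposition F = MS_between / MS_within with degrees of
#' freedom (k - 1, N - k); p from the upper tail of the F distribution.
#' Implemented via `stats::oneway.test(var.equal = TRUE)`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values). Zero within-group variance is degenerate (F undefined).
#' @return Named numeric (F, p, df1, df2).
#' @export
#' @examples
#' anovaOneway(list(c(2, 3, 4), c(4, 5, 6), c(6, 7, 8)))  # F = 12
anovaOneway <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 2,
            "invalid argument: need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  stopIfNot(all(sizes >= 2), "invalid argument: every group needs >= 2 values")
  vals <- unlist(groups)
  grp <- factor(rep(seq_along(groups), sizes))
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (msw == 0)
    stop("degenerate input: zero within-group variance", call. = FALSE)
  ft <- oneway.test(vals ~ grp, var.equal = TRUE)
  c(F = unname(ft$statistic), p = unname(ft$p.value),
    df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}
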