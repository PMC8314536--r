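# Diagnostic and agreement statistics: ROC with Youden cutoff, 2x2 table
# arithmetic and reconstruction from printed summaries, Lin's concordance
# correlation coefficient, Bland-Altman limits of agreement.

#' Confusion table
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts, not all zero.
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) {
    stopf("confusion_table: negative cell (%s)",
          paste(names(cells)[cells < 0], collapse = ", "))
  }
  if (sum(cells) == 0) stopf("confusion_table: all cells are zero")
  structure(as.list(cells), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fp=%d fn=%d tn=%d (N=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' ROC curve with AUC and Youden-optimal cutoff
#'
#' The curve is evaluated at every unique score value. AUC is computed by
#' the trapezoidal rule, which equals the Mann-Whitney pair statistic with
#' half credit for ties. The optimal cutoff maximizes Youden's
#' J = sensitivity + specificity - 1; ties are resolved toward higher
#' sensitivity, then toward the lower threshold. With `direction = "auto"`
#' the rule (`">="`: high scores positive, or `"<="`) giving AUC >= 0.5 is
#' chosen.
#'
#' @param scores Numeric marker values.
#' @param labels Binary class labels (logical, or coercible 0/1), `TRUE` =
#'   positive. Both classes must be present.
#' @param direction `">="`, `"<="` or `"auto"`.
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr` (curve
#'   points, threshold decreasing from `Inf` for the `">="` rule), `auc`,
#'   `optimal_cutoff`, `optimal_rule`, `youden`.
#' @export
roc_curve <- function(scores, labels, direction = c("auto", ">=", "<=")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("roc_curve: length mismatch")
  if (anyNA(scores) || anyNA(labels)) stopf("roc_curve: missing values not allowed")
  if (!any(labels) || all(labels)) stopf("roc_curve: both classes must be present")

  build <- function(sc) {
    # ">=" rule on sc: predicted positive when sc >= threshold
    thr <- sort(unique(sc), decreasing = TRUE)
    n_pos <- sum(labels)
    n_neg <- sum(!labels)
    tpr <- vapply(thr, function(t) sum(sc >= t & labels) / n_pos, numeric(1))
    fpr <- vapply(thr, function(t) sum(sc >= t & !labels) / n_neg, numeric(1))
    tpr_c <- c(0, tpr)
    fpr_c <- c(0, fpr)
    auc <- sum(diff(fpr_c) * (utils::head(tpr_c, -1) + utils::tail(tpr_c, -1)) / 2)
    # ensure the curve ends at (1, 1)
    if (fpr_c[length(fpr_c)] < 1 || tpr_c[length(tpr_c)] < 1) {
      auc <- auc + (1 - fpr_c[length(fpr_c)]) * (tpr_c[length(tpr_c)] + 1) / 2
    }
    list(thresholds = c(Inf, thr), tpr = tpr_c, fpr = fpr_c, auc = auc,
         cand_thr = thr, cand_tpr = tpr, cand_fpr = fpr)
  }

  ge <- build(scores)
  use_le <- switch(direction, ">=" = FALSE, "<=" = TRUE, auto = ge$auc < 0.5)
  fit <- if (use_le) build(-scores) else ge
  j <- fit$cand_tpr - fit$cand_fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[fit$cand_tpr[best] == max(fit$cand_tpr[best])]
  # candidates are in decreasing threshold order; for the ">=" rule the last
  # index is the lowest threshold, for "<=" (negated scores) the lowest
  # original threshold is the first index
  best <- if (use_le) best[1L] else best[length(best)]
  cutoff <- if (use_le) -fit$cand_thr[best] else fit$cand_thr[best]
  structure(list(
    thresholds = if (use_le) -fit$thresholds else fit$thresholds,
    tpr = fit$tpr, fpr = fit$fpr, auc = fit$auc,
    optimal_cutoff = cutoff, optimal_rule = if (use_le) "<=" else ">=",
    youden = max(j),
    sensitivity = fit$cand_tpr[best], specificity = 1 - fit$cand_fpr[best]
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f; optimal cutoff %s %.4g (sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$optimal_rule, x$optimal_cutoff,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Diagnostic statistics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value, in
#' percent at full precision (display rounds to one decimal). A statistic
#' with a zero denominator is returned as `NA` and flagged in the
#' `undefined` attribute instead of being silently zero.
#'
#' @param t A [confusion_table()].
#' @return Object of class `diag_stats`: `sensitivity`, `specificity`,
#'   `ppv`, `npv` (percent).
#' @export
diag_stats <- function(t) {
  if (!inherits(t, "confusion_table")) stopf("diag_stats: t must be a confusion_table")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(
    sensitivity = ratio(t$tp, t$tp + t$fn),
    specificity = ratio(t$tn, t$tn + t$fp),
    ppv = ratio(t$tp, t$tp + t$fp),
    npv = ratio(t$tn, t$tn + t$fn)
  )
  structure(out, undefined = names(out)[vapply(out, is.na, logical(1))],
            class = "diag_stats")
}

#' @export
print.diag_stats <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("<diag_stats> sens %s, spec %s, PPV %s, NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Reconstruct a 2x2 table from printed cohort summaries
#'
#' Given the total N, the number of reference-positive cases, the number of
#' test-positive cases, and the reported sensitivity, the implied table is
#' `tp = round(sens * n_positive)`, `fn = n_positive - tp`,
#' `fp = n_test_positive - tp`, `tn = n_total - n_positive - fp`.
#'
#' @param n_total,n_positive,n_test_positive Counts.
#' @param sensitivity Fraction in `[0, 1]`.
#' @return A [confusion_table()]; an inconsistency (negative implied cell)
#'   is an error naming the violated cell.
#' @export
table_from_summary <- function(n_total, n_positive, n_test_positive, sensitivity) {
  if (sensitivity < 0 || sensitivity > 1) {
    stopf("table_from_summary: sensitivity must be in [0, 1]")
  }
  tp <- round(sensitivity * n_positive)
  fn <- n_positive - tp
  fp <- n_test_positive - tp
  tn <- n_total - n_positive - fp
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) {
    stopf("table_from_summary: inconsistent summary, implied %s = %d is negative",
          names(cells)[cells < 0][1L], cells[cells < 0][1L])
  }
  confusion_table(tp, fp, fn, tn)
}

#' Reconstruct a 2x2 table from sensitivity and specificity
#'
#' Counterpart of [table_from_summary()] for summaries that print
#' sensitivity and specificity with the class sizes:
#' `tp = round(sens * n_positive)`, `tn = round(spec * n_negative)`.
#'
#' @param n_positive,n_negative Reference class sizes.
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return A [confusion_table()].
#' @export
table_from_rates <- function(n_positive, n_negative, sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stopf("table_from_rates: rates must be in [0, 1]")
  }
  tp <- round(sensitivity * n_positive)
  tn <- round(specificity * n_negative)
  confusion_table(tp, n_negative - tn, n_positive - tp, tn)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, per Lin's original definition (sample-moment variants
#' differ slightly). Interpretation bands in the reporting convention used
#' here: < 0.40 poor, 0.40-0.75 fair to good, > 0.75 excellent.
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @return CCC in `[-1, 1]`; `NA` (with a warning) when both variances and
#'   the mean difference are zero, where concordance is undefined.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("lin_ccc: x and y must be paired")
  if (length(x) < 2L) stopf("lin_ccc: need at least 2 pairs")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    warnf("lin_ccc: undefined (zero variance and equal means)")
    return(NA_real_)
  }
  2 * sxy / denom
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `d = x - y`; bias is `mean(d)` and the limits of
#' agreement are `bias +/- 1.96 * SD(d)` with the sample SD (n-1).
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @param ccc Optionally attach a concordance coefficient (computed with
#'   [lin_ccc()] when `TRUE`).
#' @return Object of class `agreement_result`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and `ccc` when requested.
#' @export
bland_altman <- function(x, y, ccc = FALSE) {
  if (length(x) != length(y)) stopf("bland_altman: x and y must be paired")
  if (length(x) < 2L) stopf("bland_altman: need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d),
                 ccc = if (isTRUE(ccc)) lin_ccc(x, y) else NULL),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.3f, 95%% LoA [%.3f, %.3f], n=%d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  if (!is.null(x$ccc)) cat(sprintf("  CCC %.3f\n", x$ccc))
  invisible(x)
}
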