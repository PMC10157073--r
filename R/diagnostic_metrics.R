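#' Confusion summary from counts
#'
#' Derives the full diagnostic metric set from confusion counts with +1 as the
#' positive class: sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced
#' accuracy (their mean), predictive values PPV = TP/(TP+FP) and
#' NPV = TN/(TN+FN), the number needed to diagnose NND = 1/(sens+spec-1)
#' (inverse Youden index; +Inf when the Youden index is not positive), the
#' predictive summary index PSI = PPV+NPV-1, and the number needed to predict
#' NNP = 1/PSI (+Inf when PSI is not positive). Ratios with zero denominators
#' are reported as `NA` (absent), never as 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return An object of class `confusion_summary`.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stopf("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  bac <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  youden <- if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else NA_real_
  psi <- if (!is.na(ppv) && !is.na(npv)) ppv + npv - 1 else NA_real_
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sens = sens, spec = spec, bac = bac,
    ppv = ppv, npv = npv,
    youden = youden,
    nnd = if (is.na(youden)) NA_real_ else if (youden > 0) 1 / youden else Inf,
    psi = psi,
    nnp = if (is.na(psi)) NA_real_ else if (psi > 0) 1 / psi else Inf,
    auc = NA_real_
  ), class = "confusion_summary")
}

#' Confusion summary from predicted labels
#'
#' @param true_labels,predicted_labels equal-length vectors in `{+1, -1}`.
#' @param decision_scores optional continuous scores used to attach a
#'   rank-based AUC.
#' @return A [confusion_from_counts()] summary.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels,
                                       decision_scores = NULL) {
  if (length(true_labels) == 0L) stopf("empty input")
  if (length(true_labels) != length(predicted_labels)) stopf("length mismatch")
  if (!all(c(true_labels, predicted_labels) %in% c(-1, 1))) {
    stopf("labels must be +1 or -1")
  }
  cs <- confusion_from_counts(
    tp = sum(true_labels == 1 & predicted_labels == 1),
    tn = sum(true_labels == -1 & predicted_labels == -1),
    fp = sum(true_labels == -1 & predicted_labels == 1),
    fn = sum(true_labels == 1 & predicted_labels == -1)
  )
  if (!is.null(decision_scores) && length(unique(true_labels)) == 2L) {
    cs$auc <- auc_from_scores(true_labels, decision_scores)
  }
  cs
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("sens=%.3f spec=%.3f BAC=%.3f PPV=%.3f NPV=%.3f\n",
              x$sens, x$spec, x$bac, x$ppv, x$npv))
  cat(sprintf("NND=%.2f PSI=%.3f NNP=%.2f AUC=%s\n", x$nnd, x$psi, x$nnp,
              if (is.na(x$auc)) "-" else sprintf("%.2f", x$auc)))
  invisible(x)
}

#' Rank-based AUC from decision scores
#'
#' The Mann-Whitney statistic divided by `n_pos * n_neg`; ties contribute 1/2
#' (midranks).
#'
#' @param true_labels vector in `{+1, -1}` with both classes present.
#' @param decision_scores numeric scores, higher favoring the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(true_labels, decision_scores) {
  if (length(true_labels) != length(decision_scores)) stopf("length mismatch")
  pos <- true_labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(decision_scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prevalence sweep of predictive values
#'
#' Recomputes PPV, NPV, PSI and NNP at assumed prevalences via Bayes' theorem:
#' `PPV(p) = sens*p / (sens*p + (1-spec)*(1-p))` and
#' `NPV(p) = spec*(1-p) / (spec*(1-p) + (1-sens)*p)`.
#'
#' In printed-rounding mode the sensitivity and specificity are first rounded
#' half-up to one percentage decimal, reproducing the arithmetic of published
#' prevalence tables whose entries were derived from rounded inputs; the
#' default uses full precision.
#'
#' @param sens,spec proportions in `[0, 1]`.
#' @param prevalences vector of assumed prevalences, each in `(0, 1)`.
#' @param printed_rounding round sens/spec to one percentage decimal first.
#' @return data.frame with columns `prevalence`, `ppv`, `npv`, `psi`, `nnp`.
#' @export
prevalence_sweep <- function(sens, spec,
                             prevalences = c(0.01, 0.05, 0.10, 0.20, 0.30,
                                             0.40, 0.50, 0.60, 0.70),
                             printed_rounding = FALSE) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) stopf("sens/spec must be in [0,1]")
  if (any(prevalences <= 0 | prevalences >= 1)) stopf("prevalences must be in (0,1)")
  if (printed_rounding) {
    sens <- round_half_up(100 * sens, 1) / 100
    spec <- round_half_up(100 * spec, 1) / 100
  }
  p <- prevalences
  ppv <- sens * p / (sens * p + (1 - spec) * (1 - p))
  npv <- spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)
  ppv[sens * p + (1 - spec) * (1 - p) == 0] <- NA_real_
  npv[spec * (1 - p) + (1 - sens) * p == 0] <- NA_real_
  psi <- ppv + npv - 1
  nnp <- ifelse(is.na(psi), NA_real_, ifelse(psi > 0, 1 / psi, Inf))
  data.frame(prevalence = p, ppv = ppv, npv = npv, psi = psi, nnp = nnp)
}

#' Format a prevalence sweep the way published tables print it
#'
#' Percentages rounded half-up to whole percent, NNP to two decimals.
#'
#' @param sweep output of [prevalence_sweep()].
#' @return data.frame with display-rounded columns.
#' @export
format_prevalence_table <- function(sweep) {
  data.frame(prevalence_pct = round_half_up(100 * sweep$prevalence),
             ppv_pct = round_half_up(100 * sweep$ppv),
             npv_pct = round_half_up(100 * sweep$npv),
             psi_pct = round_half_up(100 * sweep$psi),
             nnp = round_half_up(sweep$nnp, 2))
}
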