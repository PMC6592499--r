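#' Patient-wise cross-validation plan (Scenario A)
#'
#' Patients are randomly partitioned into `k` groups; each group serves
#' once as the test set while the remaining groups train. No patient ever
#' contributes windows to both sides of a fold, so the classifier always
#' faces new patients at test time. The partition is redrawn for every
#' repeat.
#'
#' @param patient_ids Character vector of patient identifiers (duplicates
#'   allowed; the unique set is partitioned).
#' @param k Number of folds.
#' @param repeats Number of independent repetitions.
#' @param seed Integer seed.
#' @return A `cv_plan` object.
#' @export
split_scenario_a <- function(patient_ids, k = 5, repeats = 10, seed = 1) {
  ids <- unique(as.character(patient_ids))
  check_number(k, "k", lower = 2)
  check_number(repeats, "repeats", lower = 1)
  if (length(ids) < k)
    stop_ppgaf(sprintf("need at least k = %d patients, got %d", k, length(ids)),
               "ppgaf_parameter_error")
  set.seed(seed)
  assign <- lapply(seq_len(repeats), function(r) {
    stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  })
  structure(list(scenario = "A", k = k, repeats = repeats, seed = seed,
                 assign = assign, patient_ids = ids),
            class = "cv_plan")
}

#' Sample-wise cross-validation plan (Scenario B)
#'
#' Windows (samples) are randomly partitioned into `k` folds regardless of
#' patient, so windows from the same patient can appear in both training
#' and test sets — emulating a training distribution that matches the test
#' distribution. Folds are stratified by label to keep the class balance.
#'
#' @param labels Window labels (`"AF"`/`"SR"`); their length defines the
#'   number of windows.
#' @param k,repeats,seed As in [split_scenario_a()].
#' @param stratify Stratify fold assignment by label (default `TRUE`).
#' @return A `cv_plan` object.
#' @export
split_scenario_b <- function(labels, k = 5, repeats = 10, seed = 1,
                             stratify = TRUE) {
  n <- length(labels)
  check_number(k, "k", lower = 2)
  check_number(repeats, "repeats", lower = 1)
  if (n < k)
    stop_ppgaf(sprintf("need at least k = %d windows, got %d", k, n),
               "ppgaf_parameter_error")
  set.seed(seed)
  assign <- lapply(seq_len(repeats), function(r) {
    fold <- integer(n)
    if (stratify) {
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
  structure(list(scenario = "B", k = k, repeats = repeats, seed = seed,
                 assign = assign, n = n),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  what <- if (x$scenario == "A") "patient-wise" else "sample-wise"
  cat(sprintf("<cv_plan> Scenario %s (%s): %d-fold x %d repeats (seed %s)\n",
              x$scenario, what, x$k, x$repeats, format(x$seed)))
  invisible(x)
}

#' Test-set membership for one fold of a plan
#'
#' @param plan A `cv_plan`.
#' @param meta Window metadata with a `patient_id` column (Scenario A) or
#'   one row per window (Scenario B).
#' @param rep,fold Repeat and fold indices.
#' @return Logical vector over windows: `TRUE` where the window is in the
#'   test set.
#' @export
test_windows <- function(plan, meta, rep, fold) {
  stopifnot(inherits(plan, "cv_plan"))
  if (plan$scenario == "A") {
    unname(plan$assign[[rep]][meta$patient_id] == fold)
  } else {
    plan$assign[[rep]] == fold
  }
}

#' Core diagnostic rates
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value of AF-vs-SR window diagnoses, as percentages. AF is the positive
#' class: sensitivity is the fraction of AF-labelled windows diagnosed AF,
#' specificity the fraction of SR-labelled windows diagnosed SR. A rate
#' whose denominator is empty is reported as `NA` (undefined), never 0.
#'
#' @param predicted,labels Vectors of `"AF"`/`"SR"` values.
#' @param positive Positive class (default `"AF"`).
#' @return List: `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percent) and the confusion counts `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
classifier_metrics <- function(predicted, labels, positive = "AF") {
  predicted <- as.character(predicted); labels <- as.character(labels)
  if (length(predicted) != length(labels) || length(labels) == 0)
    stop_ppgaf("'predicted' and 'labels' must be non-empty and equal length",
               "ppgaf_input_error")
  is_pos <- labels == positive
  pred_pos <- predicted == positive
  tp <- sum(is_pos & pred_pos); fn <- sum(is_pos & !pred_pos)
  fp <- sum(!is_pos & pred_pos); tn <- sum(!is_pos & !pred_pos)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(accuracy = rate(tp + tn, length(labels)),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn, n = length(labels))
}

#' Empirical ROC curve
#'
#' @param scores Numeric scores, larger meaning more AF-like.
#' @param labels `"AF"`/`"SR"` labels.
#' @param positive Positive class.
#' @return Data frame of (`fpr`, `tpr`) points from (0,0) to (1,1), one per
#'   distinct score threshold.
#' @export
roc_curve <- function(scores, labels, positive = "AF") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop_ppgaf("ROC needs both classes present", "ppgaf_input_error")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord] == positive
  tp <- cumsum(y); fp <- cumsum(!y)
  # collapse ties: keep the last point of each tied score block
  last <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!y)), tpr = c(0, tp[last] / sum(y)))
}

#' Area under the ROC curve (midrank Mann-Whitney estimator)
#'
#' The AUC equals the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`, with ties handled by midranks — identical to the
#' trapezoidal area under the empirical ROC.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels, positive = "AF") {
  labels <- as.character(labels)
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0)
    stop_ppgaf("AUC needs both classes present", "ppgaf_input_error")
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

# structural components of the AUC (placements), rank-based
delong_components <- function(scores, labels, positive = "AF") {
  labels <- as.character(labels)
  pos <- which(labels == positive); neg <- which(labels != positive)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0)
    stop_ppgaf("DeLong components need both classes", "ppgaf_input_error")
  r_all <- rank(c(scores[pos], scores[neg]))
  v10 <- (r_all[seq_len(m)] - rank(scores[pos])) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(scores[neg])) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong variance and confidence interval of one AUC
#'
#' @inheritParams roc_curve
#' @param level Confidence level.
#' @return List: `auc`, `se`, `ci` (length 2, clipped to \[0, 1\]).
#' @export
auc_ci <- function(scores, labels, positive = "AF", level = 0.95) {
  cm <- delong_components(scores, labels, positive)
  v <- stats::var(cm$v10) / cm$m + stats::var(cm$v01) / cm$n
  se <- sqrt(v)
  zq <- qnorm(1 - (1 - level) / 2)
  list(auc = cm$auc, se = se,
       ci = c(max(0, cm$auc - zq * se), min(1, cm$auc + zq * se)))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two classifiers scored on the *same* test windows,
#' using the structural-component covariance estimate for correlated ROC
#' curves. Two-sided.
#'
#' @param scores_1,scores_2 Paired score vectors (same windows, same
#'   order).
#' @param labels Window labels.
#' @param positive Positive class.
#' @return List: `auc1`, `auc2`, `se1`, `se2`, `ci1`, `ci2`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_1, scores_2, labels, positive = "AF") {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stop_ppgaf("DeLong requires paired scores on identical test windows",
               "ppgaf_input_error")
  c1 <- delong_components(scores_1, labels, positive)
  c2 <- delong_components(scores_2, labels, positive)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var1 <- s10[1, 1] / c1$m + s01[1, 1] / c1$n
  var2 <- s10[2, 2] / c1$m + s01[2, 2] / c1$n
  cov12 <- s10[1, 2] / c1$m + s01[1, 2] / c1$n
  var_diff <- var1 + var2 - 2 * cov12
  d <- c1$auc - c2$auc
  z <- if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  zq <- qnorm(0.975)
  list(auc1 = c1$auc, auc2 = c2$auc,
       se1 = sqrt(var1), se2 = sqrt(var2),
       ci1 = c(max(0, c1$auc - zq * sqrt(var1)), min(1, c1$auc + zq * sqrt(var1))),
       ci2 = c(max(0, c2$auc - zq * sqrt(var2)), min(1, c2$auc + zq * sqrt(var2))),
       var_diff = var_diff, z = z, p = 2 * pnorm(-abs(z)))
}

#' Specificity stratified by PAC burden
#'
#' SR-labelled test windows are binned by their PAC burden and the
#' specificity (fraction diagnosed SR) is computed per bin — the analysis
#' showing how false AF alarms concentrate in windows with frequent
#' ectopy.
#'
#' @param predicted Predicted labels for SR-labelled windows.
#' @param burden PAC burden of the same windows, as fractions in \[0, 1\].
#' @param edges Lower bin edges in percent (default `c(0, 5, 10, 15, 20)`;
#'   the last bin is open-ended).
#' @return Data frame: `bin` (label), `lo`, `hi` (percent), `n`,
#'   `specificity` (percent, `NA` for empty bins).
#' @export
burden_stratified_specificity <- function(predicted, burden,
                                          edges = c(0, 5, 10, 15, 20)) {
  predicted <- as.character(predicted)
  if (length(predicted) != length(burden))
    stop_ppgaf("'predicted' and 'burden' must be equal length", "ppgaf_input_error")
  pct <- 100 * burden
  breaks <- c(edges, Inf)
  bin <- findInterval(pct, breaks, rightmost.closed = FALSE)
  bin[bin < 1] <- 1L
  n_bins <- length(edges)
  lab <- c(sprintf("[%g,%g)", edges[-n_bins], edges[-1]),
           sprintf(">=%g", edges[n_bins]))
  out <- data.frame(bin = lab, lo = edges,
                    hi = c(edges[-1], Inf), n = 0L, specificity = NA_real_)
  for (b in seq_len(n_bins)) {
    sel <- bin == b & !is.na(pct)
    out$n[b] <- sum(sel)
    if (out$n[b] > 0)
      out$specificity[b] <- 100 * mean(predicted[sel] == "SR")
  }
  out
}

#' Confidence-level analysis of a set of diagnoses
#'
#' Splits confidence levels (CLs) by diagnostic correctness (the "true CL"
#' of correct diagnoses versus the "false CL" of misdiagnoses), computes
#' the accuracy restricted to confident diagnoses (CL at or above the
#' cut-off) and the share of such diagnoses, and tabulates the
#' misdiagnosis probability per CL bin — for a calibrated classifier the
#' misdiagnosis probability at CL x is about 100 - x.
#'
#' @param cl Confidence levels in percent (50--100).
#' @param correct Logical: was each diagnosis correct?
#' @param cutoff Confidence cut-off in percent (default 95).
#' @param bin_width Width of the CL histogram bins, percent.
#' @return List: `mean_true_cl`, `mean_false_cl`, `median_true_cl`,
#'   `median_false_cl`, `n_true`, `n_false`, `cutoff`, `cutoff_accuracy`,
#'   `share_above_cutoff` (all percentages; false-CL summaries are `NA`
#'   when nothing was misdiagnosed) and `bins` (data frame: `cl_lo`,
#'   `cl_hi`, `n`, `misdiagnosis_pct`).
#' @export
cl_analysis <- function(cl, correct, cutoff = 95, bin_width = 5) {
  if (length(cl) != length(correct) || length(cl) == 0)
    stop_ppgaf("'cl' and 'correct' must be non-empty and equal length",
               "ppgaf_input_error")
  if (any(cl < 50 - 1e-9 | cl > 100 + 1e-9))
    stop_ppgaf("confidence levels must lie in [50, 100]", "ppgaf_input_error")
  tru <- cl[correct]; fls <- cl[!correct]
  hi_conf <- cl >= cutoff
  edges <- seq(50, 100, by = bin_width)
  bin <- pmin(findInterval(cl, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  bins <- data.frame(cl_lo = edges[-length(edges)], cl_hi = edges[-1],
                     n = 0L, misdiagnosis_pct = NA_real_)
  for (b in seq_len(nrow(bins))) {
    sel <- bin == b
    bins$n[b] <- sum(sel)
    if (bins$n[b] > 0)
      bins$misdiagnosis_pct[b] <- 100 * mean(!correct[sel])
  }
  list(mean_true_cl = if (length(tru)) mean(tru) else NA_real_,
       mean_false_cl = if (length(fls)) mean(fls) else NA_real_,
       median_true_cl = if (length(tru)) median(tru) else NA_real_,
       median_false_cl = if (length(fls)) median(fls) else NA_real_,
       n_true = length(tru), n_false = length(fls),
       cutoff = cutoff,
       cutoff_accuracy = if (any(hi_conf)) 100 * mean(correct[hi_conf]) else NA_real_,
       share_above_cutoff = 100 * mean(hi_conf),
       bins = bins)
}
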