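#' Assemble the analysis-ready dataset from a cohort
#'
#' Runs the full front end once — conditioning and segmentation, beat
#' detection, baseline feature extraction, and resampling to the deep
#' classifiers' input rate — so that cross-validation experiments can reuse
#' the same windows.
#'
#' @param cohort An `af_cohort` (or list of `ppg_record`s).
#' @param win,overlap Segmentation parameters, seconds.
#' @param fs_dl Input rate of the deep classifiers, Hz.
#' @param n_lags Autocorrelation feature count.
#' @return An `af_dataset`: `meta` (window metadata plus detected PAC
#'   burden), `features` (baseline feature frame), `x_dl` (window matrix at
#'   `fs_dl`), `labels` (factor), and the ground-truth `truth` list when
#'   the cohort carries annotations.
#' @export
build_af_dataset <- function(cohort, win = 30, overlap = 20, fs_dl = 40,
                             n_lags = 30) {
  w <- preprocess_cohort(cohort, win = win, overlap = overlap)
  feat <- window_features(w, n_lags = n_lags)
  meta <- w$meta
  meta$burden <- feat$burden
  structure(
    list(meta = meta,
         features = feat,
         x_dl = dl_input(w, fs_out = fs_dl, win = win),
         labels = factor(meta$label, levels = c("SR", "AF")),
         truth = w$truth, fs = w$fs, fs_dl = fs_dl, win = win,
         n_lags = n_lags),
    class = "af_dataset"
  )
}

#' @export
print.af_dataset <- function(x, ...) {
  tab <- table(x$meta$label)
  cat(sprintf("<af_dataset> %d windows (%s) from %d patients\n",
              nrow(x$meta),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$meta$patient_id))))
  invisible(x)
}

.AF_MODELS <- c("cnn", "rnn", "svm_rmssd_she", "svm_acf", "svm_ensemble")

fit_one_model <- function(model, ds, train_idx, seed, dl_config = list()) {
  if (model %in% c("cnn", "rnn")) {
    cfg <- do.call(af_net_config,
                   c(list(arch = model), dl_config, list(seed = seed)))
    af_net(ds$x_dl[train_idx, , drop = FALSE],
           ds$labels[train_idx], config = cfg)
  } else {
    fset <- sub("^svm_", "", model)
    af_svm(ds$features[train_idx, , drop = FALSE], ds$labels[train_idx],
           feature_set = fset, n_lags = ds$n_lags)
  }
}

predict_one_model <- function(fit, ds, test_idx) {
  if (inherits(fit, "af_net")) {
    d <- predict(fit, ds$x_dl[test_idx, , drop = FALSE])
    data.frame(score = d$p_af, predicted = d$predicted, cl = d$cl)
  } else {
    d <- predict(fit, ds$features[test_idx, , drop = FALSE])
    data.frame(score = d$score, predicted = d$predicted, cl = NA_real_)
  }
}

#' Run a repeated cross-validation experiment
#'
#' Evaluates the selected classifiers under one cross-validation scenario:
#' per repeat, the data are split into `k` folds ([split_scenario_a()] or
#' [split_scenario_b()]); every model is trained on each fold's training
#' side and scored on its test side, so all models see identical fold
#' assignments and their pooled test scores are paired (as the DeLong test
#' requires). Diagnostic rates are computed per fold and averaged over all
#' `k * repeats` validations; the AUC is computed on the scores pooled
#' within each repeat (each window scored exactly once per repeat) and
#' averaged over repeats.
#'
#' @param ds An [build_af_dataset()] result.
#' @param scenario `"A"` (patient-wise) or `"B"` (sample-wise).
#' @param models Subset of `c("cnn", "rnn", "svm_rmssd_she", "svm_acf",
#'   "svm_ensemble")`.
#' @param k Folds per repeat.
#' @param repeats Repeats.
#' @param seed Integer seed; drives the fold draws and each fit's
#'   initialisation.
#' @param dl_config List of [af_net_config()] overrides applied to both
#'   deep models.
#' @param verbose Progress messages.
#' @return An `af_eval` object: per-model fold metrics, per-repeat AUCs,
#'   pooled per-window predictions, burden-stratified specificity and
#'   confidence-level analysis.
#' @export
run_af_experiment <- function(ds, scenario = c("A", "B"),
                              models = c("cnn", "rnn", "svm_rmssd_she"),
                              k = 5, repeats = 10, seed = 1,
                              dl_config = list(), verbose = FALSE) {
  stopifnot(inherits(ds, "af_dataset"))
  scenario <- match.arg(scenario)
  models <- match.arg(models, .AF_MODELS, several.ok = TRUE)
  plan <- if (scenario == "A")
    split_scenario_a(ds$meta$patient_id, k = k, repeats = repeats, seed = seed)
  else
    split_scenario_b(ds$meta$label, k = k, repeats = repeats, seed = seed)

  fold_metrics <- list(); pooled <- list()
  for (m in models) { fold_metrics[[m]] <- list(); pooled[[m]] <- list() }

  for (r in seq_len(plan$repeats)) {
    rep_pred <- lapply(models, function(m)
      data.frame(window = integer(0), score = numeric(0),
                 predicted = character(0), cl = numeric(0)))
    names(rep_pred) <- models
    for (f in seq_len(plan$k)) {
      te <- test_windows(plan, ds$meta, r, f)
      tr_idx <- which(!te); te_idx <- which(te)
      for (mi in seq_along(models)) {
        m <- models[mi]
        fit_seed <- seed * 10000L + r * 1000L + f * 10L + mi
        fit <- fit_one_model(m, ds, tr_idx, fit_seed, dl_config)
        pr <- predict_one_model(fit, ds, te_idx)
        mt <- classifier_metrics(pr$predicted, ds$meta$label[te_idx])
        fold_metrics[[m]][[length(fold_metrics[[m]]) + 1]] <-
          data.frame(repeat_ = r, fold = f, n = mt$n,
                     accuracy = mt$accuracy, sensitivity = mt$sensitivity,
                     specificity = mt$specificity, ppv = mt$ppv, npv = mt$npv)
        rep_pred[[m]] <- rbind(rep_pred[[m]],
                               data.frame(window = te_idx, score = pr$score,
                                          predicted = as.character(pr$predicted),
                                          cl = pr$cl))
        if (verbose)
          message(sprintf("scenario %s repeat %d fold %d %s: acc %.2f%%",
                          scenario, r, f, m, mt$accuracy))
      }
    }
    for (m in models) {
      rp <- rep_pred[[m]]
      rp <- rp[order(rp$window), ]
      rp$repeat_ <- r
      pooled[[m]][[r]] <- rp
    }
  }

  results <- list()
  for (m in models) {
    fm <- do.call(rbind, fold_metrics[[m]])
    pool <- do.call(rbind, pooled[[m]])
    auc_per_repeat <- vapply(seq_len(plan$repeats), function(r) {
      rp <- pooled[[m]][[r]]
      auc_mw(rp$score, ds$meta$label[rp$window])
    }, numeric(1))
    sr <- ds$meta$label[pool$window] == "SR"
    burden_spec <- burden_stratified_specificity(
      pool$predicted[sr], ds$meta$burden[pool$window][sr])
    cl_an <- if (!all(is.na(pool$cl)))
      cl_analysis(pool$cl, pool$predicted == ds$meta$label[pool$window])
    else NULL
    results[[m]] <- list(
      fold_metrics = fm,
      mean_metrics = colMeans(fm[, c("accuracy", "sensitivity", "specificity",
                                     "ppv", "npv")], na.rm = TRUE),
      auc_per_repeat = auc_per_repeat,
      auc = mean(auc_per_repeat),
      predictions = pool,
      burden_specificity = burden_spec,
      cl = cl_an)
  }
  structure(list(scenario = scenario, k = plan$k, repeats = plan$repeats,
                 seed = seed, models = models, results = results,
                 labels = ds$meta$label, burden = ds$meta$burden),
            class = "af_eval")
}

#' @export
print.af_eval <- function(x, ...) {
  cat(sprintf("<af_eval> Scenario %s: %d-fold x %d repeats, %d models\n",
              x$scenario, x$k, x$repeats, length(x$models)))
  print(af_report(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summary table of an evaluation
#'
#' One row per classifier: rates averaged over all validations, the mean
#' AUC with its DeLong 95\% CI (from the first repeat's pooled scores), and
#' the mean confidence level of correct versus incorrect diagnoses where
#' the model provides one.
#'
#' @param x An `af_eval` (or several, whose rows are concatenated with a
#'   scenario column).
#' @param ... Further `af_eval` objects.
#' @return A data frame.
#' @export
af_report <- function(x, ...) {
  evals <- c(list(x), list(...))
  rows <- list()
  for (ev in evals) {
    for (m in ev$models) {
      res <- ev$results[[m]]
      ci <- auc_ci(res$predictions$score[res$predictions$repeat_ == 1],
                   ev$labels[res$predictions$window[res$predictions$repeat_ == 1]])
      rows[[length(rows) + 1]] <- data.frame(
        scenario = ev$scenario, model = m,
        accuracy = res$mean_metrics["accuracy"],
        sensitivity = res$mean_metrics["sensitivity"],
        specificity = res$mean_metrics["specificity"],
        ppv = res$mean_metrics["ppv"], npv = res$mean_metrics["npv"],
        auc = res$auc, auc_ci_lo = ci$ci[1], auc_ci_hi = ci$ci[2],
        true_cl = if (!is.null(res$cl)) res$cl$mean_true_cl else NA_real_,
        false_cl = if (!is.null(res$cl)) res$cl$mean_false_cl else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DeLong comparison of two evaluated classifiers
#'
#' Uses the pooled scores of one repeat, where all models were tested on
#' identical fold assignments, so the pairing assumption holds.
#'
#' @param eval An `af_eval` containing both models.
#' @param model_1,model_2 Model names.
#' @param rep Repeat whose pooled scores are compared.
#' @return See [delong_test()].
#' @export
delong_compare <- function(eval, model_1, model_2, rep = 1) {
  stopifnot(inherits(eval, "af_eval"))
  p1 <- eval$results[[model_1]]$predictions
  p2 <- eval$results[[model_2]]$predictions
  p1 <- p1[p1$repeat_ == rep, ]; p2 <- p2[p2$repeat_ == rep, ]
  stopifnot(identical(p1$window, p2$window))
  delong_test(p1$score, p2$score, eval$labels[p1$window])
}

#' @export
plot.af_eval <- function(x, rep = 1, ...) {
  cols <- seq_along(x$models)
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC, scenario %s", x$scenario), ...)
  for (i in seq_along(x$models)) {
    p <- x$results[[x$models[i]]]$predictions
    p <- p[p$repeat_ == rep, ]
    rc <- roc_curve(p$score, x$labels[p$window])
    lines(rc$fpr, rc$tpr, col = cols[i], lwd = 2)
  }
  legend("bottomright", legend = x$models, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Bar plot of burden-stratified specificity
#'
#' @param eval An `af_eval`.
#' @param models Models to show (default: all in the evaluation).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_burden_specificity <- function(eval, models = eval$models, ...) {
  mat <- do.call(rbind, lapply(models, function(m)
    eval$results[[m]]$burden_specificity$specificity))
  colnames(mat) <- eval$results[[models[1]]]$burden_specificity$bin
  rownames(mat) <- models
  barplot(mat, beside = TRUE, col = seq_along(models),
          ylab = "specificity (%)", xlab = "PAC burden bin",
          legend.text = models, ylim = c(0, 100), ...)
  invisible(mat)
}
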