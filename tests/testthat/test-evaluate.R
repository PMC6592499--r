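test_that("patient-wise folds partition patients with no leakage", {
  ids <- sprintf("P%03d", 1:75)
  plan <- split_scenario_a(ids, k = 5, repeats = 3, seed = 2)
  for (r in 1:3) {
    a <- plan$assign[[r]]
    expect_setequal(names(a), ids)
    expect_equal(unname(table(a)), rep(15L, 5), ignore_attr = TRUE)
    meta <- data.frame(patient_id = rep(ids, each = 4))
    for (f in 1:5) {
      te <- test_windows(plan, meta, r, f)
      expect_length(intersect(unique(meta$patient_id[te]),
                              unique(meta$patient_id[!te])), 0)
    }
    # union of test folds covers every window exactly once
    cover <- rowSums(vapply(1:5, function(f) test_windows(plan, meta, r, f),
                            logical(nrow(meta))))
    expect_true(all(cover == 1))
  }
  expect_error(split_scenario_a(ids[1:3], k = 5), class = "ppgaf_parameter_error")
})

test_that("sample-wise folds give stratified 80/20 splits, reproducibly", {
  labs <- rep(c("AF", "SR"), each = 700)
  plan <- split_scenario_b(labs, k = 5, repeats = 2, seed = 3)
  meta <- data.frame(patient_id = "x")
  for (r in 1:2) {
    for (f in 1:5) {
      te <- plan$assign[[r]] == f
      expect_equal(sum(te), 280)
      expect_equal(sum(te & labs == "AF"), 140)
    }
  }
  plan2 <- split_scenario_b(labs, k = 5, repeats = 2, seed = 3)
  expect_identical(plan$assign, plan2$assign)
})

test_that("diagnostic rates follow their definitions exactly", {
  labels <- c(rep("AF", 10), rep("SR", 10))
  pred <- c(rep("AF", 9), "SR", rep("SR", 8), "AF", "AF")
  m <- classifier_metrics(pred, labels)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$ppv, 100 * 9 / 11)
  expect_equal(m$npv, 100 * 8 / 9)
  expect_equal(m$accuracy, 85)
  expect_equal(m$tp + m$fn + m$tn + m$fp, m$n)

  perf <- classifier_metrics(labels, labels)
  expect_true(all(unlist(perf[c("accuracy", "sensitivity", "specificity",
                                "ppv", "npv")]) == 100))
  always_af <- classifier_metrics(rep("AF", 20), labels)
  expect_equal(always_af$sensitivity, 100)
  expect_equal(always_af$specificity, 0)
  expect_true(is.na(always_af$npv))   # undefined, not zero
  one_class <- classifier_metrics(rep("AF", 5), rep("AF", 5))
  expect_true(is.na(one_class$specificity))
})

test_that("AUC: separation gives 1, independence gives 1/2", {
  expect_equal(auc_mw(c(1, 2, 3, 10, 11, 12),
                      c("SR", "SR", "SR", "AF", "AF", "AF")), 1)
  set.seed(5)
  n <- 4000
  expect_equal(auc_mw(rnorm(n), sample(rep(c("AF", "SR"), n / 2))), 0.5,
               tolerance = 0.03)
  expect_error(auc_mw(1:5, rep("AF", 5)), class = "ppgaf_input_error")
})

test_that("trapezoidal ROC area equals the midrank Mann-Whitney estimate", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labs <- c(rep("AF", ceiling(n / 3) + 1), rep("SR", n))
    # discretised scores force ties to exercise the midrank convention
    sc <- round(c(rnorm(ceiling(n / 3) + 1, 0.8), rnorm(n)), 1)
    expect_equal(trapezoid_auc(sc, labs), auc_mw(sc, labs),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(8)
  sc <- rnorm(100); labs <- rep(c("AF", "SR"), 50)
  rc <- roc_curve(sc, labs)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(tail(rc$fpr, 1), 1); expect_equal(tail(rc$tpr, 1), 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("the DeLong test is null for self- and monotone-transformed scores", {
  set.seed(9)
  sc <- rnorm(120)
  labs <- rep(c("AF", "SR"), 60)
  self <- delong_test(sc, sc, labs)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  mono <- delong_test(sc, exp(2 * sc) + 3, labs)
  expect_equal(mono$auc1, mono$auc2)
  expect_equal(mono$z, 0)
  expect_error(delong_test(sc, sc[-1], labs), class = "ppgaf_input_error")
})

test_that("DeLong variance agrees with a stratified bootstrap", {
  set.seed(10)
  n_pos <- 90; n_neg <- 110
  sc <- c(rnorm(n_pos, 1), rnorm(n_neg, 0))
  labs <- c(rep("AF", n_pos), rep("SR", n_neg))
  dl <- auc_ci(sc, labs)
  boot <- replicate(2000, {
    s <- c(sample(sc[1:n_pos], n_pos, replace = TRUE),
           sample(sc[-(1:n_pos)], n_neg, replace = TRUE))
    auc_mw(s, labs)
  })
  expect_lt(abs(dl$se^2 - var(boot)) / var(boot), 0.15)
})

test_that("DeLong quantities match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  labs <- rep(c("AF", "SR"), 75)
  s1 <- rnorm(150) + (labs == "AF") * 1.2
  s2 <- rnorm(150) + (labs == "AF") * 0.8
  ours <- delong_test(s1, s2, labs)
  ref <- pROC::roc.test(pROC::roc(labs, s1, levels = c("SR", "AF"),
                                  direction = "<", quiet = TRUE),
                        pROC::roc(labs, s2, levels = c("SR", "AF"),
                                  direction = "<", quiet = TRUE),
                        method = "delong")
  expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  ci <- auc_ci(s1, labs)
  expect_equal(ci$ci, as.numeric(pROC::ci.auc(pROC::roc(labs, s1,
    levels = c("SR", "AF"), direction = "<", quiet = TRUE),
    method = "delong"))[c(1, 3)], tolerance = 1e-9)
})

test_that("burden-stratified specificity partitions SR windows", {
  set.seed(12)
  n <- 500
  burden <- c(rep(0, 300), runif(200, 0, 0.35))
  pred <- rep("SR", n)
  bs <- burden_stratified_specificity(pred, burden)
  expect_equal(sum(bs$n), n)
  expect_true(all(bs$specificity[bs$n > 0] == 100))
  # misdiagnoses only in the top bin drop only that bin
  pred2 <- pred
  top <- burden >= 0.20
  pred2[which(top)[1:5]] <- "AF"
  bs2 <- burden_stratified_specificity(pred2, burden)
  expect_lt(bs2$specificity[5], 100)
  expect_true(all(bs2$specificity[1:4] == 100))
  # empty bins are reported as undefined with n = 0
  bs3 <- burden_stratified_specificity(rep("SR", 3), rep(0, 3))
  expect_equal(bs3$n[5], 0)
  expect_true(is.na(bs3$specificity[5]))
})

test_that("confidence-level analysis summarises calibration", {
  perfect <- cl_analysis(rep(100, 50), rep(TRUE, 50))
  expect_equal(perfect$mean_true_cl, 100)
  expect_equal(perfect$cutoff_accuracy, 100)
  expect_equal(perfect$share_above_cutoff, 100)
  expect_true(is.na(perfect$mean_false_cl))

  # a calibrated classifier: misdiagnosis probability at CL x is 100 - x
  set.seed(13)
  cl <- runif(40000, 50, 100)
  correct <- rbinom(length(cl), 1, cl / 100) == 1
  an <- cl_analysis(cl, correct)
  mid <- (an$bins$cl_lo + an$bins$cl_hi) / 2
  expect_equal(an$bins$misdiagnosis_pct, 100 - mid, tolerance = 2.5)
  expect_gt(an$mean_true_cl, an$mean_false_cl)
})
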