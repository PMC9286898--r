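test_that("confusion counts partition the set and swap with the class", {
  cc <- confusion_counts(rep(c("positive", "negative"), c(10, 10)),
                         rep(c("positive", "negative"), c(10, 10)))
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 10L, FP = 0L, TN = 10L, FN = 0L))

  cc <- confusion_counts(rep("positive", 10),
                         rep(c("positive", "negative"), c(4, 6)))
  expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), c(4, 6, 0, 0))

  set.seed(13)
  for (i in 1:10) {
    pred <- sample(c("positive", "negative"), 30, replace = TRUE)
    truth <- sample(c("positive", "negative"), 30, replace = TRUE)
    a <- confusion_counts(pred, truth, "positive")
    b <- confusion_counts(pred, truth, "negative")
    # brute-force pairwise tally
    expect_equal(a$TP, sum(pred == "positive" & truth == "positive"))
    expect_equal(a$FN, sum(pred == "negative" & truth == "positive"))
    # orientation swap: TP<->TN, FP<->FN
    expect_equal(c(a$TP, a$FP), c(b$TN, b$FN))
    expect_equal(a$TP + a$FP + a$TN + a$FN, 30)
  }

  expect_error(confusion_counts("positive", c("positive", "negative")),
               "lengths")
  expect_error(confusion_counts("positive", NA), "NA")
})

test_that("metrics match their definitions on canonical cases", {
  perfect <- structure(list(TP = 50, FP = 0, TN = 50, FN = 0),
                       class = "confusion_counts")
  m <- classification_metrics(perfect)
  expect_equal(unlist(m), c(acc = 1, pre = 1, sen = 1, f_measure = 1, mcc = 1))

  chance <- structure(list(TP = 25, FP = 25, TN = 25, FN = 25),
                      class = "confusion_counts")
  m <- classification_metrics(chance)
  expect_equal(m$acc, 0.5)
  expect_equal(m$mcc, 0)

  # F-measure is the harmonic mean of precision and sensitivity
  set.seed(17)
  for (i in 1:25) {
    cnt <- structure(as.list(setNames(sample(1:20, 4, replace = TRUE),
                                      c("TP", "FP", "TN", "FN"))),
                     class = "confusion_counts")
    m <- classification_metrics(cnt)
    expect_equal(m$f_measure, 2 / (1 / m$pre + 1 / m$sen))
  }

  # zero denominators give NA, never 0
  never_pos <- structure(list(TP = 0, FP = 0, TN = 9, FN = 3),
                         class = "confusion_counts")
  m <- classification_metrics(never_pos)
  expect_true(is.na(m$pre))
  expect_true(is.na(m$mcc))
  expect_equal(m$acc, 0.75)

  # MCC is symmetric under simultaneous TP<->TN, FP<->FN swap
  a <- classification_metrics(structure(list(TP = 7, FP = 2, TN = 11, FN = 5),
                                        class = "confusion_counts"))
  b <- classification_metrics(structure(list(TP = 11, FP = 5, TN = 7, FN = 2),
                                        class = "confusion_counts"))
  expect_equal(a$mcc, b$mcc)

  # the audit-only unnormalized variant
  m <- classification_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                                        class = "confusion_counts"),
                              legacy_mcc = TRUE)
  expect_equal(m$mcc_legacy, (3 * 4 - 1 * 2) / ((3 + 1) * (3 + 2) * (4 + 2)))
})

test_that("AUC equals the Mann-Whitney statistic and the ROC trapezoid", {
  truth <- rep(c("positive", "negative"), c(4, 4))
  expect_equal(roc_auc(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0.1), truth), 1)
  expect_equal(roc_auc(rep(0.7, 8), truth), 0.5)

  trapezoid <- function(curve) {
    sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  }
  set.seed(19)
  for (i in 1:30) {
    n <- 8
    truth <- sample(rep(c("positive", "negative"), c(3, n - 3)))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    got <- roc_auc(scores, truth)
    expect_equal(got, auc_bruteforce(scores, truth))
    expect_equal(got, trapezoid(roc_curve(scores, truth)))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * scores) - 1, truth), got)
  }

  # cross-check against an independent ROC implementation
  set.seed(23)
  scores <- runif(60)
  truth <- sample(c("positive", "negative"), 60, replace = TRUE,
                  prob = c(0.4, 0.6))
  expect_equal(roc_auc(scores, truth),
               as.numeric(pROC::auc(pROC::roc(
                 truth, scores, levels = c("negative", "positive"),
                 direction = "<", quiet = TRUE))))

  expect_error(roc_auc(runif(5), rep("positive", 5)), "both classes")
})

test_that("metric reports combine thresholded counts, per-class views and AUC", {
  probs <- c(0.9, 0.8, 0.6, 0.5, 0.4, 0.2)
  truth <- c("positive", "positive", "negative", "positive", "negative",
             "negative")
  rep <- metric_report(probs, truth)
  # 0.5 is not above the threshold: that positive becomes a false negative
  expect_equal(c(rep$counts$TP, rep$counts$FP, rep$counts$TN, rep$counts$FN),
               c(2, 1, 2, 1))
  expect_equal(rep$acc, 4 / 6)

  # the negative-class view equals the positive-class view on flipped labels
  # (scores kept off the threshold so the strict-> rule is symmetric)
  probs_nt <- c(0.9, 0.8, 0.6, 0.45, 0.4, 0.2)
  rep_nt <- metric_report(probs_nt, truth)
  rep_flip <- metric_report(1 - probs_nt,
                            ifelse(truth == "positive", "negative",
                                   "positive"))
  expect_equal(rep_nt$per_class$negative[c("pre", "sen", "f_measure")],
               rep_flip$per_class$positive[c("pre", "sen", "f_measure")])

  # 0/1 truth coding is accepted
  rep01 <- metric_report(probs, c(1, 1, 0, 1, 0, 0))
  expect_equal(as.data.frame(rep01), as.data.frame(rep))
})

test_that("relative improvement and drop reproduce published comparisons", {
  # sensitivity 0.956 vs 0.933 and MCC 0.920 vs 0.839
  expect_equal(relative_improvement(0.956, 0.933), 2.465)
  expect_equal(relative_improvement(0.920, 0.839), 9.654)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  # accuracy 0.960 -> 0.909 and AUC 0.964 -> 0.948
  expect_equal(relative_drop(0.960, 0.909), 5.312)
  expect_equal(relative_drop(0.964, 0.948), 1.660)
  expect_equal(relative_drop(0.5, 0.5), 0)
  expect_error(relative_improvement(0.9, 0), "baseline")
  expect_error(relative_drop(-1, 0.5), "original")
})
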