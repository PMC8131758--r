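test_that("confusion counts match a hand tally and conserve totals", {
  truth <- c("MONO", "MONO", "BN", "BN", "BN_MN", "POLY", "IRREG", "MONO_MN",
             "BN", "MONO")
  pred <- c("MONO", "BN", "BN", "BN", "BN_MN", "POLY", "BN", "MONO_MN",
            "UNKNOWN", "MONO")
  cc <- confusion_counts(pred, truth)
  # hand tally: MONO tp=2 fn=1; BN tp=2 fp=2 fn=1 (one UNKNOWN); IRREG fn=1
  expect_equal(cc$tp[cc$class == "MONO"], 2)
  expect_equal(cc$fn[cc$class == "MONO"], 1)
  expect_equal(cc$tp[cc$class == "BN"], 2)
  expect_equal(cc$fp[cc$class == "BN"], 2)
  expect_equal(cc$fn[cc$class == "BN"], 1)
  expect_equal(cc$fn[cc$class == "IRREG"], 1)
  expect_equal(sum(cc$tp) + sum(cc$fn), length(truth))
  # per class TP + FN equals the truth count
  expect_equal(cc$tp + cc$fn,
               as.vector(table(factor(truth, levels = mn_classes()))))
  # perfect predictions
  cc0 <- confusion_counts(truth, truth)
  expect_true(all(cc0$fp == 0) && all(cc0$fn == 0))
  expect_error(confusion_counts(truth, pred), "invalid class label")
})

test_that("precision/recall/F1 reproduce published per-class values", {
  m1 <- compute_class_metrics(data.frame(class = "MONO", tp = 972, fp = 19,
                                         fn = 28))
  expect_equal(round(m1$precision, 1), 98.1)
  expect_equal(round(m1$recall, 1), 97.2)
  expect_equal(round(m1$f1, 1), 97.6)
  m2 <- compute_class_metrics(data.frame(class = "MONO", tp = 3561, fp = 149,
                                         fn = 39))
  expect_equal(round(m2$precision, 1), 96.0)
  expect_equal(round(m2$recall, 1), 98.9)
  expect_equal(round(m2$f1, 1), 97.4)
  m3 <- compute_class_metrics(data.frame(class = "X", tp = 50, fp = 0, fn = 0))
  expect_equal(unlist(m3[c("precision", "recall", "f1")], use.names = FALSE),
               c(100, 100, 100))
  # undefined metrics are NA, not zero
  m4 <- compute_class_metrics(data.frame(class = "X", tp = 0, fp = 0, fn = 5))
  expect_true(is.na(m4$precision))
  expect_false(isTRUE(m4$precision == 0))
})

test_that("F1 lies between precision and recall; weighted average bounded", {
  set.seed(3)
  for (i in 1:50) {
    cc <- data.frame(class = mn_classes(),
                     tp = sample(1:500, 6), fp = sample(0:100, 6),
                     fn = sample(0:100, 6))
    m <- compute_class_metrics(cc)
    expect_true(all(m$f1 >= pmin(m$precision, m$recall) - 1e-9))
    expect_true(all(m$f1 <= pmax(m$precision, m$recall) + 1e-9))
    w <- weighted_average_metrics(m)
    expect_gte(w, min(m$f1) - 1e-9)
    expect_lte(w, max(m$f1) + 1e-9)
  }
  # constant F1 averages to itself
  mconst <- compute_class_metrics(data.frame(class = c("A", "B"),
                                             tp = c(10, 40),
                                             fp = c(0, 0), fn = c(0, 0)))
  expect_equal(weighted_average_metrics(mconst), 100)
})

test_that("reference counts reproduce the published weighted averages", {
  counts <- reference_confusion_counts()
  val <- compute_class_metrics(counts[counts$dataset == "validation", ])
  expect_equal(round(weighted_average_metrics(val), 1), 96.3)
  # independent hand computation from rounded per-class F1: 303,320 / 3,150
  hand <- sum(round(val$f1, 1) * val$truth_count) / sum(val$truth_count)
  expect_equal(round(hand, 1), 96.3)
  tab <- metrics_table(counts)
  expect_equal(nrow(tab), 21)  # 6 classes + weighted row, per dataset
})
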