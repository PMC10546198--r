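test_that("confusion counts at a threshold", {
  y <- c(1, 1, 0, 0, 1)
  expect_equal(unlist(confusion_counts(y, y)[, c("fp", "fn")]),
               c(fp = 0L, fn = 0L))
  # the printed held-out matrix: 50 images, 7 plus, 2 scored below threshold
  probs <- c(rep(0.9, 5), rep(0.2, 2), rep(0.1, 43))
  labels <- c(rep("plus", 7), rep("no_plus", 43))
  cc <- confusion_counts(probs, labels, 0.5)
  expect_equal(unlist(cc[, c("tp", "fp", "tn", "fn")]),
               c(tp = 5L, fp = 0L, tn = 43L, fn = 2L))
  cc0 <- confusion_counts(probs, labels, 0)
  expect_equal(cc0$fn, 0L)
  expect_equal(cc0$tn, 0L)
  expect_error(confusion_counts(numeric(), character()),
               class = "fundusplus_parameter_error")
})

test_that("metrics match the printed values and flag undefined ratios", {
  m <- classification_metrics(list(tp = 5, fn = 2, fp = 0, tn = 43))
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$sensitivity, 5 / 7, tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 4), 0.7143)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  expect_equal(round(m$f1, 3), 0.833)
  m2 <- classification_metrics(list(tp = 6, fn = 1, fp = 4, tn = 39))
  expect_equal(m2$sensitivity, 6 / 7, tolerance = 1e-12)
  expect_equal(m2$specificity, 39 / 43, tolerance = 1e-12)
  perfect <- classification_metrics(list(tp = 7, fn = 0, fp = 0, tn = 43))
  expect_true(all(unlist(perfect) == 1))
  nopos <- classification_metrics(list(tp = 0, fn = 0, fp = 0, tn = 10))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$precision))
})

test_that("metrics agree with a brute-force recount on random batches", {
  withr::with_seed(30, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      probs <- runif(n)
      y <- rbinom(n, 1, 0.3)
      thr <- runif(1, 0.2, 0.8)
      cc <- confusion_counts(probs, y, thr)
      pred <- as.integer(probs >= thr)
      expect_equal(cc$tp, sum(pred & y))
      expect_equal(cc$fp, sum(pred & !y))
      expect_equal(cc$fn, sum(!pred & y))
      expect_equal(classification_metrics(cc)$accuracy, mean(pred == y))
    }
  })
})

test_that("empirical ROC equals the pair-counting statistic", {
  expect_equal(roc_empirical(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_empirical(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_empirical(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(10:100, 1)
      s <- round(runif(n), 2) # rounded scores force ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      r <- roc_empirical(s, y)
      expect_equal(r$auc, auc_pairs(s, y), tolerance = 1e-12)
      expect_equal(r$points$fpr[1], 0)
      expect_equal(r$points$tpr[nrow(r$points)], 1)
      expect_true(all(diff(r$points$fpr) >= 0))
      expect_true(all(diff(r$points$tpr) >= 0))
    }
  })
  expect_error(roc_empirical(runif(5), rep(1, 5)),
               class = "fundusplus_parameter_error")
})

test_that("binormal ROC has the closed-form area", {
  # equal sample moments -> AUC exactly 0.5
  s <- c(-1, 0, 1, -1, 0, 1)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(roc_binormal(s, y, transform = "none")$auc, 0.5)
  # sample means 0/1, sds 1/1 -> Phi(1/sqrt(2)) ~ 0.7602
  s2 <- c(-1, 0, 1, 0, 1, 2)
  r2 <- roc_binormal(s2, y, transform = "none")
  expect_equal(r2$auc, pnorm(1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(r2$auc, 4), 0.7602)
  # huge separation
  s3 <- c(rnorm(20), rnorm(20) + 10)
  y3 <- rep(c(0, 1), each = 20)
  expect_gt(roc_binormal(s3, y3, transform = "none")$auc, 0.999)
  expect_error(roc_binormal(c(1, 1, 2, 3), c(0, 0, 1, 1), transform = "none"),
               class = "fundusplus_degenerate_error")
  expect_error(roc_binormal(c(1, 2), c(0, 1)),
               class = "fundusplus_parameter_error")
})

test_that("binormal and empirical AUC converge under normal scores", {
  withr::with_seed(32, {
    s <- c(rnorm(5000, 0, 1), rnorm(5000, 1.2, 1.4))
    y <- rep(c(0, 1), each = 5000)
  })
  a_emp <- roc_empirical(s, y)$auc
  a_bin <- roc_binormal(s, y, transform = "none")$auc
  expect_lt(abs(a_emp - a_bin), 0.02)
})

test_that("real-world cost arithmetic", {
  w <- cost_weights(1.7e6, 1.7e4)
  expect_equal(real_world_cost(list(tp = 5, fn = 0, fp = 0, tn = 45), w), 0)
  # the held-out matrix: 2 misses in 50 -> $68,000 per screened infant
  expect_equal(real_world_cost(list(tp = 5, fn = 2, fp = 0, tn = 43), w), 68000)
  base <- real_world_cost(list(tp = 5, fn = 1, fp = 3, tn = 41), w)
  dbl <- real_world_cost(list(tp = 4, fn = 2, fp = 3, tn = 41), w)
  expect_equal(dbl - base, 1.7e6 / 50)
  # unit weights give the error rate
  cc <- list(tp = 10, fn = 3, fp = 7, tn = 30)
  expect_equal(real_world_cost(cc, cost_weights(1, 1)),
               1 - classification_metrics(cc)$accuracy)
  expect_error(real_world_cost(list(tp = 0, fn = 0, fp = 0, tn = 0), w),
               class = "fundusplus_parameter_error")
})

test_that("cohort projection and dollar deltas", {
  expect_equal(cohort_projection(1000, 0.125, 11, avg_fn = 3.3), 38)
  expect_equal(cohort_projection(1000, 0.125, 11, avg_fn = 2.65), 30)
  expect_equal(cohort_projection(1000, 0.125, 11, avg_fn = 0), 0)
  expect_error(cohort_projection(1000, 0.125, 0, avg_fn = 1),
               class = "fundusplus_parameter_error")
  expect_error(cohort_projection(1000, 1.2, 11, avg_fn = 1),
               class = "fundusplus_parameter_error")
  expect_equal(cost_delta(38, 30, 1.7e6), 13600000)
  expect_equal(cost_delta(5, 5, 1.7e6), 0)
  expect_equal(cost_delta(1, 0, 1.7e6), 1700000)
  expect_error(cost_delta(3, 5), class = "fundusplus_parameter_error")
})

test_that("fold-wise ROC curves average vertically", {
  withr::with_seed(33, {
    rocs <- lapply(1:4, function(i) {
      s <- c(rnorm(30), rnorm(30) + 2)
      roc_empirical(s, rep(c(0, 1), each = 30))
    })
  })
  avg <- roc_average(rocs)
  expect_equal(nrow(avg), 101)
  expect_true(all(avg$tpr_mean >= 0 & avg$tpr_mean <= 1))
  expect_true(all(diff(avg$tpr_mean) >= -1e-9))
  expect_equal(attr(avg, "auc_mean"),
               mean(vapply(rocs, `[[`, numeric(1), "auc")))
})
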