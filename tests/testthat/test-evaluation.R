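test_that("minority oversampling balances the classes exactly", {
  y <- c(rep(0, 12), rep(1, 45))              # 12 normal vs 45 abnormal
  idx <- oversample_minority(y, seed = 3)
  yb <- y[idx]
  expect_equal(sum(yb == 0), 45)
  expect_equal(sum(yb == 1), 45)
  expect_equal(sum(yb == 0) / sum(yb == 1), 1)
  expect_true(all(seq_along(y) %in% idx))      # originals kept once each
  expect_equal(oversample_minority(c(0, 0, 1, 1)), 1:4)  # balanced identity
  expect_error(oversample_minority(rep(1, 5)), "both classes")
})

test_that("confusion metrics reproduce hand-computed values", {
  m <- confusion_metrics(tp = 45, fp = 0, tn = 45, fn = 0)
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["g"]), 1)
  m2 <- confusion_metrics(tp = 9, fp = 1, tn = 9, fn = 1)
  expect_equal(unname(m2["sensitivity"]), 0.9)
  expect_equal(unname(m2["specificity"]), 0.9)
  expect_equal(unname(m2["g"]), 0.9)
  m3 <- confusion_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m3["sensitivity"]))        # undefined denominator
  ## g is invariant under swapping classes and sens <-> spec
  a <- confusion_metrics(tp = 8, fp = 3, tn = 20, fn = 2)
  b <- confusion_metrics(tp = 20, fp = 2, tn = 8, fn = 3)
  expect_equal(unname(a["g"]), unname(b["g"]))
})

test_that("cross-validation partitions the data and nails separable features", {
  set.seed(80)
  x <- rbind(matrix(rnorm(60), ncol = 2),
             matrix(rnorm(60, mean = 5), ncol = 2))
  y <- rep(c(0, 1), each = 30)
  ev <- cross_validate(x, y, folds = 10, retrains = 3, pca_retain = NULL,
                       seed = 12)
  expect_equal(sum(ev$counts), length(y))       # balanced input: no inflation
  expect_true(all(table(ev$predictions$fold) > 0))
  expect_equal(anyNA(ev$predictions$pred), FALSE)
  expect_equal(unname(ev$metrics["g"]), 1)
  expect_equal(colSums(ev$per_fold), ev$counts)
})

test_that("cross-validation is deterministic given the master seed", {
  set.seed(81)
  x <- rbind(matrix(rnorm(40), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
  y <- rep(c(0, 1), each = 20)
  e1 <- cross_validate(x, y, folds = 5, retrains = 2, seed = 99)
  e2 <- cross_validate(x, y, folds = 5, retrains = 2, seed = 99)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$predictions, e2$predictions)
})

test_that("leave-one-out folds and guard rails work", {
  set.seed(82)
  x <- rbind(matrix(rnorm(24), ncol = 2), matrix(rnorm(24, 5), ncol = 2))
  y <- rep(c(0, 1), each = 12)
  ev <- cross_validate(x, y, folds = length(y), retrains = 1, n_networks = 1,
                       pca_retain = NULL, seed = 5)
  expect_equal(sum(ev$counts), length(y))
  expect_error(cross_validate(x, y, folds = 100), "fewer examples")
  expect_error(cross_validate(x, rep(1, length(y)), folds = 4), "both classes")
})

test_that("ROC endpoints, separability and random-score area behave", {
  scores <- c(rep(0.9, 20), rep(0.1, 20))
  labels <- rep(c(1, 0), each = 20)
  roc <- roc_curve(scores, labels)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))          # ideal point
  expect_equal(roc$tpr[roc$threshold == 0], 1)
  expect_equal(roc$fpr[roc$threshold == 0], 1)
  expect_equal(roc$tpr[roc$threshold == 1], 0)           # above max score
  set.seed(83)
  rnd <- roc_curve(runif(4000), rep(c(0, 1), 2000))
  expect_lt(abs(attr(rnd, "auc") - 0.5), 0.05)
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(84)
  scores <- c(rnorm(100, 0.4, 0.15), rnorm(100, 0.6, 0.15))
  labels <- rep(c(0, 1), each = 100)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  auc_grid <- attr(roc_curve(scores, labels, seq(-1, 2, length.out = 601)),
                   "auc")
  expect_equal(auc_grid, auc_ref, tolerance = 0.01)
})

test_that("leave-one-type-out excludes the named type and reports bookkeeping", {
  set.seed(85)
  x <- rbind(matrix(rnorm(40), ncol = 2),         # normal
             matrix(rnorm(30, 4), ncol = 2),      # murmur-like, loud
             matrix(rnorm(8, 5), ncol = 2))       # the held-out type
  y <- c(rep(0, 20), rep(1, 15), rep(1, 4))
  types <- c(rep("normal", 20), rep("murmurA", 15), rep("murmurB", 4))
  res <- leave_one_type_out(x, y, types, "murmurB", retrains = 3,
                            pca_retain = NULL, seed = 6)
  expect_equal(res$total, 4)
  expect_gte(res$correct, 3)                      # generalizes to unseen type
  expect_error(leave_one_type_out(x, y, types, "gallop"), "unknown type")
})
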