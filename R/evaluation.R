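#' Oversample the minority class to balance a training set
#'
#' Returns indices: every original example once, plus uniformly resampled
#' minority-class examples until both classes are equally sized. The
#' majority class is untouched.
#'
#' @param y binary labels (0/1).
#' @param seed integer RNG seed.
#' @return integer index vector into the original data.
#' @export
oversample_minority <- function(y, seed = 1L) {
  y <- as.numeric(y)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present", call. = FALSE)
  if (n0 == n1) return(seq_along(y))
  minority <- which(y == if (n0 < n1) 0 else 1)
  deficit <- abs(n0 - n1)
  set.seed(seed)
  c(seq_along(y), sample(minority, deficit, replace = TRUE))
}

#' Confusion-matrix performance metrics
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the geometric mean `g = sqrt(sensitivity * specificity)`
#' -- the class-imbalance-robust index used throughout the package
#' (positive = diseased). A metric whose denominator is zero is returned as
#' `NA` (undefined).
#'
#' @param tp,fp,tn,fn nonnegative integer counts, or a single list/vector
#'   with those names passed as `tp`.
#' @return named numeric vector: `accuracy`, `sensitivity`, `specificity`, `g`.
#' @examples
#' confusion_metrics(tp = 9, fp = 1, tn = 9, fn = 1)  # g = 0.9
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4)) {
    cc <- tp; tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  }
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  g <- if (!is.na(sens) && !is.na(spec)) sqrt(sens * spec) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec, g = g)
}

.count_confusion <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

## Stratified fold assignment: examples ordered class by class (shuffled
## within class), fold labels dealt cyclically over that ordering, so folds
## are balanced in size and in class mix even when folds > class size
## (folds = n gives leave-one-out).
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  ord <- unlist(lapply(unique(y), function(cls) sample(which(y == cls))),
                use.names = FALSE)
  assign <- integer(length(y))
  assign[ord] <- rep_len(seq_len(folds), length(y))
  assign
}

#' Cross-validate the bagged ensemble
#'
#' Ten-fold (by default) cross-validation incorporating bagging: per fold,
#' the training portion is bootstrapped into one resample per network, each
#' network is trained with repeated restarts keeping the lowest-holdout-SAE
#' instance, and the untouched test portion is classified by threshold
#' voting. Folds are stratified by class. Confusion counts are pooled over
#' folds.
#'
#' Class imbalance is handled by minority oversampling. The default
#' (`oversample = "before"`) balances the full set once before folding,
#' which lets replicates of one example straddle the train/test split;
#' `"within"` oversamples only each fold's training portion and is the
#' leakage-safe mode. `"none"` disables balancing.
#'
#' When `pca_retain` is non-`NULL`, a PCA is fitted on each fold's training
#' portion and applied to both portions, so the projection never sees test
#' data.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y binary labels (0/1).
#' @param folds number of folds (default 10).
#' @param oversample `"before"`, `"within"`, or `"none"`.
#' @param pca_retain variance fraction for per-fold PCA, or `NULL` to use
#'   the features as given.
#' @param pca_standardize standardize columns before the per-fold PCA.
#' @param seed master integer seed; the whole report is deterministic
#'   given it.
#' @inheritParams train_bagging
#' @return object of class `pcg_evaluation`: `per_fold` (count matrix),
#'   `counts` (pooled), `metrics` (from [confusion_metrics()]),
#'   `predictions` data frame.
#' @export
cross_validate <- function(x, y, folds = 10L, n_networks = 5L,
                           threshold = 0.15, hidden_units = 10L,
                           retrains = 30L, holdout_fraction = 0.2,
                           maxit = 200L,
                           oversample = c("before", "within", "none"),
                           pca_retain = 0.9, pca_standardize = TRUE,
                           seed = 1L) {
  oversample <- match.arg(oversample)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) < folds) stop("fewer examples than folds", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (oversample == "before") {
    idx <- oversample_minority(y, seed = .derive_seed(seed, 1L))
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  fold_of <- .stratified_folds(y, folds, seed = .derive_seed(seed, 2L))
  per_fold <- matrix(0L, nrow = folds, ncol = 4,
                     dimnames = list(NULL, c("tp", "fp", "tn", "fn")))
  preds <- data.frame(index = seq_along(y), fold = fold_of,
                      truth = y, pred = NA_integer_, score = NA_real_)
  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    if (oversample == "within") {
      oi <- oversample_minority(ytr, seed = .derive_seed(seed, 100L + f))
      xtr <- xtr[oi, , drop = FALSE]; ytr <- ytr[oi]
    }
    xte <- x[te, , drop = FALSE]
    if (!is.null(pca_retain)) {
      pca <- fit_pca(xtr, retain = pca_retain, standardize = pca_standardize)
      xtr <- predict(pca, xtr)
      xte <- predict(pca, xte)
    }
    ens <- train_bagging(xtr, ytr, n_networks = n_networks,
                         threshold = threshold, hidden_units = hidden_units,
                         retrains = retrains,
                         holdout_fraction = holdout_fraction, maxit = maxit,
                         seed = .derive_seed(seed, 1000L + f))
    pr <- predict(ens, xte)
    per_fold[f, ] <- .count_confusion(pr$label, y[te])
    preds$pred[te] <- pr$label
    preds$score[te] <- rowMeans(pr$outputs)
  }
  counts <- colSums(per_fold)
  structure(list(per_fold = per_fold, counts = counts,
                 metrics = confusion_metrics(as.list(counts)),
                 predictions = preds, folds = folds, seed = seed),
            class = "pcg_evaluation")
}

#' @export
print.pcg_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<pcg_evaluation> %d folds, %d examples\n",
                     "  tp %d  fp %d  tn %d  fn %d\n",
                     "  accuracy %.3f  sensitivity %.3f  specificity %.3f  g %.3f\n"),
              x$folds, sum(x$counts), x$counts["tp"], x$counts["fp"],
              x$counts["tn"], x$counts["fn"], m["accuracy"],
              m["sensitivity"], m["specificity"], m["g"]))
  invisible(x)
}

#' ROC curve over a threshold grid
#'
#' For each threshold, scores at or above it are classified positive;
#' returns (FPR, TPR) per threshold and the Youden-optimal threshold
#' maximizing TPR - FPR (the criterion behind the default vote threshold
#' T = 0.15).
#'
#' @param scores numeric classifier scores (higher = more abnormal).
#' @param labels binary truth (0/1), both classes present.
#' @param thresholds threshold grid (default 101 points in \[0, 1\]).
#' @return data frame (`threshold`, `fpr`, `tpr`) with attributes
#'   `optimal_threshold`, `auc` (trapezoidal).
#' @export
roc_curve <- function(scores, labels, thresholds = seq(0, 1, length.out = 101)) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  pos <- labels == 1
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), 0)
  out <- data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
  ord <- order(fpr, tpr)
  auc <- sum(diff(c(0, fpr[ord], 1)) * (c(0, tpr[ord]) + c(tpr[ord], 1)) / 2)
  attr(out, "optimal_threshold") <- thresholds[which.max(tpr - fpr)]
  attr(out, "auc") <- auc
  out
}

#' Leave one abnormal sound type out
#'
#' Excludes every example of the named type from training (and from the
#' balancing oversample), trains an ensemble on the rest, and classifies the
#' left-out examples -- a robustness probe for unseen abnormal sound types.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (0/1).
#' @param types character vector of per-example sound-type tags.
#' @param leave_out the type tag to hold out.
#' @param pca_retain,pca_standardize per-training-set PCA settings (as in
#'   [cross_validate()]).
#' @param seed master integer seed.
#' @inheritParams train_bagging
#' @return list: `type`, `correct`, `total`, `accuracy`, `predictions`.
#' @export
leave_one_type_out <- function(x, y, types, leave_out, n_networks = 5L,
                               threshold = 0.15, hidden_units = 10L,
                               retrains = 30L, holdout_fraction = 0.2,
                               maxit = 200L, pca_retain = 0.9,
                               pca_standardize = TRUE, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!leave_out %in% types)
    stop("unknown type tag: ", leave_out, call. = FALSE)
  te <- which(types == leave_out)
  tr <- which(types != leave_out)
  ytr <- y[tr]
  oi <- oversample_minority(ytr, seed = .derive_seed(seed, 1L))
  xtr <- x[tr, , drop = FALSE][oi, , drop = FALSE]
  ytr <- ytr[oi]
  xte <- x[te, , drop = FALSE]
  if (!is.null(pca_retain)) {
    pca <- fit_pca(xtr, retain = pca_retain, standardize = pca_standardize)
    xtr <- predict(pca, xtr)
    xte <- predict(pca, xte)
  }
  ens <- train_bagging(xtr, ytr, n_networks = n_networks,
                       threshold = threshold, hidden_units = hidden_units,
                       retrains = retrains,
                       holdout_fraction = holdout_fraction, maxit = maxit,
                       seed = .derive_seed(seed, 2L))
  pr <- predict(ens, xte)
  correct <- sum(pr$label == y[te])
  list(type = leave_out, correct = correct, total = length(te),
       accuracy = correct / length(te),
       predictions = data.frame(index = te, truth = y[te], pred = pr$label))
}
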