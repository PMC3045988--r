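#' Bootstrap resampled training sets
#'
#' Draws `n_sets` uniform with-replacement resamples of the row indices,
#' each the size of the data; deterministic given `seed`.
#'
#' @param n_examples number of examples in the training set.
#' @param n_sets number of resamples (one per ensemble network).
#' @param seed integer RNG seed.
#' @return list of `n_sets` integer index vectors of length `n_examples`.
#' @export
bootstrap_sets <- function(n_examples, n_sets, seed = 1L) {
  if (n_examples < 1) stop("empty training set", call. = FALSE)
  lapply(seq_len(n_sets), function(i) {
    set.seed(.derive_seed(seed, i))
    sample.int(n_examples, n_examples, replace = TRUE)
  })
}

#' Sum of absolute errors
#'
#' Model-selection score: `sum |y_i - d_i|` between network outputs and
#' binary targets.
#'
#' @param outputs numeric vector of raw network outputs.
#' @param targets binary targets (0/1), same length.
#' @return nonnegative scalar.
#' @export
sae <- function(outputs, targets) {
  if (length(outputs) != length(targets))
    stop("outputs and targets differ in length", call. = FALSE)
  sum(abs(outputs - targets))
}

#' Train one network with repeated restarts
#'
#' Reserves a stratified holdout fraction, then fits `retrains` independent
#' random initializations of a single-hidden-layer network (logistic hidden
#' and output units, squared-error loss, via [nnet::nnet]); the squared-error
#' surface is non-convex, so the restart with the lowest holdout [sae()] is
#' kept. Deterministic given `seed`.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y binary labels (0/1).
#' @param hidden_units hidden layer width (default 10).
#' @param retrains number of random restarts (default 30).
#' @param holdout_fraction fraction of examples reserved for restart
#'   selection (default 0.2).
#' @param maxit optimizer iteration cap per restart.
#' @param seed integer RNG seed.
#' @return object of class `pcg_net`: the kept fit, its `holdout_sae`,
#'   `all_sae` (holdout SAE of every restart) and `holdout` (the reserved
#'   row indices).
#' @export
train_network <- function(x, y, hidden_units = 10L, retrains = 30L,
                          holdout_fraction = 0.2, maxit = 200L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("training set contains a single class", call. = FALSE)
  n <- nrow(x)
  set.seed(.derive_seed(seed, 0L))
  ho <- unlist(lapply(split(seq_len(n), y), function(idx) {
    k <- max(1L, round(holdout_fraction * length(idx)))
    if (k >= length(idx)) k <- length(idx) - 1L
    sample(idx, k)
  }), use.names = FALSE)
  tr <- setdiff(seq_len(n), ho)
  if (length(unique(y[tr])) < 2)
    stop("holdout split left a single-class training portion", call. = FALSE)
  best <- NULL; best_sae <- Inf; all_sae <- numeric(retrains)
  for (r in seq_len(retrains)) {
    set.seed(.derive_seed(seed, r))
    fit <- nnet::nnet(x[tr, , drop = FALSE], y[tr], size = hidden_units,
                      entropy = FALSE, linout = FALSE, maxit = maxit,
                      trace = FALSE)
    s <- sae(as.numeric(stats::predict(fit, x[ho, , drop = FALSE])), y[ho])
    all_sae[r] <- s
    if (s < best_sae) { best_sae <- s; best <- fit }
  }
  structure(list(fit = best, holdout_sae = best_sae, all_sae = all_sae,
                 holdout = ho, input_dim = ncol(x),
                 hidden_units = as.integer(hidden_units)),
            class = "pcg_net")
}

#' @export
predict.pcg_net <- function(object, newdata, ...) {
  Xn <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(Xn) != object$input_dim)
    stop("input dimension mismatch", call. = FALSE)
  as.numeric(stats::predict(object$fit, Xn))
}

#' Train a bagged neural-network ensemble
#'
#' Draws `n_networks` bootstrap resamples of the training set and trains one
#' network on each with [train_network()]. Prediction is by threshold
#' voting: network `i` votes abnormal when its output `Y_i >= threshold`,
#' and the ensemble declares abnormal when at least `floor(N/2)` networks
#' vote so -- with `N = 5` two votes suffice, a deliberate sensitivity bias
#' toward the diseased class.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y binary labels (0/1).
#' @param n_networks ensemble size `N` (default 5).
#' @param threshold vote threshold `T` in (0,1) (default 0.15).
#' @param seed integer RNG seed.
#' @inheritParams train_network
#' @return object of class `pcg_bagging`.
#' @export
train_bagging <- function(x, y, n_networks = 5L, threshold = 0.15,
                          hidden_units = 10L, retrains = 30L,
                          holdout_fraction = 0.2, maxit = 200L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  sets <- bootstrap_sets(nrow(x), n_networks, seed = .derive_seed(seed, 101L))
  nets <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    idx <- sets[[i]]
    if (length(unique(y[idx])) < 2) {
      ## a resample can miss the minority class entirely; force one example
      ## of each class in (rare at realistic sizes, fatal if unhandled)
      idx[1] <- which(y == 0)[1]
      idx[2] <- which(y == 1)[1]
    }
    nets[[i]] <- train_network(x[idx, , drop = FALSE], y[idx],
                               hidden_units = hidden_units,
                               retrains = retrains,
                               holdout_fraction = holdout_fraction,
                               maxit = maxit, seed = .derive_seed(seed, 200L + i))
  }
  structure(list(networks = nets, threshold = threshold,
                 n_networks = as.integer(n_networks),
                 input_dim = ncol(x)),
            class = "pcg_bagging")
}

#' Threshold vote over raw network outputs
#'
#' Network `i` votes abnormal when `Y_i >= threshold`; the ensemble class is
#' abnormal when at least `floor(N/2)` votes agree (but never fewer than one
#' vote, so a single-network ensemble reduces to plain thresholding).
#'
#' @param outputs numeric matrix of raw outputs, one column per network
#'   (a vector is treated as one row).
#' @param threshold vote threshold `T`.
#' @return list with `label` (0/1 per row) and `votes` (binary matrix).
#' @examples
#' ensemble_vote(c(0.2, 0.1, 0.1, 0.05, 0.3), 0.15)  # 2 votes of 5: abnormal
#' @export
ensemble_vote <- function(outputs, threshold) {
  outs <- if (is.null(dim(outputs))) matrix(outputs, nrow = 1) else outputs
  votes <- (outs >= threshold) * 1L
  need <- max(1L, floor(ncol(outs) / 2))
  list(label = as.integer(rowSums(votes) >= need), votes = votes)
}

#' Classify feature vectors with a bagged ensemble
#'
#' @param object a `pcg_bagging` ensemble.
#' @param newdata `k`-vector or matrix with `k` columns.
#' @param threshold override the ensemble's vote threshold.
#' @param ... unused.
#' @return list with `label` (0/1 per row), `votes` (n x N binary matrix)
#'   and `outputs` (n x N raw network outputs).
#' @export
predict.pcg_bagging <- function(object, newdata, threshold = object$threshold, ...) {
  Xn <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  outs <- vapply(object$networks, function(nw) predict(nw, Xn),
                 numeric(nrow(Xn)))
  outs <- matrix(outs, nrow = nrow(Xn))
  v <- ensemble_vote(outs, threshold)
  list(label = v$label, votes = v$votes, outputs = outs)
}

#' @export
print.pcg_bagging <- function(x, ...) {
  cat(sprintf("<pcg_bagging> %d networks (%d inputs), vote threshold %.2f\n",
              x$n_networks, x$input_dim, x$threshold))
  invisible(x)
}
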