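test_that("bootstrap resamples have the right size and are seed-deterministic", {
  sets <- bootstrap_sets(100, 5, seed = 7)
  expect_length(sets, 5)
  expect_true(all(lengths(sets) == 100))
  expect_identical(sets, bootstrap_sets(100, 5, seed = 7))
  expect_false(identical(sets, bootstrap_sets(100, 5, seed = 8)))
})

test_that("bootstrap distinct-example fraction approaches 1 - 1/e", {
  fracs <- vapply(1:100, function(s)
    length(unique(bootstrap_sets(1000, 1, seed = s)[[1]])) / 1000, 0)
  expect_lt(abs(mean(fracs) - (1 - exp(-1))), 0.03)
})

test_that("sum of absolute errors matches hand evaluation", {
  expect_equal(sae(c(1, 0), c(1, 0)), 0)
  expect_equal(sae(c(0.8, 0.3), c(1, 0)), 0.5)
  expect_equal(sae(rep(0.5, 12), rep(1, 12)), 6)
  expect_error(sae(1:3, 1:2), "length")
})

## small separable two-cluster problem reused below
make_clusters <- function(n = 60, gap = 4, seed = 70) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), ncol = 2),
             matrix(rnorm(n, mean = gap), ncol = 2))
  list(x = x, y = rep(c(0, 1), each = n / 2))
}

test_that("restart selection keeps the best network and is monotone in retrains", {
  d <- make_clusters()
  net30 <- train_network(d$x, d$y, hidden_units = 5, retrains = 30, seed = 3)
  expect_equal(net30$holdout_sae, min(net30$all_sae))
  expect_lte(net30$holdout_sae, max(net30$all_sae))
  net1 <- train_network(d$x, d$y, hidden_units = 5, retrains = 1, seed = 3)
  ## retrains = 1 under the same seed stream is the first element of the 30
  expect_equal(net1$all_sae, net30$all_sae[1])
  expect_lte(net30$holdout_sae, net1$holdout_sae)
  expect_error(train_network(d$x, rep(1, nrow(d$x))), "single class")
})

test_that("the selected network solves XOR with 10 hidden units", {
  set.seed(71)
  base <- matrix(rep(c(0, 0, 1, 0, 0, 1, 1, 1), 25), ncol = 2, byrow = TRUE)
  x <- base + matrix(rnorm(200, sd = 0.05), ncol = 2)
  y <- as.numeric(xor(base[, 1] == 1, base[, 2] == 1))
  net <- train_network(x, y, hidden_units = 10, retrains = 30, seed = 5)
  ## the kept instance must classify its reserved holdout perfectly
  pred <- as.numeric(predict(net, x[net$holdout, ]) >= 0.5)
  expect_equal(mean(pred == y[net$holdout]), 1)
})

test_that("threshold voting follows the two-of-five rule", {
  v <- ensemble_vote(c(0.2, 0.1, 0.1, 0.05, 0.3), 0.15)
  expect_equal(drop(v$votes), c(1, 0, 0, 0, 1))      # 2 votes = floor(5/2)
  expect_equal(v$label, 1L)
  expect_equal(ensemble_vote(rep(0.1, 5), 0.15)$label, 0L)   # no votes
  expect_equal(ensemble_vote(rep(1, 5), 0.9)$label, 1L)      # unanimous
})

test_that("raising the vote threshold never flips a prediction to abnormal", {
  d <- make_clusters(gap = 2, seed = 72)
  ens <- train_bagging(d$x, d$y, n_networks = 5, retrains = 3, seed = 9)
  grid <- seq(0.05, 0.95, by = 0.1)
  labs <- vapply(grid, function(t) predict(ens, d$x, threshold = t)$label,
                 integer(nrow(d$x)))
  for (j in seq_len(ncol(labs) - 1))
    expect_true(all(labs[, j + 1] <= labs[, j]))
})

test_that("a single-network ensemble reduces to plain thresholding", {
  d <- make_clusters(seed = 73)
  ens <- train_bagging(d$x, d$y, n_networks = 1, retrains = 3, seed = 4)
  pr <- predict(ens, d$x)
  expect_equal(pr$label, as.integer(pr$outputs[, 1] >= ens$threshold))
})

test_that("a 5-network ensemble separates well-separated synthetic classes", {
  d <- make_clusters(n = 100, gap = 4, seed = 74)
  set.seed(75)
  ho <- sample(nrow(d$x), 30)
  ens <- train_bagging(d$x[-ho, ], d$y[-ho], n_networks = 5, retrains = 10,
                       seed = 6)
  pr <- predict(ens, d$x[ho, ])
  cm <- confusion_metrics(sum(pr$label == 1 & d$y[ho] == 1),
                          sum(pr$label == 1 & d$y[ho] == 0),
                          sum(pr$label == 0 & d$y[ho] == 0),
                          sum(pr$label == 0 & d$y[ho] == 1))
  expect_gte(cm["g"], 0.95)
})
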