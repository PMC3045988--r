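## Independent brute-force oracles. These deliberately avoid the package's
## FFT / incremental implementations so agreement is a genuine cross-check.

## Direct evaluation of the scalogram envelope: for each scale, correlate
## the signal with the untruncated (full signal support) Morlet atom by an
## explicit double loop over time, then sum squared magnitudes.
envelope_direct <- function(x, config) {
  n <- length(x)
  env <- numeric(n)
  for (a in config$scales) {
    for (t in seq_len(n)) {
      k <- seq_len(n) - t                       # atom argument k - n
      psi <- pi^(-0.25) * exp(-k^2 / (2 * a^2)) *
        exp(1i * config$omega0 * k / a)
      env[t] <- env[t] + Mod(sum(psi * x))^2
    }
  }
  env
}

## Direct O(N^2) positive-lag raw autocorrelation.
autocorr_direct <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m) sum(x[(m + 1):n] * x[1:(n - m)]), 0)
}

## Explicit assembly of the sample covariance as a sum of outer products.
covariance_direct <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  C <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) {
    d <- X[i, ] - mu
    C <- C + outer(d, d)
  }
  C / (n - 1)
}

## Brute-force prominence filter: every strict local maximum whose
## topographic prominence (value minus the higher of the two flanking
## valley minima, valleys extending to the nearest higher sample or the
## signal end) is at least delta.
peaks_by_prominence <- function(E, delta) {
  n <- length(E)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (!(E[i] > E[i - 1] && E[i] > E[i + 1])) next
    l <- i - 1
    while (l >= 1 && E[l] < E[i]) l <- l - 1
    left_min <- min(E[max(l, 1):i])
    r <- i + 1
    while (r <= n && E[r] < E[i]) r <- r + 1
    right_min <- min(E[i:min(r, n)])
    if (E[i] - max(left_min, right_min) >= delta) out <- c(out, i)
  }
  out
}

## Gaussian bump train on a zero baseline: piecewise-smooth test signals
## whose peak prominences are bounded away from any delta in (0.3, 0.7)
## (bump heights are either >= 1 or <= 0.2), with a low tail after the last
## bump so every qualifying peak is followed by a full fall.
random_bump_signal <- function(n_bumps, len = 600, seed = 1) {
  set.seed(seed)
  centers <- sort(sample(seq(40, len - 40), n_bumps))
  while (n_bumps > 1 && min(diff(centers)) < 45)
    centers <- sort(sample(seq(40, len - 40), n_bumps))
  heights <- ifelse(stats::runif(n_bumps) < 0.6,
                    stats::runif(n_bumps, 1, 2),      # clearly prominent
                    stats::runif(n_bumps, 0.05, 0.2)) # clearly not
  x <- numeric(len)
  t <- seq_len(len)
  for (b in seq_len(n_bumps))
    x <- x + heights[b] * exp(-(t - centers[b])^2 / (2 * 6^2))
  list(x = x, centers = centers, heights = heights)
}

## Shared fixture: a small clean synthetic record analyzed once per test file.
make_normal_record <- function(bpm = 80, n_cycles = 8, seed = 3, ...) {
  generate_heart_sound(sim_config(bpm = bpm, fs = 4000, n_cycles = n_cycles,
                                  seed = seed, ...))
}
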