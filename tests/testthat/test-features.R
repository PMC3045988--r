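test_that("the 32 window energies partition the d2 coefficient energy", {
  expect_equal(wavelet_window_energies(numeric(4096)), rep(0, 32))
  set.seed(50)
  x <- rnorm(5000)
  en <- wavelet_window_energies(x)
  d2 <- dwt(x, "db2", 6)$details[[2]]
  expect_length(en, 32)
  expect_equal(sum(en), sum(d2^2), tolerance = 1e-9)
})

test_that("window energies of a unit impulse match an independent windowing of d2", {
  x <- numeric(4096); x[2049] <- 1
  d2 <- dwt(x, "db2", 6)$details[[2]]
  n <- length(d2); base <- n %/% 32; extra <- n %% 32
  sizes <- rep(base, 32) + c(rep(1, extra), rep(0, 32 - extra))
  ends <- cumsum(sizes)
  expected <- vapply(seq_len(32), function(w)
    sum(d2[(ends[w] - sizes[w] + 1):ends[w]]^2), 0)
  expect_equal(wavelet_window_energies(x), expected, tolerance = 1e-12)
})

test_that("peak detector resolves bumps, rejects ramps and flat signals", {
  t <- 1:400
  two <- exp(-(t - 100)^2 / 200) + exp(-(t - 300)^2 / 200) +
    0.1 * exp(-(t - 200)^2 / 5000)
  pk <- detect_peaks(two, 0.25)
  expect_equal(nrow(pk), 2)
  expect_lte(abs(pk$position[1] - 100), 1)
  expect_lte(abs(pk$position[2] - 300), 1)
  expect_equal(nrow(detect_peaks(seq(0, 10, length.out = 100), 0.5)), 0)
  expect_equal(nrow(detect_peaks(numeric(100), 1)), 0)
  expect_equal(nrow(detect_peaks(numeric(0), 1)), 0)
  expect_error(detect_peaks(two, 0), "positive")
})

test_that("peak detector agrees with the brute-force prominence oracle", {
  ## 200 random bump trains whose prominences sit far from delta, with a
  ## low tail after the last bump, so both definitions must coincide
  for (s in 1:200) {
    sig <- random_bump_signal(n_bumps = sample(2:6, 1), seed = s)
    delta <- 0.5
    got <- detect_peaks(sig$x, delta)$position
    want <- peaks_by_prominence(sig$x, delta)
    expect_equal(length(got), length(want), info = paste("seed", s))
    if (length(got)) expect_true(all(abs(got - want) <= 1),
                                 info = paste("seed", s))
  }
})

test_that("envelope features count FHS peaks and handle degenerate inputs", {
  rec <- make_normal_record(bpm = 75, n_cycles = 6)
  env <- compute_envelope(rec)
  L <- rec$truth$cycle_length
  seg <- env$values[1:(5 * L)]
  f <- envelope_features(seg, 0.25 * max(seg))
  expect_equal(unname(f["n_peaks"]), 10)        # 2 FHS x 5 cycles
  expect_gt(f["mean_peak_dist"], 0)
  expect_equal(unname(f["env_energy"]), sum(seg))
  single <- c(numeric(50), exp(-((-25):25)^2 / 20), numeric(50))
  f1 <- envelope_features(single, 0.25)
  expect_equal(unname(f1["n_peaks"]), 1)
  expect_equal(unname(f1["mean_peak_dist"]), 0) # < 2 peaks convention
  expect_equal(unname(envelope_features(numeric(100), 0.3)),
               c(0, 0, 0))
})

test_that("extract_features returns the documented 35-element layout", {
  rec <- make_normal_record(bpm = 90, n_cycles = 7)
  env <- compute_envelope(rec)
  est <- estimate_cycle_length(autocorrelate(env))
  seg <- crop_segment(rec, env, est)
  fv <- extract_features(seg)
  expect_length(fv, 35)
  expect_named(fv, c("n_peaks", "mean_peak_dist", "env_energy",
                     paste0("w", 1:32)))
  expect_true(all(fv[4:35] >= 0))
  expect_identical(fv, extract_features(seg))   # deterministic
})

test_that("feature scaling follows the energy laws under amplitude doubling", {
  rec <- make_normal_record(bpm = 90, n_cycles = 7)
  env <- compute_envelope(rec)
  est <- estimate_cycle_length(autocorrelate(env))
  seg <- crop_segment(rec, env, est)
  seg2 <- seg
  seg2$sound <- 2 * seg$sound
  seg2$envelope <- 4 * seg$envelope   # envelope is quadratic in amplitude
  f1 <- extract_features(seg)
  f2 <- extract_features(seg2)
  expect_equal(unname(f2["n_peaks"]), unname(f1["n_peaks"]))
  expect_equal(unname(f2["env_energy"]), 4 * unname(f1["env_energy"]),
               tolerance = 1e-10)
  expect_equal(unname(f2[4:35]), 4 * unname(f1[4:35]), tolerance = 1e-10)
})

test_that("peak counts are invariant to where the crop begins", {
  rec <- make_normal_record(bpm = 80, n_cycles = 8)
  env <- compute_envelope(rec)
  est <- estimate_cycle_length(autocorrelate(env))
  f0 <- extract_features(crop_segment(rec, env, est, offset = 0L))
  f1 <- extract_features(crop_segment(rec, env, est, offset = 137L))
  expect_equal(unname(f0["n_peaks"]), unname(f1["n_peaks"]))
})
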