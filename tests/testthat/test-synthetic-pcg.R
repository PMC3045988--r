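test_that("generated records honour the exact cycle-length annotation", {
  rec <- generate_heart_sound(sim_config(bpm = 60, fs = 4000, n_cycles = 5))
  expect_equal(rec$truth$cycle_length, 4000)     # one second per cycle
  expect_equal(length(rec$samples), 20000)
  expect_equal(rec$label, 0L)
  ab <- generate_heart_sound(sim_config(components = "systolic_murmur"))
  expect_equal(ab$label, 1L)
})

test_that("generation is bit-identical given the same config and seed", {
  cfg <- sim_config(bpm = 95, components = c("S3", "systolic_murmur"), seed = 77)
  expect_identical(generate_heart_sound(cfg)$samples,
                   generate_heart_sound(cfg)$samples)
})

test_that("normal records are periodic cycle to cycle", {
  rec <- make_normal_record(bpm = 72, n_cycles = 4)
  L <- rec$truth$cycle_length
  for (k in 1:3) {
    c1 <- rec$samples[((k - 1) * L + 1):(k * L)]
    c2 <- rec$samples[(k * L + 1):((k + 1) * L)]
    expect_gte(stats::cor(c1, c2), 0.99)
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(bpm = 30), "48")
  expect_error(sim_config(systole_fraction = 0.6), "shorter than diastole")
  expect_error(sim_config(bpm = 240, burst_duration = 0.09), "burst_duration")
  expect_error(sim_config(components = "S5"), "unknown components")
  expect_error(sim_config(murmur_band = c(300, 100)), "murmur_band")
})

test_that("white noise realizes the requested SNR exactly", {
  rec <- make_normal_record()
  for (snr in c(15, 10, 5)) {
    noisy <- add_white_noise(rec, snr, seed = 21)
    noise <- noisy$samples - rec$samples
    realized <- 10 * log10(mean(rec$samples^2) / mean(noise^2))
    expect_equal(realized, snr, tolerance = 0.01)
  }
  expect_identical(add_white_noise(rec, Inf)$samples, rec$samples)
  expect_error(add_white_noise(heart_sound_record(rep(0, 100), 4000), 10),
               "zero power")
})

test_that("different noise seeds give different realizations at identical SNR", {
  rec <- make_normal_record()
  n1 <- add_white_noise(rec, 10, seed = 1)$samples - rec$samples
  n2 <- add_white_noise(rec, 10, seed = 2)$samples - rec$samples
  expect_gt(max(abs(n1 - n2)), 0.01)
  expect_equal(mean(n1^2), mean(n2^2), tolerance = 1e-12)
})

test_that("impulse noise replaces exactly the requested window, bounded by the signal max", {
  rec <- make_normal_record()
  out <- add_impulse_noise(rec, duration_s = 0.3, start_s = 1.0, seed = 5)
  changed <- which(out$samples != rec$samples)
  expect_equal(length(changed), 1200)            # 0.3 s at 4000 Hz
  expect_equal(diff(range(changed)), 1199)       # contiguous
  expect_lte(max(abs(out$samples[changed])), max(abs(rec$samples)))
  expect_identical(add_impulse_noise(rec, 0)$samples, rec$samples)
  expect_error(add_impulse_noise(rec, duration_s = 1e5), "past the end")
})

test_that("noise injectors preserve length, rate and annotation", {
  rec <- make_normal_record()
  for (out in list(add_white_noise(rec, 10, seed = 3),
                   add_impulse_noise(rec, 0.2, 0.5, seed = 3))) {
    expect_equal(length(out$samples), length(rec$samples))
    expect_equal(out$fs, rec$fs)
    expect_equal(out$truth$cycle_length, rec$truth$cycle_length)
    expect_equal(out$label, rec$label)
  }
})

test_that("WAV round-trip preserves samples, rate and sidecar annotation", {
  rec <- make_normal_record(n_cycles = 2)
  rec$samples <- rec$samples / max(abs(rec$samples))  # PCM16 clips beyond +-1
  for (fmt in c("float32", "pcm16")) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(rec, path, format = fmt)
    back <- read_wav(path)
    expect_equal(back$fs, rec$fs)
    tol <- if (fmt == "float32") 1e-6 else 1 / 32767
    expect_lt(max(abs(back$samples - rec$samples)), tol)
    expect_equal(back$truth$cycle_length, rec$truth$cycle_length)
    expect_equal(back$label, rec$label)
  }
})
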