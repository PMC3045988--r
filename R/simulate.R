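#' Configuration for the synthetic phonocardiogram generator
#'
#' Describes one simulated heart sound: constant heart rate, Gaussian-windowed
#' tone bursts for S1 and S2, and optional abnormal components (extra heart
#' sounds S3/S4 and band-limited murmur noise in systole or diastole).
#'
#' The S1 and S2 carriers default to 50 and 80 Hz, inside the low-frequency
#' band where fundamental heart sounds carry most of their energy; S3/S4 are
#' synthesized as softer, lower-pitched bursts in early and late diastole.
#' Systole (S1 onset to S2 onset) must be the shorter half of the cycle.
#'
#' @param bpm heart rate, beats per minute (48--240). Constant over the record.
#' @param fs sampling frequency, Hz.
#' @param n_cycles number of cardiac cycles to synthesize.
#' @param systole_fraction fraction of the cycle from S1 onset to S2 onset;
#'   must lie in (0, 0.5).
#' @param s1_freq,s2_freq tone-burst carrier frequencies, Hz.
#' @param burst_duration effective burst length, seconds; must fit within
#'   systole at the requested rate.
#' @param components character vector drawn from `"S3"`, `"S4"`,
#'   `"systolic_murmur"`, `"diastolic_murmur"`. Empty means a normal sound.
#' @param murmur_band two-sided band (low, high) in Hz for murmur noise.
#' @param murmur_gain murmur peak amplitude relative to the S1 peak.
#' @param seed integer RNG seed; all stochastic components derive from it.
#' @return list of class `sim_config`.
#' @seealso [generate_heart_sound()]
#' @export
sim_config <- function(bpm = 72, fs = 4000, n_cycles = 8,
                       systole_fraction = 0.35,
                       s1_freq = 50, s2_freq = 80,
                       burst_duration = 0.08,
                       components = character(0),
                       murmur_band = c(120, 600),
                       murmur_gain = 0.6,
                       seed = 1L) {
  vals <- c(bpm = bpm, fs = fs, n_cycles = n_cycles,
            systole_fraction = systole_fraction, s1_freq = s1_freq,
            s2_freq = s2_freq, burst_duration = burst_duration,
            murmur_band, murmur_gain = murmur_gain, seed = seed)
  if (!all(is.finite(vals))) stop("non-finite sim_config value", call. = FALSE)
  if (bpm < 48 || bpm > 240) stop("bpm must lie in [48, 240]", call. = FALSE)
  if (systole_fraction <= 0 || systole_fraction >= 0.5)
    stop("systole_fraction must lie in (0, 0.5): systole is shorter than diastole",
         call. = FALSE)
  if (burst_duration >= systole_fraction * 60 / bpm)
    stop("burst_duration must be shorter than systole at this heart rate",
         call. = FALSE)
  if (fs <= 0 || n_cycles < 1) stop("fs and n_cycles must be positive", call. = FALSE)
  bad <- setdiff(components, c("S3", "S4", "systolic_murmur", "diastolic_murmur"))
  if (length(bad)) stop("unknown components: ", paste(bad, collapse = ", "), call. = FALSE)
  if (murmur_band[1] <= 0 || murmur_band[2] <= murmur_band[1] ||
      murmur_band[2] >= fs / 2)
    stop("murmur_band must satisfy 0 < low < high < fs/2", call. = FALSE)
  structure(list(bpm = bpm, fs = fs, n_cycles = as.integer(n_cycles),
                 systole_fraction = systole_fraction, s1_freq = s1_freq,
                 s2_freq = s2_freq, burst_duration = burst_duration,
                 components = components, murmur_band = murmur_band,
                 murmur_gain = murmur_gain, seed = as.integer(seed)),
            class = "sim_config")
}

## Gaussian-windowed tone burst centred at sample `center` (1-based), added
## in place. Window sd = duration/6 so the burst has ~ +-3 sd support.
.add_burst <- function(x, fs, center, freq, duration, amp) {
  sd_s <- duration / 6
  half <- ceiling(3 * sd_s * fs)
  k <- (-half):half
  idx <- center + k
  keep <- idx >= 1L & idx <= length(x)
  t <- k[keep] / fs
  x[idx[keep]] <- x[idx[keep]] +
    amp * exp(-t^2 / (2 * sd_s^2)) * sin(2 * pi * freq * t)
  x
}

## Band-limited murmur noise gated over [from, to] (samples) with raised-
## cosine edges; peak amplitude scaled to `gain`.
.add_murmur <- function(x, fs, from, to, band, gain) {
  n <- to - from + 1L
  if (n < 8L) return(x)
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  noise <- signal::filtfilt(bf, noise)
  ramp <- max(4L, round(0.05 * n))
  gate <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  gate[seq_len(ramp)] <- up
  gate[n - ramp + seq_len(ramp)] <- rev(up)
  noise <- noise * gate
  peak <- max(abs(noise))
  if (peak > 0) noise <- noise * (gain / peak)
  x[from:to] <- x[from:to] + noise
  x
}

#' Generate a synthetic annotated phonocardiogram
#'
#' Synthesizes `n_cycles` identical cardiac cycles at an exactly constant
#' heart rate: a Gaussian-windowed S1 tone burst at each cycle start and an
#' S2 burst at `systole_fraction` of the cycle (S2 slightly softer than S1,
#' as in normal auscultation). Requested abnormal components are
#' superimposed: S3 in early diastole, S4 in late diastole, and murmurs as
#' Butterworth band-passed white noise gated over systole or diastole. The
#' returned record carries a truth annotation (exact cycle length in samples
#' and S1/S2 onsets) and `label = 1` iff any abnormal component was added.
#'
#' Generation is fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [heart_sound_record()].
#' @examples
#' rec <- generate_heart_sound(sim_config(bpm = 60, fs = 4000, n_cycles = 5))
#' rec$truth$cycle_length   # 4000 samples: one second per cycle at 60 BPM
#' @export
generate_heart_sound <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  cycle_len <- as.integer(round(fs * 60 / config$bpm))
  n <- config$n_cycles * cycle_len
  x <- numeric(n)
  s1_onsets <- integer(config$n_cycles)
  s2_onsets <- integer(config$n_cycles)
  half_burst <- round(config$burst_duration / 2 * fs)
  sys_len <- round(config$systole_fraction * cycle_len)
  for (c_i in seq_len(config$n_cycles)) {
    start <- (c_i - 1L) * cycle_len + 1L
    s1_center <- start + half_burst
    s2_center <- start + sys_len + half_burst
    s1_onsets[c_i] <- start
    s2_onsets[c_i] <- start + sys_len
    x <- .add_burst(x, fs, s1_center, config$s1_freq, config$burst_duration, 1.0)
    x <- .add_burst(x, fs, s2_center, config$s2_freq, config$burst_duration, 0.8)
    if ("S3" %in% config$components)     # early diastole, ~0.13 s after S2
      x <- .add_burst(x, fs, s2_center + round(0.13 * fs),
                      config$s1_freq * 0.6, config$burst_duration, 0.6)
    if ("S4" %in% config$components)     # late diastole, just before next S1
      x <- .add_burst(x, fs, start + cycle_len - round(0.09 * fs),
                      config$s1_freq * 0.6, config$burst_duration, 0.55)
    if ("systolic_murmur" %in% config$components) {
      from <- s1_center + half_burst
      to <- s2_center - half_burst
      if (to > from) x <- .add_murmur(x, fs, from, to, config$murmur_band,
                                      config$murmur_gain)
    }
    if ("diastolic_murmur" %in% config$components) {
      from <- s2_center + half_burst
      to <- start + cycle_len - 2L * half_burst
      if (to > from) x <- .add_murmur(x, fs, from, to, config$murmur_band,
                                      config$murmur_gain)
    }
  }
  heart_sound_record(x, fs,
                     label = as.integer(length(config$components) > 0),
                     truth = list(cycle_length = cycle_len,
                                  s1_onsets = s1_onsets,
                                  s2_onsets = s2_onsets))
}

#' Add Gaussian white noise at an exact signal-to-noise ratio
#'
#' The realized noise sequence is rescaled so that
#' `10 * log10(signal power / noise power)` equals `snr_db` exactly, not just
#' in expectation. `snr_db = Inf` disables noise and returns the input.
#'
#' @param record a [heart_sound_record()] with nonzero power.
#' @param snr_db target SNR in dB (`Inf` for no noise).
#' @param seed integer RNG seed.
#' @return a new record; length, rate, label and truth are unchanged.
#' @export
add_white_noise <- function(record, snr_db, seed = 1L) {
  stopifnot(inherits(record, "heart_sound_record"))
  if (is.infinite(snr_db) && snr_db > 0) return(record)
  p_sig <- mean(record$samples^2)
  if (p_sig <= 0) stop("record has zero power; SNR undefined", call. = FALSE)
  set.seed(seed)
  noise <- stats::rnorm(length(record$samples))
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  heart_sound_record(record$samples + noise, record$fs,
                     label = record$label, truth = record$truth)
}

#' Inject random-value impulse noise
#'
#' Replaces the samples in `[start_s, start_s + duration_s)` with an i.i.d.
#' uniform sequence on `[-max, +max]`, where `max` is the maximum absolute
#' value of the original record -- emulating a chest-piece friction artifact.
#'
#' @param record a [heart_sound_record()].
#' @param duration_s impulse duration in seconds.
#' @param start_s impulse start time in seconds (default 0).
#' @param seed integer RNG seed.
#' @return a new record of identical length and rate.
#' @export
add_impulse_noise <- function(record, duration_s, start_s = 0, seed = 1L) {
  stopifnot(inherits(record, "heart_sound_record"))
  if (duration_s < 0 || start_s < 0)
    stop("duration_s and start_s must be nonnegative", call. = FALSE)
  fs <- record$fs
  n <- length(record$samples)
  if (start_s + duration_s > n / fs + 1e-9)
    stop("impulse window extends past the end of the record", call. = FALSE)
  n_rep <- round(duration_s * fs)
  if (n_rep == 0L) return(record)
  i0 <- floor(start_s * fs) + 1L
  idx <- i0:(i0 + n_rep - 1L)
  mx <- max(abs(record$samples))
  set.seed(seed)
  x <- record$samples
  x[idx] <- stats::runif(n_rep, -mx, mx)
  heart_sound_record(x, fs, label = record$label, truth = record$truth)
}
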