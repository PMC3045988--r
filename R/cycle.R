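#' Raw autocorrelation of an envelope signal
#'
#' Computes the unnormalized positive-lag autocorrelation
#' `R(m) = sum_{n=0}^{N-m-1} x(n+m) x(n)` for `m = 0 .. N-1`, via FFT with
#' zero padding (exact linear autocorrelation). Only positive lags are
#' needed for a real signal.
#'
#' @param E an `envelope_signal` (or plain numeric vector).
#' @return object of class `acf_signal`: list with `values` (lags 0..N-1)
#'   and `fs`.
#' @export
autocorrelate <- function(E) {
  x <- if (inherits(E, "envelope_signal")) E$values else as.numeric(E)
  fs <- if (inherits(E, "envelope_signal")) E$fs else NA_real_
  if (length(x) < 1) stop("empty signal", call. = FALSE)
  .assert_finite(x, "envelope")
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2)
  xf <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(xf * Conj(xf), inverse = TRUE)) / nfft
  structure(list(values = r[seq_len(n)], fs = fs), class = "acf_signal")
}

#' Estimate the cardiac-cycle length from an autocorrelation function
#'
#' A quasi-periodic envelope has an autocorrelation maximum at the lag where
#' the signal is shifted by exactly one cardiac cycle. The estimate is the
#' argmax of `R` over the lag window corresponding to `bpm_range`
#' (`min_lag = round(60 fs / bpm_max)`, `max_lag = round(60 fs / bpm_min)`;
#' 1000--5000 samples at 4000 Hz for 48--240 BPM). Exact ties resolve to the
#' smaller lag. Heart rate is assumed constant over the record.
#'
#' @param R an `acf_signal` from [autocorrelate()] (or numeric vector of
#'   lags 0..N-1).
#' @param fs sampling rate in Hz (taken from `R` when available).
#' @param bpm_range plausible heart-rate range, beats per minute.
#' @return object of class `cycle_estimate`: `lag_samples`, `bpm`,
#'   `search_window` (samples), and `low_confidence` (TRUE when the argmax
#'   sits on a window endpoint, suggesting a rate outside `bpm_range`).
#' @export
estimate_cycle_length <- function(R, fs = NULL, bpm_range = c(48, 240)) {
  vals <- if (inherits(R, "acf_signal")) R$values else as.numeric(R)
  if (is.null(fs)) fs <- if (inherits(R, "acf_signal")) R$fs else
    stop("fs required", call. = FALSE)
  stopifnot(length(bpm_range) == 2, bpm_range[1] > 0,
            bpm_range[2] > bpm_range[1])
  min_lag <- as.integer(round(60 * fs / bpm_range[2]))
  max_lag <- as.integer(round(60 * fs / bpm_range[1]))
  if (length(vals) - 1L < max_lag)
    stop("autocorrelation too short for the search window (need lags up to ",
         max_lag, ")", call. = FALSE)
  win <- vals[(min_lag + 1L):(max_lag + 1L)]       # vals[m+1] is lag m
  if (diff(range(win)) == 0)
    stop("autocorrelation is constant in the search window; no periodicity",
         call. = FALSE)
  lag <- min_lag + which.max(win) - 1L             # first max: smaller lag
  structure(list(lag_samples = lag, bpm = 60 * fs / lag,
                 search_window = c(min_lag = min_lag, max_lag = max_lag),
                 low_confidence = lag %in% c(min_lag, max_lag)),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat(sprintf("<cycle_estimate> lag %d samples = %.1f BPM (window %d-%d)%s\n",
              x$lag_samples, x$bpm, x$search_window[1], x$search_window[2],
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Crop a fixed number of cardiac cycles from a record and its envelope
#'
#' Cuts `n_cycles * lag_samples` samples starting at `offset` from both the
#' sound and the envelope. The start does not need to align with a cycle
#' boundary: features downstream are insensitive to where within a cycle the
#' segment begins.
#'
#' @param record a [heart_sound_record()].
#' @param E its `envelope_signal`.
#' @param est a [estimate_cycle_length()] result (or an integer lag).
#' @param n_cycles cycles to crop (default 5).
#' @param offset 0-based start offset in samples.
#' @return object of class `cycle_segment`: `sound`, `envelope` (equal
#'   length `n_cycles * cycle_length`), `cycle_length`, `fs`, `label`.
#' @export
crop_segment <- function(record, E, est, n_cycles = 5L, offset = 0L) {
  stopifnot(inherits(record, "heart_sound_record"))
  lag <- if (inherits(est, "cycle_estimate")) est$lag_samples else as.integer(est)
  ev <- if (inherits(E, "envelope_signal")) E$values else as.numeric(E)
  if (length(ev) != length(record$samples))
    stop("envelope and record lengths differ", call. = FALSE)
  len <- as.integer(n_cycles) * lag
  if (offset + len > length(record$samples))
    stop("signal too short: need ", offset + len, " samples for ", n_cycles,
         " cycles of ", lag, " but record has ", length(record$samples),
         call. = FALSE)
  idx <- (offset + 1L):(offset + len)
  structure(list(sound = record$samples[idx], envelope = ev[idx],
                 cycle_length = lag, fs = record$fs, label = record$label),
            class = "cycle_segment")
}
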