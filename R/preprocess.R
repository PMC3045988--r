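#' Preprocessing configuration
#'
#' @param target_fs pipeline sampling rate in Hz (default 4000). Must exceed
#'   twice the 300 Hz top of the analysis band.
#' @param denoise_wavelet wavelet for DWT-threshold denoising.
#' @param denoise_levels decomposition depth.
#' @param threshold_rule `"universal"` (per-level MAD noise estimate times
#'   `sqrt(2 log n)`) or `"fixed"` (use `threshold` as given).
#' @param threshold_mode `"soft"` or `"hard"` shrinkage.
#' @param threshold fixed threshold value (only with `threshold_rule = "fixed"`).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 4000, denoise_wavelet = "db5",
                              denoise_levels = 5L,
                              threshold_rule = c("universal", "fixed"),
                              threshold_mode = c("soft", "hard"),
                              threshold = 0) {
  threshold_rule <- match.arg(threshold_rule)
  threshold_mode <- match.arg(threshold_mode)
  if (target_fs <= 2 * 300)
    stop("target_fs must exceed 600 Hz (Nyquist above the 10-300 Hz analysis band)",
         call. = FALSE)
  structure(list(target_fs = target_fs, denoise_wavelet = denoise_wavelet,
                 denoise_levels = as.integer(denoise_levels),
                 threshold_rule = threshold_rule,
                 threshold_mode = threshold_mode, threshold = threshold),
            class = "preprocess_config")
}

#' Resample a record to a target rate
#'
#' Polyphase rational resampling with FIR anti-alias filtering (via
#' `signal::resample`). A record already at the target rate is returned
#' unchanged; duration is preserved to within one output sample.
#'
#' @param record a [heart_sound_record()].
#' @param target_fs target sampling rate, Hz.
#' @return resampled record. Any truth annotation is dropped unless the rate
#'   is unchanged (its sample indices would no longer apply exactly).
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "heart_sound_record"))
  if (target_fs <= 0) stop("target_fs must be positive", call. = FALSE)
  if (isTRUE(all.equal(record$fs, target_fs))) return(record)
  ratio <- target_fs / record$fs
  frac <- .simplify_ratio(ratio)
  y <- signal::resample(record$samples, frac[1], frac[2])
  expected <- round(length(record$samples) * ratio)
  if (abs(length(y) - expected) > 1)
    y <- y[seq_len(min(length(y), expected))]
  heart_sound_record(y, target_fs, label = record$label)
}

## Smallest p/q with p/q == ratio to ~1e-9 (continued fractions).
.simplify_ratio <- function(ratio, tol = 1e-9, max_den = 1e6) {
  a <- ratio; p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  repeat {
    f <- floor(a)
    p2 <- f * p1 + p0; q2 <- f * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - ratio) < tol * ratio) break
    if (a - f < 1e-12) break
    a <- 1 / (a - f)
  }
  c(p1, q1)
}

#' Denoise a record by wavelet thresholding
#'
#' Decomposes the signal with an orthogonal DWT, shrinks each detail level
#' and reconstructs. Under the universal rule the per-level threshold is
#' `sigma_j * sqrt(2 log n_j)` with `sigma_j` the median-absolute-deviation
#' noise estimate of that level's coefficients.
#'
#' @param record a [heart_sound_record()] at the pipeline rate.
#' @param config a [preprocess_config()].
#' @return denoised record of identical length and rate.
#' @export
denoise_record <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "heart_sound_record"),
            inherits(config, "preprocess_config"))
  w <- dwt(record$samples, config$denoise_wavelet, config$denoise_levels)
  for (lev in seq_len(w$levels)) {
    d <- w$details[[lev]]
    thr <- switch(config$threshold_rule,
                  universal = {
                    sigma <- stats::median(abs(d)) / 0.6745
                    sigma * sqrt(2 * log(max(length(d), 2)))
                  },
                  fixed = config$threshold)
    w$details[[lev]] <- if (config$threshold_mode == "soft")
      sign(d) * pmax(abs(d) - thr, 0)
    else
      d * (abs(d) > thr)
  }
  heart_sound_record(idwt(w), record$fs, label = record$label,
                     truth = record$truth)
}
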