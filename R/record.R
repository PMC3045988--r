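#' Construct a heart-sound record
#'
#' The basic container of the package: a sampled single-channel
#' phonocardiogram with its sampling rate, an optional binary class label
#' (0 = normal, 1 = abnormal) and, for simulated sounds, a ground-truth
#' annotation (exact cycle length and event onsets).
#'
#' @param samples numeric vector, dimensionless amplitude.
#' @param fs sampling frequency in Hz.
#' @param label 0, 1 or `NA` (unknown).
#' @param truth optional list with `cycle_length` (samples), `s1_onsets`,
#'   `s2_onsets` (sample indices, 1-based).
#' @return object of class `heart_sound_record`.
#' @export
heart_sound_record <- function(samples, fs, label = NA_integer_, truth = NULL) {
  if (length(samples) < 1L) stop("record must contain at least one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  .assert_finite(samples, "samples")
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0, 1 or NA", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 truth = truth),
            class = "heart_sound_record")
}

#' @export
print.heart_sound_record <- function(x, ...) {
  cat(sprintf("<heart_sound_record> %d samples @ %g Hz (%.2f s), label = %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.na(x$label)) "unknown" else x$label))
  if (!is.null(x$truth))
    cat(sprintf("  truth: cycle length %d samples (%.1f BPM)\n",
                x$truth$cycle_length, 60 * x$fs / x$truth$cycle_length))
  invisible(x)
}

#' @export
length.heart_sound_record <- function(x) length(x$samples)
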