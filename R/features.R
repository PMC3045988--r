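#' Wavelet window energies of a sound segment
#'
#' Decomposes the segment with a 6-level Daubechies-2 DWT, takes the level-2
#' detail coefficients (d2: roughly the upper-middle quarter of the band,
#' where murmur turbulence concentrates relative to the low-frequency
#' fundamental heart sounds), splits them into `n_windows` contiguous
#' non-overlapping windows and returns each window's energy `sum(c^2)`.
#' When the coefficient count is not divisible, the first
#' `length %% n_windows` windows take one extra coefficient.
#'
#' @param x numeric vector (sound segment).
#' @param wavelet,levels DWT settings (defaults: `"db2"`, 6).
#' @param n_windows number of energy windows (default 32).
#' @return numeric vector of `n_windows` nonnegative energies.
#' @export
wavelet_window_energies <- function(x, wavelet = "db2", levels = 6L,
                                    n_windows = 32L) {
  w <- dwt(x, wavelet, levels)
  d2 <- w$details[[2L]]
  n <- length(d2)
  if (n < n_windows)
    stop("segment too short: ", n, " d2 coefficients for ", n_windows,
         " windows", call. = FALSE)
  base <- n %/% n_windows
  extra <- n %% n_windows
  sizes <- rep(base, n_windows) + c(rep(1L, extra), rep(0L, n_windows - extra))
  grp <- rep(seq_len(n_windows), sizes)
  as.numeric(tapply(d2^2, grp, sum))
}

#' Peak detection by running-maximum drop
#'
#' Scans left to right keeping a running maximum; when the signal falls more
#' than `delta` below it, the running maximum is committed as a peak and the
#' tracker resets at the current sample. A peak is thus a local maximum that
#' stands above the valleys on both sides by at least `delta` -- measured
#' from the top of the peak, not from the x-axis, so a loud murmur plateau
#' riding above a fixed threshold does not produce spurious peaks.
#'
#' @param E numeric vector (envelope segment).
#' @param delta commitment threshold, in envelope units.
#' @return data frame with columns `position` (1-based sample index) and
#'   `value`, in increasing position order.
#' @export
detect_peaks <- function(E, delta) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  n <- length(E)
  pos <- integer(0); val <- numeric(0)
  m_x <- -Inf; m_xpos <- 0L; m_n <- Inf
  look_for_max <- TRUE
  for (i in seq_len(n)) {
    t <- E[i]
    if (look_for_max) {
      if (t > m_x) { m_x <- t; m_xpos <- i }
      if (t < m_x - delta) {          # fell a full delta: commit the max,
        pos <- c(pos, m_xpos)         # then track the valley until the
        val <- c(val, m_x)            # signal rises delta above it
        m_n <- t
        look_for_max <- FALSE
      }
    } else {
      if (t < m_n) m_n <- t
      if (t > m_n + delta) { m_x <- t; m_xpos <- i; look_for_max <- TRUE }
    }
  }
  data.frame(position = pos, value = val)
}

#' Envelope statistics of a segment
#'
#' Three scalar features of an envelope segment: the number of detected
#' peaks, the mean distance in samples between consecutive peaks (0 when
#' fewer than two peaks), and the segment energy -- the sum of all envelope
#' samples (the envelope is itself a sum of squared scalogram magnitudes, so
#' this sum is the segment's signal energy).
#'
#' @param E numeric vector (envelope segment).
#' @param delta peak-commitment threshold for [detect_peaks()].
#' @return named numeric 3-vector: `n_peaks`, `mean_peak_dist`, `env_energy`.
#' @export
envelope_features <- function(E, delta) {
  if (length(E) == 0) return(c(n_peaks = 0, mean_peak_dist = 0, env_energy = 0))
  if (all(E == 0)) return(c(n_peaks = 0, mean_peak_dist = 0, env_energy = 0))
  pk <- detect_peaks(E, delta)
  np <- nrow(pk)
  c(n_peaks = np,
    mean_peak_dist = if (np >= 2) mean(diff(pk$position)) else 0,
    env_energy = sum(E))
}

#' Extract the 35-element feature vector from a cropped segment
#'
#' Concatenates the three envelope statistics with the 32 wavelet window
#' energies of the sound, in the fixed order
#' `[n_peaks, mean_peak_dist, env_energy, w1..w32]`. The default
#' peak-commitment threshold is `delta_frac` times the segment's envelope
#' maximum.
#'
#' @param segment a `cycle_segment` from [crop_segment()].
#' @param delta absolute peak threshold; overrides `delta_frac` when given.
#' @param delta_frac relative threshold as a fraction of the envelope
#'   maximum (default 0.25).
#' @param wavelet,levels,n_windows passed to [wavelet_window_energies()].
#' @return named numeric vector of length 35.
#' @export
extract_features <- function(segment, delta = NULL, delta_frac = 0.25,
                             wavelet = "db2", levels = 6L, n_windows = 32L) {
  stopifnot(inherits(segment, "cycle_segment"))
  if (is.null(delta)) {
    emax <- max(segment$envelope)
    delta <- if (emax > 0) delta_frac * emax else 1
  }
  env3 <- envelope_features(segment$envelope, delta)
  wen <- wavelet_window_energies(segment$sound, wavelet, levels, n_windows)
  names(wen) <- paste0("w", seq_along(wen))
  c(env3, wen)
}
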