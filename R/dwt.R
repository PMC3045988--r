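## Orthogonal periodized discrete wavelet transform (pyramid algorithm).
## Daubechies scaling filters are standard constants (extremal-phase family).

.db_filters <- list(
  db2 = c(0.48296291314453416, 0.83651630373780790,
          0.22414386804201340, -0.12940952255126037),
  db5 = c(0.16010239797419293, 0.60382926979718960, 0.72430852843777290,
          0.13842814590132074, -0.24229488706638203, -0.03224486958463837,
          0.07757149384004572, -0.00624149021279827, -0.01258075199908200,
          0.00333572528547377)
)

.wavelet_filter <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h))
    stop("unsupported wavelet '", wavelet, "' (available: ",
         paste(names(.db_filters), collapse = ", "), ")", call. = FALSE)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror highpass
  list(h = h, g = g, L = L)
}

## One analysis step: circular correlation with h/g, downsample by 2.
.dwt_step <- function(x, flt) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(flt$L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    a <- a + flt$h[j] * x[idx]
    d <- d + flt$g[j] * x[idx]
  }
  list(a = a, d = d)
}

## One synthesis step (transpose of the analysis operator).
.idwt_step <- function(a, d, flt, n_out) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(flt$L)) {
    idx <- (base + (j - 1L)) %% n + 1L
    contrib <- flt$h[j] * a + flt$g[j] * d
    x[idx] <- x[idx] + contrib
  }
  x[seq_len(n_out)]
}

#' Discrete wavelet decomposition
#'
#' Multi-level orthogonal DWT with periodic boundary handling. Odd-length
#' inputs at any level are zero-padded by one sample before the step; the
#' original lengths are recorded so [idwt()] can restore them.
#'
#' @param x numeric vector.
#' @param wavelet filter name, one of `"db2"`, `"db5"`.
#' @param levels decomposition depth.
#' @return an object of class `pcg_dwt`: list with `approx` (coarsest
#'   approximation), `details` (list, finest level first), `lengths`,
#'   `wavelet`, `levels`.
#' @seealso [idwt()], [wavelet_window_energies()]
#' @export
dwt <- function(x, wavelet = "db2", levels = 6L) {
  stopifnot(is.numeric(x), levels >= 1L)
  flt <- .wavelet_filter(wavelet)
  if (length(x) < flt$L * 2^(levels - 1))
    stop("signal of length ", length(x), " too short for a ", levels,
         "-level ", wavelet, " decomposition", call. = FALSE)
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, 0)
    st <- .dwt_step(cur, flt)
    details[[lev]] <- st$d
    cur <- st$a
  }
  structure(list(approx = cur, details = details, lengths = lengths,
                 wavelet = wavelet, levels = levels),
            class = "pcg_dwt")
}

#' Inverse discrete wavelet transform
#'
#' @param w a `pcg_dwt` object from [dwt()].
#' @return numeric vector of the original length.
#' @export
idwt <- function(w) {
  stopifnot(inherits(w, "pcg_dwt"))
  flt <- .wavelet_filter(w$wavelet)
  cur <- w$approx
  for (lev in rev(seq_len(w$levels))) {
    n_out <- w$lengths[lev]
    n_pad <- n_out + n_out %% 2L
    cur <- .idwt_step(cur, w$details[[lev]], flt, n_pad)[seq_len(n_out)]
  }
  cur
}
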