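#' Fit a principal-component reduction of the feature matrix
#'
#' Computes the sample covariance `C = 1/(n-1) sum (a_i - abar)(a_i - abar)^T`
#' of the training rows, its eigendecomposition, and keeps the smallest
#' number `k` of leading eigenvectors whose cumulative eigenvalue sum
#' exceeds `retain` of the total. Each eigenvector's sign is fixed by making
#' its largest-magnitude entry positive, so fits are reproducible.
#'
#' Features mix units (counts, sample distances, energies); set
#' `standardize = TRUE` to scale columns to unit variance first (then `C` is
#' the correlation matrix).
#'
#' @param X numeric matrix, one row per example (35 columns in the standard
#'   pipeline).
#' @param retain fraction of total variance to retain (default 0.9).
#' @param standardize scale columns to unit variance before fitting.
#' @return object of class `pcg_pca`: `mean`, `sd` (or NULL), `rotation`
#'   (`k x p`, eigenvector rows), `eigenvalues` (all `p`, non-increasing),
#'   `k`, `variance_fraction`.
#' @export
fit_pca <- function(X, retain = 0.9, standardize = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit PCA", call. = FALSE)
  .assert_finite(X, "feature matrix")
  mu <- colMeans(X)
  sdv <- NULL
  Xc <- sweep(X, 2, mu)
  if (standardize) {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  C <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)            # clamp tiny negative roundoff
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {      # sign convention
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  S <- sum(vals)
  if (S <= 0) {
    k <- 1L
    vfrac <- 1
  } else {
    k <- which(cumsum(vals) > retain * S)[1]
    if (is.na(k)) k <- length(vals)        # retain = 1: keep everything
    vfrac <- cumsum(vals)[k] / S
  }
  structure(list(mean = mu, sd = sdv, rotation = t(vecs[, seq_len(k), drop = FALSE]),
                 eigenvalues = vals, k = as.integer(k),
                 variance_fraction = vfrac, retain = retain),
            class = "pcg_pca")
}

#' Project feature vectors onto the retained principal components
#'
#' @param object a `pcg_pca` model.
#' @param newdata numeric vector of length `p` or matrix with `p` columns.
#' @param ... unused.
#' @return a `k`-vector, or an `n x k` matrix for matrix input.
#' @export
predict.pcg_pca <- function(object, newdata, ...) {
  single <- is.null(dim(newdata))
  Xn <- if (single) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(Xn) != length(object$mean))
    stop("feature dimension ", ncol(Xn), " does not match model dimension ",
         length(object$mean), call. = FALSE)
  Xc <- sweep(Xn, 2, object$mean)
  if (!is.null(object$sd)) Xc <- sweep(Xc, 2, object$sd, "/")
  out <- Xc %*% t(object$rotation)
  if (single) drop(out) else out
}

#' @export
print.pcg_pca <- function(x, ...) {
  cat(sprintf("<pcg_pca> %d -> %d components (%.1f%% variance retained)\n",
              length(x$mean), x$k, 100 * x$variance_fraction))
  invisible(x)
}
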