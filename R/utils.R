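# Shared helpers: circular A-line arithmetic, interval handling, image resize.
# Frames are matrices with rows = A-lines (theta, circular) and columns =
# depth (r). Pullback volumes are arrays (frame x A-line x depth).

#' Indices of a circular A-line interval
#'
#' @param start 1-based first A-line of the interval.
#' @param len interval length in A-lines (0 gives an empty interval).
#' @param n_alines number of A-lines per frame.
#' @return integer vector of 1-based A-line indices, wrapping past `n_alines`.
#' @keywords internal
circ_interval <- function(start, len, n_alines) {
  if (len <= 0) return(integer(0))
  ((start - 1L + seq_len(len) - 1L) %% n_alines) + 1L
}

#' @keywords internal
circ_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

# Smallest circular gap between interval centers, in A-lines.
interval_center <- function(start, len, n) {
  ((start - 1 + (len - 1) / 2) %% n) + 1
}

#' Bilinear interpolation matrix
#'
#' Maps a length-`n_in` axis onto `n_out` samples with the half-pixel-center
#' convention; rows sum to 1, so the transpose is the exact adjoint used by
#' the CNN decoder's backward pass.
#' @keywords internal
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    A[, 1] <- 1
    return(A)
  }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  w <- src - lo
  lo <- as.integer(lo) + 1L
  hi <- pmin(lo + 1L, n_in)
  idx <- seq_len(n_out)
  A[cbind(idx, lo)] <- A[cbind(idx, lo)] + (1 - w)
  A[cbind(idx, hi)] <- A[cbind(idx, hi)] + w
  A
}

#' Bilinear resize of a 2-D image
#'
#' @param img numeric matrix.
#' @param dims target `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, dims) {
  stopifnot(is.matrix(img), length(dims) == 2L, all(dims >= 1))
  Ar <- interp_matrix(dims[1], nrow(img))
  Ac <- interp_matrix(dims[2], ncol(img))
  Ar %*% img %*% t(Ac)
}

# Reflect-pad a matrix by (pr, pc) on each side (border handling for the
# Gaussian filter). Reflection excludes the edge pixel (scipy 'mirror').
reflect_pad <- function(x, pr, pc) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(n), n - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(m), m - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

# Otsu's threshold on intensities in [0, 1]; part of the deterministic
# baseline lumen detector. 256-bin histogram, maximizes between-class
# variance.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  h <- tabulate(pmin(pmax(floor(x * levels), 0), levels - 1L) + 1L, levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 1L))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (k - 0.5) / levels
}

# Quantize intensities to the 16-bit grid used by the TIFF writer.
quantize16 <- function(x) round(x * 65535) / 65535

`%||%` <- function(a, b) if (is.null(a)) b else a
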