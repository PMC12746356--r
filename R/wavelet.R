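# Separable 3D orthogonal discrete wavelet transform with periodic
# boundaries. Only what the compressed-sensing solver needs: an exactly
# invertible, norm-preserving sparsifying transform. Daubechies-4 (default)
# and Haar filters.

wavelet_filters <- function(name = c("db4", "haar")) {
  name <- match.arg(name)
  h <- switch(name,
    db4  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    haar = c(1, 1) / sqrt(2))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror highpass
  list(h = h, g = g)
}

# One periodized analysis step along the first dimension of a matrix
# (columns are signals): returns rbind(approx, detail), each n/2 rows.
dwt_step_cols <- function(m, filt) {
  n <- nrow(m); L <- length(filt$h)
  if (n %% 2L != 0L) stop("signal length must be even for a DWT level")
  # y_a[k] = sum_j h[j] * x[(2k-1) + (j-1) mod n], k = 1..n/2
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, `+`)
  idx <- (idx - 1L) %% n + 1L
  a <- matrix(0, n / 2, ncol(m)); d <- matrix(0, n / 2, ncol(m))
  for (j in seq_len(L)) {
    rows <- idx[, j]
    a <- a + filt$h[j] * m[rows, , drop = FALSE]
    d <- d + filt$g[j] * m[rows, , drop = FALSE]
  }
  rbind(a, d)
}

# Inverse of dwt_step_cols: input rbind(approx, detail).
idwt_step_cols <- function(m, filt) {
  n2 <- nrow(m) / 2; n <- 2L * n2; L <- length(filt$h)
  a <- m[seq_len(n2), , drop = FALSE]; d <- m[n2 + seq_len(n2), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  if (is.complex(m)) out <- matrix(0i, n, ncol(m))
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, `+`)
  idx <- (idx - 1L) %% n + 1L
  for (j in seq_len(L)) {
    rows <- idx[, j]
    contrib <- filt$h[j] * a + filt$g[j] * d
    # scatter-add; rows may repeat across k only if L > n, excluded by use
    out[rows, ] <- out[rows, ] + contrib
  }
  out
}

# Apply a column-wise step along axis `ax` of a 3D array.
apply_axis <- function(x, ax, fun) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  m <- fun(m)
  dim(m) <- c(nrow(m), dp[2], dp[3])
  aperm(m, order(perm))
}

#' 3D orthogonal discrete wavelet transform
#'
#' Multi-level separable DWT with periodic boundary handling. The
#' transform is orthogonal: it preserves the Euclidean norm and
#' \code{idwt3d(dwt3d(x))} reconstructs \code{x} to machine precision.
#' Coefficients are returned in place (approximation band in the low-index
#' corner at each level), which is all the thresholding in
#' [cs_reconstruct()] needs.
#'
#' @param x 3D numeric or complex array; every dimension must be divisible
#'   by \code{2^levels}.
#' @param wavelet \code{"db4"} (Daubechies-4, default) or \code{"haar"}.
#' @param levels decomposition depth (default 3).
#' @return Array of wavelet coefficients, same shape as \code{x}.
#' @export
dwt3d <- function(x, wavelet = "db4", levels = 3L) {
  filt <- wavelet_filters(wavelet)
  d <- dim(x)
  if (any(d %% 2^levels != 0))
    stop("all dimensions must be divisible by 2^levels")
  out <- x
  cur <- d
  for (l in seq_len(levels)) {
    sub <- out[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3]), drop = FALSE]
    for (ax in 1:3) sub <- apply_axis(sub, ax, function(m) dwt_step_cols(m, filt))
    out[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3])] <- sub
    cur <- cur %/% 2L
  }
  out
}

#' Inverse 3D orthogonal discrete wavelet transform
#'
#' @param w coefficient array from [dwt3d()].
#' @inheritParams dwt3d
#' @return Reconstructed array, same shape as \code{w}.
#' @export
idwt3d <- function(w, wavelet = "db4", levels = 3L) {
  filt <- wavelet_filters(wavelet)
  d <- dim(w)
  out <- w
  for (l in rev(seq_len(levels))) {
    cur <- d %/% (2L^(l - 1L))
    sub <- out[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3]), drop = FALSE]
    for (ax in 3:1) sub <- apply_axis(sub, ax, function(m) idwt_step_cols(m, filt))
    out[seq_len(cur[1]), seq_len(cur[2]), seq_len(cur[3])] <- sub
  }
  out
}
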