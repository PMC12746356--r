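# Internal numeric helpers shared across modules.

#' Unitary n-dimensional FFT
#'
#' Forward and inverse discrete Fourier transforms scaled by 1/sqrt(N) so
#' that the transform is unitary (Parseval holds exactly). All k-space in
#' the package uses this convention; it makes the Lipschitz constant of the
#' masked-FFT normal operator equal to one, which the compressed-sensing
#' solver relies on.
#'
#' @param x numeric or complex array.
#' @return complex array of the same shape.
#' @keywords internal
#' @noRd
fftn_u <- function(x) stats::fft(x) / sqrt(length(x))

#' @noRd
ifftn_u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Signed integer frequencies 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1
#' @noRd
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Fourier-domain translation of a 3D array
#'
#' Shifts `x` by `shift_vox` voxels (possibly fractional) under periodic
#' boundary conditions: result(r) = x(r - shift). Exact for integer shifts,
#' interpolation-free for fractional ones.
#'
#' @param x 3D numeric or complex array.
#' @param shift_vox length-3 shift in voxels.
#' @return array of the same shape and mode (complex if input complex).
#' @keywords internal
#' @noRd
fourier_shift <- function(x, shift_vox) {
  d <- dim(x)
  stopifnot(length(d) == 3L, length(shift_vox) == 3L)
  if (all(shift_vox == 0)) return(x)
  # even-length Nyquist frequency zeroed for fractional shifts (keeps result real)
  kx <- fft_freq(d[1]) / d[1]; ky <- fft_freq(d[2]) / d[2]; kz <- fft_freq(d[3]) / d[3]
  if (d[1] %% 2L == 0L && shift_vox[1] %% 1 != 0) kx[d[1] / 2 + 1] <- 0
  if (d[2] %% 2L == 0L && shift_vox[2] %% 1 != 0) ky[d[2] / 2 + 1] <- 0
  if (d[3] %% 2L == 0L && shift_vox[3] %% 1 != 0) kz[d[3] / 2 + 1] <- 0
  ramp <- outer(outer(kx * shift_vox[1], ky * shift_vox[2], `+`), kz * shift_vox[3], `+`)
  out <- stats::fft(stats::fft(x) * exp(-2i * pi * ramp), inverse = TRUE) / length(x)
  if (!is.complex(x)) out <- Re(out)
  out
}

#' Gaussian smoothing of a 3D array (periodic, FFT-based)
#'
#' @param x 3D numeric array.
#' @param sigma isotropic standard deviation in voxels; 0 returns `x`.
#' @keywords internal
#' @noRd
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  g1 <- function(n) {
    u <- fft_freq(n)
    k <- exp(-u^2 / (2 * sigma^2))
    k / sum(k)
  }
  ker <- outer(outer(g1(d[1]), g1(d[2]), `*`), g1(d[3]), `*`)
  out <- Re(stats::fft(stats::fft(x) * stats::fft(ker), inverse = TRUE) / length(x))
  out
}

#' Trilinear interpolation in a 3D array
#'
#' Coordinates are continuous 1-based array subscripts. Points outside the
#' array (beyond half a voxel past the boundary sample) return NA; points in
#' the half-voxel rim are clamped.
#'
#' @param a 3D numeric array.
#' @param x,y,z equal-length coordinate vectors (1-based subscripts).
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
interp_trilinear <- function(a, x, y, z) {
  d <- dim(a)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0.5 & x <= d[1] + 0.5 & y >= 0.5 & y <= d[2] + 0.5 &
        z >= 0.5 & z <= d[3] + 0.5
  if (!any(ok)) return(out)
  xc <- pmin(pmax(x[ok], 1), d[1]); yc <- pmin(pmax(y[ok], 1), d[2])
  zc <- pmin(pmax(z[ok], 1), d[3])
  x0 <- pmin(floor(xc), d[1] - 1L); y0 <- pmin(floor(yc), d[2] - 1L)
  z0 <- pmin(floor(zc), d[3] - 1L)
  fx <- xc - x0; fy <- yc - y0; fz <- zc - z0
  idx <- function(i, j, k) a[cbind(i, j, k)]
  v <- idx(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
       idx(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
       idx(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
       idx(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
       idx(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
       idx(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
       idx(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
       idx(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out[ok] <- v
  out
}

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never
#' perturbs the user's random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Scatter-accumulate: mean of `values` grouped by integer destination index.
# Returns list(sum, count) as dense vectors of length n.
#' @noRd
accumulate_mean <- function(dest, values, n) {
  counts <- tabulate(dest, nbins = n)
  sums <- numeric(n)
  rs <- rowsum(values, dest)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  list(sum = sums, count = counts)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
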