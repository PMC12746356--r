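#' Compressed-sensing reconstruction settings
#'
#' @param lam soft-threshold weight on the wavelet l1 term (in units of the
#'   k-space data scale). Default 0.01.
#' @param n_iter ISTA iteration count (default 40).
#' @param wavelet sparsifying basis, \code{"db4"} (default) or \code{"haar"}.
#' @param levels wavelet decomposition depth (default 3).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @return Object of class \code{recon_config}.
#' @export
recon_config <- function(lam = 0.01, n_iter = 40L, wavelet = "db4",
                         levels = 3L, tol = 1e-6) {
  stopifnot(lam >= 0, n_iter >= 1)
  structure(list(lam = lam, n_iter = as.integer(n_iter), wavelet = wavelet,
                 levels = as.integer(levels), tol = tol),
            class = "recon_config")
}

#' Zero-filled reconstruction
#'
#' The baseline image formation: inverse (unitary) FFT of the masked
#' k-space, unsampled locations left at zero.
#'
#' @param kspace complex 3D array of (already masked) k-space samples.
#' @param mask optional \code{\link{make_mask}} result; if given, the
#'   masking is (re)applied before the inverse transform.
#' @param spacing,origin grid geometry for the returned volume.
#' @return A complex \code{\link{voxel_grid}}.
#' @export
zero_fill <- function(kspace, mask = NULL, spacing = c(1.2, 1.2, 1.2),
                      origin = c(0, 0, 0)) {
  if (!is.null(mask)) kspace <- kspace * expand_mask3d(mask, dim(kspace))
  voxel_grid(ifftn_u(kspace), spacing, origin)
}

# Soft-threshold complex (or real) values by magnitude.
soft_threshold <- function(x, t) {
  m <- Mod(x)
  scale <- pmax(0, 1 - t / pmax(m, .Machine$double.eps))
  x * scale
}

#' Iterative compressed-sensing reconstruction (ISTA)
#'
#' Approximately minimizes
#' \deqn{f(x) = \tfrac12 \| M F x - y \|_2^2 + \lambda \| \Psi x \|_1}
#' with \eqn{F} the unitary FFT, \eqn{M} the sampling mask, and \eqn{\Psi}
#' an orthogonal 3D wavelet transform, by proximal gradient descent with
#' unit step (the Lipschitz constant of the masked unitary-FFT normal
#' operator is 1). Plain ISTA is used rather than an accelerated variant
#' so the objective is guaranteed non-increasing, which the solver checks
#' each iteration.
#'
#' @param kspace complex 3D array of measured (masked) k-space.
#' @param mask a \code{\link{make_mask}} result describing the sampling.
#' @param cfg a \code{\link{recon_config}}.
#' @param spacing,origin grid geometry for the returned volume.
#' @return A complex \code{\link{voxel_grid}} with attribute
#'   \code{"objective"}: the per-iteration objective trace.
#' @export
cs_reconstruct <- function(kspace, mask, cfg = recon_config(),
                           spacing = c(1.2, 1.2, 1.2), origin = c(0, 0, 0)) {
  shape <- dim(kspace)
  m3 <- expand_mask3d(mask, shape)
  y <- kspace * m3
  x <- ifftn_u(y)                      # zero-fill start
  l1 <- function(x) sum(Mod(dwt3d(x, cfg$wavelet, cfg$levels)))
  objective <- function(x) {
    r <- fftn_u(x) * m3 - y
    0.5 * sum(Mod(r)^2) + cfg$lam * l1(x)
  }
  obj <- numeric(cfg$n_iter)
  prev <- objective(x)
  for (it in seq_len(cfg$n_iter)) {
    grad <- ifftn_u(fftn_u(x) * m3 - y)
    z <- x - grad
    if (cfg$lam > 0) {
      w <- dwt3d(z, cfg$wavelet, cfg$levels)
      z <- idwt3d(soft_threshold(w, cfg$lam), cfg$wavelet, cfg$levels)
    }
    cur <- objective(z)
    if (cur > prev * (1 + 1e-8) + 1e-12)
      stop(sprintf("ISTA objective increased at iteration %d (%.6g -> %.6g)",
                   it, prev, cur))
    x <- z
    obj[it] <- cur
    if (it > 1 && abs(obj[it - 1] - cur) <= cfg$tol * max(abs(prev), 1e-12)) {
      obj <- obj[seq_len(it)]
      break
    }
    prev <- cur
  }
  out <- voxel_grid(x, spacing, origin)
  attr(out, "objective") <- obj
  out
}
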