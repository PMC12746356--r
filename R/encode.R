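#' Pseudo-random variable-density sampling mask
#'
#' Bernoulli sampling pattern over the two phase-encode dimensions (the
#' readout axis is always fully sampled). Sampling probability falls off
#' from the k-space center as \eqn{(1-r)^{p}}; a central calibration block
#' is always fully sampled; the density scale is calibrated so the
#' expected sampled fraction equals \code{1/accel}. Deterministic per seed.
#'
#' @param shape two integers: the phase-encode matrix size.
#' @param accel nominal acceleration factor (>= 1).
#' @param calib_size width in lines of the fully sampled central square.
#' @param seed integer RNG seed.
#' @param density_pow fall-off exponent of the variable density (default 3).
#' @return Object of class \code{sampling_mask}: fields \code{mask}
#'   (logical matrix), \code{accel_nominal}, \code{calib_size},
#'   \code{seed}, \code{fraction} (achieved sampled fraction).
#' @export
make_mask <- function(shape, accel, calib_size = 8L, seed = 1L,
                      density_pow = 3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, accel >= 1)
  if (calib_size >= min(shape))
    stop("calib_size must be smaller than the smallest mask dimension")
  cy <- (shape[1] - 1) / 2; cz <- (shape[2] - 1) / 2
  ry <- abs(seq_len(shape[1]) - 1 - cy) / max(cy, 0.5)
  rz <- abs(seq_len(shape[2]) - 1 - cz) / max(cz, 0.5)
  r <- pmin(sqrt(outer(ry^2, rz^2, `+`)), 1)
  g <- (1 - r)^density_pow
  calib <- matrix(FALSE, shape[1], shape[2])
  iy <- seq.int(floor(cy - calib_size / 2) + 1, length.out = calib_size)
  iz <- seq.int(floor(cz - calib_size / 2) + 1, length.out = calib_size)
  calib[iy, iz] <- TRUE
  target <- 1 / accel
  reachable <- mean(pmax((g > 0) * 1, calib))   # corners with zero density never sample
  if (target >= reachable) {
    prob <- matrix(1, shape[1], shape[2])
  } else if (mean(calib) >= target) {
    prob <- ifelse(calib, 1, 0)
  } else {
    # calibrate the density scale so E[fraction] hits the target exactly
    f <- function(s) mean(pmax(pmin(s * g, 1), calib)) - target
    s <- stats::uniroot(f, c(0, 1e9), tol = 1e-10)$root
    prob <- pmax(pmin(s * g, 1), calib)
  }
  m <- with_seed(seed, matrix(stats::runif(prod(shape)) < prob, shape[1], shape[2]))
  m[calib] <- TRUE
  structure(list(mask = m, accel_nominal = accel, calib_size = calib_size,
                 seed = seed, fraction = mean(m)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %dx%d, nominal accel %g, sampled fraction %.4f\n",
              nrow(x$mask), ncol(x$mask), x$accel_nominal, x$fraction))
  invisible(x)
}

# Expand a 2D phase-encode mask to the full 3D k-space grid (readout =
# axis 1). The mask is defined in the centered k-space view; the FFT puts
# DC at index [1,1], so an inverse fftshift aligns the calibration block
# with the actual low frequencies.
expand_mask3d <- function(mask, shape) {
  if (!all(dim(mask$mask) == shape[2:3]))
    stop("mask shape must match the two phase-encode dimensions")
  m <- mask$mask
  sh <- function(n) { k <- floor(n / 2); c((k + 1):n, 1:k) }  # ifftshift
  m <- m[sh(nrow(m)), sh(ncol(m))]
  array(rep(as.vector(m), each = shape[1]), shape)
}

#' Simulate a four-point flow-encoded acquisition
#'
#' Turns a \code{\link{build_phantom}} result into an
#' \code{\link{encoded_study}}. Volume k is
#' \deqn{T_k\{\, M(r)\, e^{\,i (\pi/VENC)\, m_k \cdot v(r)}\,\} + n(r)}
#' with \eqn{T_k} a rigid translation (applied in k-space, exact under
#' periodic boundaries), \eqn{m_k} row k of the encoding matrix, and
#' \eqn{n} complex Gaussian noise with per-channel SD
#' \code{max(M)/noise_snr}. Phase is intrinsically wrapped (complex
#' representation); if the true speed anywhere reaches VENC the study is
#' flagged, never unwrapped. With a sampling mask, each volume passes
#' through FFT, masking, and zero-filled inverse FFT; the raw masked
#' k-space is attached when \code{keep_kspace = TRUE}.
#'
#' @param phantom a \code{digital_phantom}.
#' @param params an \code{\link{acq_params}}.
#' @param scheme an \code{\link{encoding_scheme}}.
#' @param translations 4 x 3 matrix of per-volume rigid shifts in mm
#'   (row 1 conventionally zero).
#' @param noise_snr peak-magnitude-to-noise-SD ratio; Inf for noise-free.
#'   Default 30.
#' @param mask optional \code{\link{make_mask}} result applied to the two
#'   phase-encode axes (axes 2 and 3).
#' @param seed RNG seed for the noise draw.
#' @param eddy_velocity optional function \code{(W) -> n x 3} of world
#'   coordinates (relative to the grid center, mm) returning a spurious
#'   additive velocity offset in cm/s; emulates eddy-current /
#'   concomitant-field background phase.
#' @param keep_kspace attach masked k-space (list of 4 complex arrays) as
#'   attribute \code{"kspace"} for the reconstruction module.
#' @return An \code{\link{encoded_study}}.
#' @export
encode_study <- function(phantom, params = acq_params(),
                         scheme = encoding_scheme("balanced"),
                         translations = matrix(0, 4, 3), noise_snr = 30,
                         mask = NULL, seed = NULL, eddy_velocity = NULL,
                         keep_kspace = FALSE) {
  if (qr(scheme$matrix)$rank < 3L) stop("encoding scheme matrix must have rank 3")
  translations <- rbind(translations)
  stopifnot(nrow(translations) == 4L, ncol(translations) == 3L)
  magg <- phantom$magnitude
  shape <- magg$shape
  v <- phantom$truth$v$data
  if (!is.null(eddy_velocity)) {
    W <- world_mesh(magg)
    ctr <- magg$origin + (shape - 1) * magg$spacing / 2
    off <- eddy_velocity(cbind(as.vector(W$x) - ctr[1],
                               as.vector(W$y) - ctr[2],
                               as.vector(W$z) - ctr[3]))
    v <- v + array(off, c(shape, 3L))
  }
  nvox <- prod(shape)
  vmat <- matrix(v, nvox, 3)
  sd_noise <- if (is.finite(noise_snr)) max(magg$data) / noise_snr else 0
  m3 <- if (!is.null(mask)) expand_mask3d(mask, shape) else NULL
  vols <- vector("list", 4)
  kspace <- if (keep_kspace) vector("list", 4) else NULL
  with_seed(seed, {
    for (k in 1:4) {
      phase <- (pi / params$venc) * as.vector(vmat %*% scheme$matrix[k, ])
      vol <- array(magg$data * exp(1i * phase), shape)
      if (any(translations[k, ] != 0))
        vol <- fourier_shift(vol, translations[k, ] / magg$spacing)
      if (sd_noise > 0)
        vol <- vol + complex(real = stats::rnorm(nvox, 0, sd_noise),
                             imaginary = stats::rnorm(nvox, 0, sd_noise))
      if (!is.null(m3)) {
        ks <- fftn_u(vol) * m3
        if (keep_kspace) kspace[[k]] <- ks
        vol <- ifftn_u(ks)
      }
      vols[[k]] <- voxel_grid(vol, magg$spacing, magg$origin)
    }
  })
  study <- encoded_study(vols, params, scheme, true_translations = translations)
  study$wrap_flag <- isTRUE(phantom$venc_exceeded) ||
    max(phantom$truth$speed$data) >= params$venc
  if (keep_kspace) {
    attr(study, "kspace") <- kspace
    attr(study, "mask") <- mask
  }
  study
}
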