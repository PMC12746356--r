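#' Velocity field container
#'
#' @param v \code{\link{voxel_grid}} with 4D data (last extent 3), cm/s.
#' @param magnitude companion anatomical scalar \code{\link{voxel_grid}}.
#' @param wrap_flag was phase wrapping detected / possible?
#' @return Object of class \code{velocity_field} with derived \code{speed}
#'   (scalar grid of Euclidean norms).
#' @export
velocity_field <- function(v, magnitude, wrap_flag = FALSE) {
  stopifnot(length(dim(v$data)) == 4L)
  sp <- sqrt(v$data[, , , 1]^2 + v$data[, , , 2]^2 + v$data[, , , 3]^2)
  structure(list(v = v, speed = grid_like(magnitude, sp),
                 magnitude = magnitude, wrap_flag = wrap_flag),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s, peak speed %.2f cm/s%s\n",
              paste(x$v$shape, collapse = "x"), max(x$speed$data),
              if (isTRUE(x$wrap_flag)) " [wrap flagged]" else ""))
  invisible(x)
}

#' Decode velocities from a four-point study
#'
#' Solves, per voxel, the linear phase model
#' \eqn{\phi_k = (\pi/VENC)\, m_k \cdot v + \phi_0} for the three velocity
#' components. For the "referenced" scheme the reference phase is
#' cancelled by complex phase differencing against volume 1
#' (\eqn{\Delta\phi_k = \arg(S_k \bar S_0)}) followed by a 3 x 3 solve; for
#' the "balanced" scheme all four wrapped phases enter a least-squares
#' solve with design \eqn{[(\pi/VENC) M \;|\; 1]} whose offset column
#' absorbs \eqn{\phi_0}. No phase unwrapping is performed anywhere; the
#' study is flagged if any decoded component reaches VENC.
#'
#' @param study an \code{\link{encoded_study}} (volumes aligned, i.e.
#'   post motion correction where applicable).
#' @param magnitude optional anatomical magnitude grid to attach (default:
#'   mean magnitude of the four volumes).
#' @return A \code{\link{velocity_field}} in cm/s.
#' @export
decode_velocity <- function(study, magnitude = NULL) {
  M <- study$scheme$matrix
  if (qr(M)$rank < 3L) stop("encoding scheme matrix must have rank 3")
  venc <- study$params$venc
  shape <- study$volumes[[1]]$shape
  nvox <- prod(shape)
  if (study$scheme$name == "referenced") {
    ref <- study$volumes[[1]]$data
    dphi <- vapply(2:4, function(k)
      as.vector(Arg(study$volumes[[k]]$data * Conj(ref))), numeric(nvox))
    A <- (pi / venc) * M[2:4, , drop = FALSE]
    vmat <- t(solve(A, t(dphi)))
  } else {
    phi <- vapply(1:4, function(k)
      as.vector(Arg(study$volumes[[k]]$data)), numeric(nvox))
    A <- cbind((pi / venc) * M, 1)
    P <- solve(crossprod(A), t(A))     # least-squares pseudoinverse
    sol <- t(P %*% t(phi))
    vmat <- sol[, 1:3, drop = FALSE]
  }
  if (is.null(magnitude)) {
    avg <- Reduce(`+`, lapply(study$volumes, function(g) Mod(g$data))) / 4
    magnitude <- grid_like(study$volumes[[1]], avg)
  }
  vg <- voxel_grid(array(vmat, c(shape, 3L)),
                   study$volumes[[1]]$spacing, study$volumes[[1]]$origin)
  velocity_field(vg, magnitude,
                 wrap_flag = isTRUE(study$wrap_flag) || max(abs(vmat)) >= venc)
}

#' Fit and remove a smooth background-velocity offset
#'
#' Eddy currents and concomitant (Maxwell) gradient fields leave a slowly
#' varying spurious phase that decodes into a spatially smooth velocity
#' offset. This is modelled per component as a quadratic polynomial in
#' world coordinates (relative to the grid center), least-squares fitted
#' on static-tissue voxels only, then subtracted everywhere. The audit
#' value \code{lumen_fraction_pct} reports the mean fitted background
#' speed inside the lumen as a percentage of the mean lumen speed — the
#' quantity used to decide whether the correction matters at all.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param static_mask logical \code{\link{voxel_grid}} of static-tissue
#'   voxels (must exclude lumina; >= 10 voxels).
#' @param lumen_mask optional logical \code{\link{voxel_grid}} of lumen
#'   voxels used for the audit percentage (default: voxels with speed
#'   above 10\% of the maximum).
#' @param reference_speed optional denominator (cm/s) for the audit
#'   percentage. Defaults to the mean in-lumen speed of \code{field};
#'   pass the flowing study's mean lumen speed when auditing on a
#'   no-flow (pump-off) acquisition, where \code{field}'s own lumen
#'   speed is just noise.
#' @return List with \code{model} (class \code{background_model}: fields
#'   \code{coeffs} 10 x 3, monomial basis in centered world coordinates
#'   \code{1, x, y, z, x2, y2, z2, xy, xz, yz}; \code{center};
#'   \code{static_residual_rms}; \code{lumen_fraction_pct}) and
#'   \code{corrected} (the corrected \code{\link{velocity_field}}).
#' @export
fit_background <- function(field, static_mask, lumen_mask = NULL,
                           reference_speed = NULL) {
  sm <- static_mask$data
  if (sum(sm) < 10) stop("background fit needs at least 10 static voxels")
  g <- field$v
  shape <- g$shape
  ctr <- g$origin + (shape - 1) * g$spacing / 2
  W <- world_mesh(g)
  x <- as.vector(W$x) - ctr[1]; y <- as.vector(W$y) - ctr[2]
  z <- as.vector(W$z) - ctr[3]
  X <- cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
  idx <- which(as.vector(sm))
  nvox <- prod(shape)
  vmat <- matrix(g$data, nvox, 3)
  fit <- lm.fit(X[idx, , drop = FALSE], vmat[idx, , drop = FALSE])
  coeffs <- fit$coefficients
  coeffs[is.na(coeffs)] <- 0
  dimnames(coeffs) <- list(c("1", "x", "y", "z", "x2", "y2", "z2",
                             "xy", "xz", "yz"), c("vx", "vy", "vz"))
  bg <- X %*% coeffs
  corrected_v <- vmat - bg
  resid_rms <- sqrt(mean(rowSums((vmat[idx, , drop = FALSE] -
                                  bg[idx, , drop = FALSE])^2)))
  speed <- as.vector(field$speed$data)
  lum <- if (!is.null(lumen_mask)) which(as.vector(lumen_mask$data))
         else which(speed > 0.1 * max(speed))
  denom <- reference_speed %||% if (length(lum)) mean(speed[lum]) else NA_real_
  frac <- if (length(lum) && isTRUE(denom > 0))
    100 * mean(sqrt(rowSums(bg[lum, , drop = FALSE]^2))) / denom
  else NA_real_
  model <- structure(list(coeffs = coeffs, center = ctr,
                          static_residual_rms = resid_rms,
                          lumen_fraction_pct = frac),
                     class = "background_model")
  vg <- voxel_grid(array(corrected_v, c(shape, 3L)), g$spacing, g$origin)
  list(model = model,
       corrected = velocity_field(vg, field$magnitude, field$wrap_flag))
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> quadratic, static residual RMS %.4g cm/s, lumen fraction %.3f%%\n",
              x$static_residual_rms, x$lumen_fraction_pct))
  invisible(x)
}

#' Single-step flow-displacement correction
#'
#' Moving spins are spatially encoded at times that differ per axis from
#' the flow-encoding instant, so their signal appears displaced by
#' \eqn{d = v \, \Delta t} along each axis. The correction relocates each
#' voxel's magnitude and velocity values once (no iteration) from
#' \eqn{r} to \eqn{r - d}, with \eqn{d} in mm computed from cm/s times ms
#' (factor 0.01). Destinations are the nearest voxel; colliding
#' contributions are magnitude-weighted averages (so that near-zero-signal
#' voxels, whose decoded velocity is essentially random phase noise,
#' cannot swamp a lumen voxel they land on); vacated voxels keep the
#' uncorrected value.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param params an \code{\link{acq_params}}; \code{axis_time_offsets}
#'   (ms per axis) drives the displacement. All-zero offsets make the
#'   correction the identity.
#' @param min_mag_frac voxels with magnitude below this fraction of the
#'   maximum do not move (default 0.2): where there is no signal the
#'   decoded velocity is noise and the computed displacement meaningless.
#' @return The corrected \code{\link{velocity_field}}; attribute
#'   \code{"relocation"} records counts of moved, collided and vacated
#'   voxels.
#' @export
displacement_correct <- function(field, params, min_mag_frac = 0.2) {
  dt <- params$axis_time_offsets
  g <- field$v
  shape <- g$shape
  nvox <- prod(shape)
  if (all(dt == 0)) return(field)
  vmat <- matrix(g$data, nvox, 3)
  mag <- as.vector(field$magnitude$data)
  mobile <- mag >= min_mag_frac * max(mag)
  d_mm <- sweep(vmat[mobile, , drop = FALSE], 2, dt * 0.01, `*`)  # cm/s * ms -> mm
  d_vox <- sweep(d_mm, 2, g$spacing, `/`)
  if (length(d_vox) && max(abs(d_vox)) > 3)
    warning("flow displacement exceeds 3 voxels somewhere; check axis_time_offsets")
  sub <- arrayInd(which(mobile), shape)
  dest <- round(sub - d_vox)
  for (ax in 1:3) dest[, ax] <- pmin(pmax(dest[, ax], 1), shape[ax])
  lin <- as.integer(dest[, 1] + (dest[, 2] - 1) * shape[1] +
                    (dest[, 3] - 1) * shape[1] * shape[2])
  w <- mag[mobile]
  vals <- cbind(mag, vmat)
  counts <- tabulate(lin, nbins = nvox)
  wsum <- accumulate_mean(lin, w, nvox)$sum
  acc <- lapply(1:4, function(j)
    accumulate_mean(lin, w * vals[mobile, j], nvox)$sum)
  hit <- counts > 0
  out <- vals                   # vacated / never-hit voxels keep source values
  for (j in 1:4) out[hit, j] <- acc[[j]][hit] / wsum[hit]
  reloc <- c(moved = sum(lin != which(mobile)),
             collided = sum(counts > 1),
             vacated = sum(counts[which(mobile)] == 0),
             carried_weight_in = sum(wsum), carried_weight_out = sum(w))
  vg <- voxel_grid(array(out[, 2:4], c(shape, 3L)), g$spacing, g$origin)
  mg <- grid_like(field$magnitude, array(out[, 1], shape))
  res <- velocity_field(vg, mg, field$wrap_flag)
  attr(res, "relocation") <- reloc
  res
}
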