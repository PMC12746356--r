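#' Approximate 3D Canny edge filter
#'
#' Gaussian smoothing, central-difference gradients, non-maximum
#' suppression along the gradient direction (trilinear sampling at one
#' voxel either side), then double-threshold hysteresis: weak edge voxels
#' survive only if 6-connected to a strong one. Fully deterministic.
#'
#' @param mag scalar \code{\link{voxel_grid}} (a magnitude image).
#' @param sigma Gaussian smoothing scale in voxels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 and 0.2; \code{high > low > 0}).
#' @return Object of class \code{edge_volume}: \code{edges} (logical
#'   \code{\link{voxel_grid}}), \code{sigma}, \code{thresholds}.
#' @export
canny3d <- function(mag, sigma = 1.0, low = 0.1, high = 0.2) {
  stopifnot(high > low, low > 0)
  a <- gaussian_smooth(mag$data, sigma)
  d <- dim(a)
  grad_axis <- function(x, ax) {
    hi <- x; lo <- x
    idx <- function(shift) {
      i <- pmin(pmax(seq_len(d[ax]) + shift, 1L), d[ax])
      switch(ax, x[i, , , drop = FALSE], x[, i, , drop = FALSE], x[, , i, drop = FALSE])
    }
    (idx(1L) - idx(-1L)) / 2
  }
  gx <- grad_axis(a, 1); gy <- grad_axis(a, 2); gz <- grad_axis(a, 3)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  gmax <- max(gmag)
  edges <- array(FALSE, d)
  if (gmax > 0) {
    cand <- which(gmag >= low * gmax)
    if (length(cand)) {
      sub <- arrayInd(cand, d)
      gm <- gmag[cand]
      ux <- gx[cand] / gm; uy <- gy[cand] / gm; uz <- gz[cand] / gm
      fwd <- interp_trilinear(gmag, sub[, 1] + ux, sub[, 2] + uy, sub[, 3] + uz)
      bwd <- interp_trilinear(gmag, sub[, 1] - ux, sub[, 2] - uy, sub[, 3] - uz)
      keep <- gm >= ifelse(is.na(fwd), 0, fwd) & gm >= ifelse(is.na(bwd), 0, bwd)
      weak <- array(FALSE, d); weak[cand[keep]] <- TRUE
      strong <- array(FALSE, d); strong[cand[keep & gm >= high * gmax]] <- TRUE
      edges <- hysteresis_grow(strong, weak)
    }
  }
  structure(list(edges = grid_like(mag, edges), sigma = sigma,
                 thresholds = c(low = low, high = high)),
            class = "edge_volume")
}

# Grow `strong` through `weak` by iterated 6-connected dilation.
hysteresis_grow <- function(strong, weak) {
  d <- dim(strong)
  shift_or <- function(x) {
    out <- array(FALSE, d)
    out[-1, , ] <- out[-1, , ] | x[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | x[-1, , ]
    out[, -1, ] <- out[, -1, ] | x[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | x[, -1, ]
    out[, , -1] <- out[, , -1] | x[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | x[, , -1]
    out
  }
  cur <- strong
  repeat {
    grown <- (cur | shift_or(cur)) & weak
    grown <- grown | strong
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

#' Estimate the rigid translation between two edge volumes
#'
#' Exhaustive integer-voxel search of the cross-correlation of
#' Gaussian-blurred (sigma = 1 voxel) edge maps within a search radius,
#' refined to sub-voxel precision by a separable quadratic fit around the
#' integer optimum. The returned shift \code{t} (mm) maps the moving
#' volume onto the reference: applying \code{t} to the moving volume
#' aligns it with the reference.
#'
#' @param moving_edges,ref_edges \code{edge_volume}s on the same grid.
#' @param search_mm search radius in mm (default 6).
#' @return Object of class \code{rigid_shift}: \code{t} (mm, length 3),
#'   \code{score} (similarity at the optimum), \code{search_mm}.
#' @export
estimate_translation <- function(moving_edges, ref_edges, search_mm = 6) {
  mov <- moving_edges$edges; ref <- ref_edges$edges
  if (!identical(mov$shape, ref$shape)) stop("edge volumes must share a grid")
  if (!any(mov$data) || !any(ref$data))
    stop("registration requires nonempty edge sets on both volumes")
  a <- gaussian_smooth(ref$data * 1, 1)
  b <- gaussian_smooth(mov$data * 1, 1)
  d <- dim(a)
  # S(s) = sum_x ref(x) * moving(x - s): similarity when moving is shifted by s
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / length(a)
  rad <- pmin(pmax(ceiling(search_mm / ref$spacing), 1L), (d - 1L) %/% 2L)
  offs <- function(n, r) ((-r):r) %% n + 1L
  sub <- cc[offs(d[1], rad[1]), offs(d[2], rad[2]), offs(d[3], rad[3]), drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  ivox <- as.integer(best) - (rad + 1L)   # integer shift in voxels
  # separable quadratic refinement (one axis at a time)
  frac <- numeric(3)
  for (ax in 1:3) {
    pick <- function(dlt) {
      i <- ivox; i[ax] <- i[ax] + dlt
      cc[(i[1] %% d[1]) + 1L, (i[2] %% d[2]) + 1L, (i[3] %% d[3]) + 1L]
    }
    cm <- pick(-1L); c0 <- pick(0L); cp <- pick(1L)
    den <- cm - 2 * c0 + cp
    if (den < 0) frac[ax] <- min(max(0.5 * (cm - cp) / den, -0.5), 0.5)
  }
  tvox <- ivox + frac
  structure(list(t = tvox * ref$spacing, score = max(sub), search_mm = search_mm),
            class = "rigid_shift")
}

#' @export
print.rigid_shift <- function(x, ...) {
  cat(sprintf("<rigid_shift> t = (%s) mm, score %.4g\n",
              paste(sprintf("%.3f", x$t), collapse = ", "), x$score))
  invisible(x)
}

#' Estimate shifts for all flow-encoded volumes of a study
#'
#' Runs [canny3d()] on each magnitude and registers volumes 2..4 to the
#' reference (volume 1).
#'
#' @param study an \code{\link{encoded_study}}.
#' @param search_mm search radius in mm.
#' @param sigma,low,high edge-filter settings passed to [canny3d()].
#' @return List of 3 \code{rigid_shift}s (for volumes 2, 3, 4).
#' @export
estimate_study_shifts <- function(study, search_mm = 6, sigma = 1.0,
                                  low = 0.1, high = 0.2) {
  mags <- lapply(study$volumes, function(g) grid_like(g, Mod(g$data)))
  ref_e <- canny3d(mags[[1]], sigma, low, high)
  lapply(2:4, function(k)
    estimate_translation(canny3d(mags[[k]], sigma, low, high), ref_e, search_mm))
}

#' Apply motion correction to a study
#'
#' Resamples volumes 2..4 (complex, i.e. both magnitude and phase) by
#' their estimated shifts using exact Fourier translation, and averages
#' the four aligned magnitudes into a higher-SNR anatomical image. The
#' reference volume is never altered.
#'
#' @param study an \code{\link{encoded_study}}.
#' @param shifts list of 3 \code{rigid_shift}s from
#'   [estimate_study_shifts()].
#' @return The corrected \code{\link{encoded_study}} with an extra field
#'   \code{avg_magnitude} (scalar \code{\link{voxel_grid}}) and the
#'   applied shift table as attribute \code{"shifts_mm"}.
#' @export
apply_correction <- function(study, shifts) {
  stopifnot(length(shifts) == 3L)
  vols <- study$volumes
  tab <- matrix(0, 4, 3)
  for (k in 1:3) {
    sh <- shifts[[k]]
    if (any(abs(sh$t) > sh$search_mm + 1e-9))
      stop("estimated shift exceeds the search bound; refusing to apply")
    g <- vols[[k + 1]]
    vols[[k + 1]] <- grid_like(g, fourier_shift(g$data, sh$t / g$spacing))
    tab[k + 1, ] <- sh$t
  }
  avg <- Reduce(`+`, lapply(vols, function(g) Mod(g$data))) / 4
  out <- encoded_study(vols, study$params, study$scheme,
                       true_translations = study$true_translations)
  out$wrap_flag <- study$wrap_flag
  out$avg_magnitude <- grid_like(vols[[1]], avg)
  attr(out, "shifts_mm") <- tab
  out
}
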