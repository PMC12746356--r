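#' Per-slice maximum-velocity curve
#'
#' The quantification result: maximum speed per perpendicular slice as a
#' function of arc length along a vessel centerline.
#'
#' @param arc per-slice arc position in mm.
#' @param vmax per-slice maximum speed in cm/s (NA = slice had no in-mask
#'   samples).
#' @param prune_n number of leading slices removed by [prune_ostium()].
#' @param vmean_ref,sigma_ref the 10-25 mm reference window mean and SD
#'   used by the pruning rule (NA before pruning).
#' @return Object of class \code{velocity_curve}.
#' @export
velocity_curve <- function(arc, vmax, prune_n = 0L, vmean_ref = NA_real_,
                           sigma_ref = NA_real_) {
  stopifnot(length(arc) == length(vmax))
  structure(list(arc = as.numeric(arc), vmax = as.numeric(vmax),
                 prune_n = as.integer(prune_n), vmean_ref = vmean_ref,
                 sigma_ref = sigma_ref),
            class = "velocity_curve")
}

#' @export
print.velocity_curve <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<velocity_curve> %d slices over %.1f mm; proximal (<=25 mm) peak %.2f, average %.2f cm/s%s\n",
              length(x$arc), max(x$arc), s[["peak"]], s[["average"]],
              if (x$prune_n > 0) sprintf(" (pruned %d ostial slices)", x$prune_n) else ""))
  invisible(x)
}

#' Proximal summary of a velocity curve
#'
#' Peak and average of the per-slice maxima over the proximal segment
#' (re-zeroed arc <= 25 mm), missing slices excluded.
#'
#' @param object a \code{\link{velocity_curve}} (normally after
#'   [prune_ostium()]).
#' @param max_arc proximal extent in mm (default 25).
#' @param ... unused.
#' @return Named numeric vector \code{c(peak = , average = )}.
#' @export
summary.velocity_curve <- function(object, max_arc = 25, ...) {
  sel <- object$arc <= max_arc & !is.na(object$vmax)
  if (!any(sel)) stop("no valid slices within ", max_arc, " mm")
  c(peak = max(object$vmax[sel]), average = mean(object$vmax[sel]))
}

#' @export
plot.velocity_curve <- function(x, ..., xlab = "distance along centerline [mm]",
                                ylab = "maximum velocity [cm/s]", type = "l") {
  graphics::plot(x$arc, x$vmax, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export / import a velocity curve as CSV
#'
#' Columns: \code{arc_mm}, \code{vmax_cm_s}, \code{missing}.
#' @param curve a \code{\link{velocity_curve}}.
#' @param path CSV file path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(arc_mm = curve$arc, vmax_cm_s = curve$vmax,
                              missing = is.na(curve$vmax)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  velocity_curve(df$arc_mm, df$vmax_cm_s)
}

#' Build a resampled centerline through marker points
#'
#' Natural cubic spline through the markers, resampled to \code{n_slices}
#' points equally spaced in arc length, with unit tangents from the spline
#' derivative.
#'
#' @param markers ordered m x 3 matrix of world coordinates in mm
#'   (m >= 2; manually placed or simulator truth).
#' @param n_slices number of resampled points (default 100).
#' @return Object of class \code{centerline_path}: \code{markers},
#'   \code{points} (n x 3), \code{tangents} (n x 3, unit), \code{arc}
#'   (cumulative mm from the first point).
#' @export
build_centerline <- function(markers, n_slices = 100L) {
  cl <- resample_curve(markers, n = n_slices)
  structure(list(markers = rbind(markers), points = cl$points,
                 tangents = cl$tangents, arc = cl$arc),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d points over %.1f mm (%d markers)\n",
              nrow(x$points), max(x$arc), nrow(x$markers)))
  invisible(x)
}

#' Segment a vessel around a centerline
#'
#' A fixed-radius tube around the centerline polyline, refined by
#' magnitude thresholding: voxels must also have magnitude at least
#' \code{threshold_frac} times the median magnitude of voxels within one
#' voxel of the centerline.
#'
#' @param mag scalar \code{\link{voxel_grid}} (anatomical magnitude).
#' @param path a \code{\link{build_centerline}} result.
#' @param radius_mm fixed tube radius in mm (default 2.5).
#' @param threshold_frac magnitude cutoff fraction (default 0.5); 0
#'   disables the refinement.
#' @return Object of class \code{vessel_mask}: \code{mask} (logical
#'   \code{\link{voxel_grid}}), \code{radius_mm}, \code{threshold_frac}.
#' @export
segment_vessel <- function(mag, path, radius_mm = 2.5, threshold_frac = 0.5) {
  W <- world_mesh(mag)
  vox <- cbind(as.vector(W$x), as.vector(W$y), as.vector(W$z))
  bb_lo <- apply(path$points, 2, min) - radius_mm - max(mag$spacing)
  bb_hi <- apply(path$points, 2, max) + radius_mm + max(mag$spacing)
  cand <- which(vox[, 1] >= bb_lo[1] & vox[, 1] <= bb_hi[1] &
                vox[, 2] >= bb_lo[2] & vox[, 2] <= bb_hi[2] &
                vox[, 3] >= bb_lo[3] & vox[, 3] <= bb_hi[3])
  m <- array(FALSE, mag$shape)
  if (length(cand)) {
    nn <- nearest_on_polyline(vox[cand, , drop = FALSE], path$points)
    in_tube <- nn$dist <= radius_mm
    near_cl <- nn$dist <= max(mag$spacing)
    ref_level <- stats::median(mag$data[cand[near_cl]])
    keep <- in_tube & (as.vector(mag$data)[cand] >= threshold_frac * ref_level)
    m[cand[keep]] <- TRUE
  }
  if (!any(m)) stop("segmentation produced an empty mask")
  structure(list(mask = grid_like(mag, m), radius_mm = radius_mm,
                 threshold_frac = threshold_frac),
            class = "vessel_mask")
}

#' Extract the per-slice maximum-velocity curve
#'
#' The segmentation mask is first applied to the speed volume (voxels
#' outside the mask are zeroed — random-phase background otherwise decodes
#' to loud spurious speeds that would contaminate boundary samples). For
#' each centerline point, the masked speed is then sampled (trilinear) on
#' an in-plane grid perpendicular to the local tangent — half-voxel sample
#' spacing, extent twice the mask radius. The slice value is the maximum
#' sampled speed; slices where no sample's nearest voxel lies in the mask
#' are marked missing (NA).
#'
#' @param field a \code{\link{velocity_field}}.
#' @param path a \code{\link{build_centerline}} result.
#' @param mask a \code{\link{segment_vessel}} result (same grid).
#' @return A \code{\link{velocity_curve}}.
#' @export
extract_curve <- function(field, path, mask) {
  sp <- field$speed
  if (!identical(sp$shape, mask$mask$shape)) stop("field and mask grids differ")
  r <- mask$radius_mm
  step <- min(sp$spacing) / 2
  off <- seq(-r, r, by = step)
  grid2d <- expand.grid(a = off, b = off)
  grid2d <- grid2d[grid2d$a^2 + grid2d$b^2 <= r^2, ]
  n <- nrow(path$points)
  vmax <- rep(NA_real_, n)
  mdat <- mask$mask$data
  spd <- sp$data
  spd[!mdat] <- 0                       # mask applied to the velocity volume
  for (i in seq_len(n)) {
    B <- plane_basis(path$tangents[i, ])
    pts <- path$points[rep(i, nrow(grid2d)), , drop = FALSE] +
      outer(grid2d$a, B$u) + outer(grid2d$b, B$v)
    idx <- index_coords(sp, pts) + 1
    ni <- round(idx)
    ok <- ni[, 1] >= 1 & ni[, 1] <= sp$shape[1] &
          ni[, 2] >= 1 & ni[, 2] <= sp$shape[2] &
          ni[, 3] >= 1 & ni[, 3] <= sp$shape[3]
    if (!any(ok)) next
    inmask <- ok
    inmask[ok] <- mdat[ni[ok, , drop = FALSE]]
    if (!any(inmask)) next              # slice has no in-mask voxel: missing
    vals <- interp_trilinear(spd, idx[ok, 1], idx[ok, 2], idx[ok, 3])
    if (all(is.na(vals))) next
    vmax[i] <- max(vals, na.rm = TRUE)
  }
  if (all(is.na(vmax))) stop("no slice had any in-mask sample")
  velocity_curve(arc = path$arc, vmax = vmax)
}

#' Prune overestimated ostial slices from a velocity curve
#'
#' When the first centerline marker sits too close to the parent vessel,
#' the first few slices pick up its much faster flow. The rule: compute
#' the mean \eqn{v_{mean}} and SD \eqn{\sigma} of the per-slice maxima
#' over the 10-25 mm window of the \emph{original} curve, then find the
#' smallest slice index \eqn{n \le} \code{max_n} such that
#' \eqn{v_{n+i} \le v_{mean} + \sigma} for \eqn{i = 0, 1, 2}; slices
#' before \eqn{n} are dropped and the arc is re-zeroed so slice \eqn{n}
#' becomes position 0. If no such \eqn{n} exists the curve is returned
#' unchanged (\code{prune_n = 0}) with a warning.
#'
#' @param curve a \code{\link{velocity_curve}}.
#' @param max_n maximum number of slices that may be eliminated
#'   (default 8).
#' @return The pruned \code{\link{velocity_curve}} (fields
#'   \code{prune_n}, \code{vmean_ref}, \code{sigma_ref} filled in).
#' @export
prune_ostium <- function(curve, max_n = 8L) {
  win <- which(curve$arc >= 10 & curve$arc <= 25 & !is.na(curve$vmax))
  if (length(win) < 3L) stop("the 10-25 mm reference window holds fewer than 3 slices")
  vmean <- mean(curve$vmax[win])
  sigma <- stats::sd(curve$vmax[win])
  thr <- vmean + sigma
  nsl <- length(curve$vmax)
  found <- NA_integer_
  for (n in 0:min(max_n, nsl - 3L)) {
    v3 <- curve$vmax[n + 1:3]
    if (!anyNA(v3) && all(v3 <= thr)) { found <- n; break }
  }
  if (is.na(found)) {
    warning("no compliant starting slice within max_n; curve left unchanged")
    return(velocity_curve(curve$arc, curve$vmax, prune_n = 0L,
                          vmean_ref = vmean, sigma_ref = sigma))
  }
  keep <- (found + 1L):nsl
  velocity_curve(curve$arc[keep] - curve$arc[found + 1L], curve$vmax[keep],
                 prune_n = found, vmean_ref = vmean, sigma_ref = sigma)
}
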