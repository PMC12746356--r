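#' Specify a tubular vessel for the digital flow phantom
#'
#' A vessel is a spline centerline with a radius profile, a steady
#' parabolic (Poiseuille) velocity profile, and optional focal stenoses.
#' Within a stenosis of area reduction \eqn{\alpha} the lumen radius
#' narrows to \eqn{R\sqrt{1-\alpha}} and the centerline speed rises by
#' \eqn{1/(1-\alpha)}, conserving volumetric flux.
#'
#' @param name vessel label, e.g. "LCA", "RCA", "aorta".
#' @param control_points ordered n x 3 matrix of world coordinates (mm).
#' @param radius_profile lumen radius in mm: a scalar or one value per
#'   control point (interpolated along arc length).
#' @param peak_speed centerline speed in cm/s in the unstenosed lumen.
#' @param stenoses list of stenoses, each
#'   \code{list(at = <arc mm>, length = <mm>, severity = <area fraction in [0,1)>)}.
#' @return Object of class \code{vessel_spec}.
#' @export
vessel_spec <- function(name, control_points, radius_profile, peak_speed,
                        stenoses = list()) {
  control_points <- rbind(control_points)
  nr <- nrow(control_points)
  if (length(radius_profile) == 1L) radius_profile <- rep(radius_profile, nr)
  stopifnot(length(radius_profile) == nr, all(radius_profile > 0), peak_speed >= 0)
  for (s in stenoses) {
    stopifnot(!is.null(s$at), !is.null(s$length), !is.null(s$severity))
    if (s$severity < 0 || s$severity >= 1) stop("stenosis severity must be in [0, 1)")
  }
  structure(list(name = name, control_points = control_points,
                 radius_profile = as.numeric(radius_profile),
                 peak_speed = peak_speed, stenoses = stenoses),
            class = "vessel_spec")
}

# Combined area-reduction profile alpha(s); smooth cosine-squared bump per
# stenosis, maximum over overlapping stenoses.
stenosis_alpha <- function(vessel, s) {
  a <- numeric(length(s))
  for (st in vessel$stenoses) {
    inside <- abs(s - st$at) <= st$length / 2
    prof <- numeric(length(s))
    prof[inside] <- st$severity * cos(pi * (s[inside] - st$at) / st$length)^2
    a <- pmax(a, prof)
  }
  a
}

# Dense arc-length sampling of a vessel: geometry plus local lumen radius
# and centerline speed after flux-conserving stenosis scaling.
densify_vessel <- function(vessel, step = 0.2) {
  cl <- resample_curve(vessel$control_points, step = step)
  # radius profile interpolated over the control-point arc positions
  seg <- sqrt(rowSums(diff(vessel$control_points)^2))
  cp_arc <- c(0, cumsum(seg)) / sum(seg) * cl$total
  R0 <- stats::approx(cp_arc, vessel$radius_profile, xout = cl$arc, rule = 2)$y
  alpha <- stenosis_alpha(vessel, cl$arc)
  list(points = cl$points, tangents = cl$tangents, arc = cl$arc,
       radius = R0 * sqrt(1 - alpha), vc = vessel$peak_speed / (1 - alpha),
       total = cl$total)
}

#' Build a digital flow phantom
#'
#' Rasterizes vessels onto a voxel grid: lumen voxels receive the blood
#' magnitude level and a tangent-directed parabolic velocity
#' \eqn{v(\rho) = v_c (1 - (\rho/R)^2)} at radial distance \eqn{\rho} from
#' the centerline. Where vessels overlap, the voxel takes the velocity of
#' the vessel with the smaller relative radius \eqn{\rho/R}. An optional
#' spherical "myocardium" blob provides static mid-level tissue (useful as
#' a background-phase fitting region); everything else is near-zero
#' background.
#'
#' @param vessels list of \code{\link{vessel_spec}}s.
#' @param shape grid dimensions (3 integers).
#' @param spacing voxel spacing mm, default isotropic 1.2 mm.
#' @param origin world origin mm.
#' @param tissue_levels named magnitude levels, default
#'   \code{c(blood = 1, myocardium = 0.4, background = 0.05)}.
#' @param myocardium optional \code{list(center = <mm>, radius = <mm>)}.
#' @param venc VENC (cm/s) against which the truth field is checked; if
#'   any true speed reaches it the phantom carries \code{venc_exceeded = TRUE}.
#' @return Object of class \code{digital_phantom}: fields
#'   \code{magnitude} (scalar \code{\link{voxel_grid}}), \code{truth}
#'   (a \code{velocity_field}), \code{vessels}, \code{lumen_mask},
#'   \code{venc_exceeded}.
#' @export
build_phantom <- function(vessels, shape, spacing = c(1.2, 1.2, 1.2),
                          origin = c(0, 0, 0),
                          tissue_levels = c(blood = 1, myocardium = 0.4,
                                            background = 0.05),
                          myocardium = NULL, venc = 50) {
  shape <- as.integer(shape)
  mag <- array(tissue_levels[["background"]], shape)
  grid <- voxel_grid(mag, spacing, origin)
  vel <- array(0, c(shape, 3L))
  lumen <- array(FALSE, shape)
  rho_rel <- array(Inf, shape)
  W <- world_mesh(grid)
  vox <- cbind(as.vector(W$x), as.vector(W$y), as.vector(W$z))
  lo <- origin; hi <- origin + (shape - 1) * spacing

  if (!is.null(myocardium)) {
    d2 <- (W$x - myocardium$center[1])^2 + (W$y - myocardium$center[2])^2 +
          (W$z - myocardium$center[3])^2
    mag[d2 <= myocardium$radius^2] <- tissue_levels[["myocardium"]]
  }

  for (vs in vessels) {
    dv <- densify_vessel(vs)
    margin <- 2 * spacing
    pts_lo <- dv$points - dv$radius   # per-row radius, recycled down columns
    pts_hi <- dv$points + dv$radius
    if (any(sweep(pts_lo, 2, lo + margin, `<`)) ||
        any(sweep(pts_hi, 2, hi - margin, `>`)))
      stop("vessel '", vs$name, "' exits the grid (needs a 2-voxel margin)")
    # candidate voxels: inside the padded bounding box of the centerline
    rmax <- max(dv$radius)
    bb_lo <- apply(dv$points, 2, min) - rmax - max(spacing)
    bb_hi <- apply(dv$points, 2, max) + rmax + max(spacing)
    cand <- which(vox[, 1] >= bb_lo[1] & vox[, 1] <= bb_hi[1] &
                  vox[, 2] >= bb_lo[2] & vox[, 2] <= bb_hi[2] &
                  vox[, 3] >= bb_lo[3] & vox[, 3] <= bb_hi[3])
    if (!length(cand)) next
    nn <- nearest_on_polyline(vox[cand, , drop = FALSE], dv$points)
    Rloc <- dv$radius[nn$index]
    inside <- nn$dist <= Rloc
    if (!any(inside)) next
    ci <- cand[inside]
    rr <- nn$dist[inside] / Rloc[inside]
    speed <- dv$vc[nn$index[inside]] * (1 - rr^2)
    tans <- dv$tangents[nn$index[inside], , drop = FALSE]
    take <- rr < rho_rel[ci]   # overlap tie-break: smaller relative radius wins
    ti <- ci[take]
    rho_rel[ti] <- rr[take]
    lumen[ci] <- TRUE
    mag[ci] <- tissue_levels[["blood"]]
    nvox <- prod(shape)
    vel[ti] <- speed[take] * tans[take, 1]
    vel[ti + nvox] <- speed[take] * tans[take, 2]
    vel[ti + 2 * nvox] <- speed[take] * tans[take, 3]
  }

  magg <- voxel_grid(mag, spacing, origin)
  truth <- velocity_field(voxel_grid(vel, spacing, origin), magg)
  structure(list(magnitude = magg, truth = truth, vessels = vessels,
                 lumen_mask = voxel_grid(lumen, spacing, origin),
                 tissue_levels = tissue_levels,
                 venc_exceeded = max(truth$speed$data) >= venc),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %s voxels, %d vessel(s): %s; peak true speed %.2f cm/s%s\n",
              paste(x$magnitude$shape, collapse = "x"), length(x$vessels),
              paste(vapply(x$vessels, `[[`, "", "name"), collapse = ", "),
              max(x$truth$speed$data),
              if (isTRUE(x$venc_exceeded)) " [exceeds VENC]" else ""))
  invisible(x)
}

#' Analytic ground-truth maximum-velocity curve of a phantom vessel
#'
#' Bypasses imaging entirely: per perpendicular slice along the true
#' centerline, the maximum speed of the parabolic profile is the local
#' centerline speed (after stenosis flux scaling).
#'
#' @param phantom a \code{\link{build_phantom}} result.
#' @param vessel vessel name.
#' @param n_slices number of slices along the centerline (default 100).
#' @return A \code{velocity_curve} (see [extract_curve()]).
#' @export
sample_truth_curve <- function(phantom, vessel, n_slices = 100L) {
  names <- vapply(phantom$vessels, `[[`, "", "name")
  k <- match(vessel, names)
  if (is.na(k)) stop("unknown vessel label '", vessel, "'")
  vs <- phantom$vessels[[k]]
  cl <- resample_curve(vs$control_points, n = n_slices)
  alpha <- stenosis_alpha(vs, cl$arc)
  velocity_curve(arc = cl$arc, vmax = vs$peak_speed / (1 - alpha))
}

#' Canned phantom geometries
#'
#' Convenience constructors for the study conditions used throughout the
#' tests and examples. All fit a \code{shape = c(48, 48, 48)} grid at
#' 1.2 mm isotropic spacing (57.6 mm box):
#' \describe{
#'   \item{straight_tube_spec}{an axis-aligned straight tube, radius 2 mm
#'     (4 mm diameter, the proximal coronary calibre), centerline speed
#'     15 cm/s by default.}
#'   \item{stenosed_tube_spec}{the same tube with a 50\% area-reduction
#'     stenosis of 8 mm length centered mid-vessel.}
#'   \item{curved_two_vessel_spec}{two curved coronary-like vessels
#'     (radius tapering 2.0 to 1.5 mm) with distinct peak speeds.}
#' }
#'
#' @param peak_speed centerline speed in cm/s.
#' @param severity stenosis area-reduction fraction.
#' @param stenosis_at arc position (mm) of the stenosis center.
#' @return A list of \code{\link{vessel_spec}}s.
#' @name phantom_specs
NULL

#' @rdname phantom_specs
#' @export
straight_tube_spec <- function(peak_speed = 15) {
  # along z through the grid-center voxel column of the default 48^3 grid
  c0 <- 23 * 1.2  # world x=y of voxel index 23 (0-based) = 27.6 mm
  list(vessel_spec("tube",
                   rbind(c(c0, c0, 6), c(c0, c0, 28.8), c(c0, c0, 51.6)),
                   radius_profile = 2, peak_speed = peak_speed))
}

#' @rdname phantom_specs
#' @export
stenosed_tube_spec <- function(peak_speed = 10, severity = 0.5, stenosis_at = 22.8) {
  c0 <- 23 * 1.2
  list(vessel_spec("tube",
                   rbind(c(c0, c0, 6), c(c0, c0, 28.8), c(c0, c0, 51.6)),
                   radius_profile = 2, peak_speed = peak_speed,
                   stenoses = list(list(at = stenosis_at, length = 8,
                                        severity = severity))))
}

#' @rdname phantom_specs
#' @export
curved_two_vessel_spec <- function() {
  lca <- vessel_spec("LCA",
    rbind(c(14, 14, 8), c(18, 20, 20), c(26, 26, 30), c(36, 30, 40)),
    radius_profile = c(2, 2, 1.8, 1.5), peak_speed = 16)
  rca <- vessel_spec("RCA",
    rbind(c(40, 38, 10), c(36, 34, 22), c(30, 34, 32), c(22, 38, 42)),
    radius_profile = c(2, 1.9, 1.7, 1.5), peak_speed = 11)
  list(lca, rca)
}

#' Read/write vessel specifications as JSON
#'
#' @param vessels list of \code{\link{vessel_spec}}s.
#' @param path JSON file path.
#' @return \code{read_vessel_spec} returns a list of vessel specs.
#' @export
write_vessel_spec <- function(vessels, path) {
  out <- lapply(vessels, function(v)
    list(name = v$name, control_points = v$control_points,
         radius_profile = v$radius_profile, peak_speed = v$peak_speed,
         stenoses = v$stenoses))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vessel_spec
#' @export
read_vessel_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(v) {
    sten <- v$stenoses %||% list()
    cp <- v$control_points
    if (!is.matrix(cp)) cp <- matrix(unlist(cp), ncol = 3, byrow = TRUE)
    vessel_spec(v$name, cp, unlist(v$radius_profile), v$peak_speed,
                stenoses = sten)
  })
}
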