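#' Voxel grid: a 3D lattice with physical geometry
#'
#' The basic container for every image in the package: a 3D array of
#' scalar, complex, or 3-vector values together with its physical voxel
#' spacing and world origin (both in mm). Grids are axis-aligned; the
#' world position of the voxel with 0-based index \eqn{(i,j,k)} is
#' \eqn{origin + (i,j,k) \cdot spacing}. Note that R array subscripts are
#' 1-based, so subscript \code{[i,j,k]} sits at world
#' \code{origin + (c(i,j,k)-1)*spacing}.
#'
#' @param data 3D array (scalar or complex), or a 4D array whose fourth
#'   dimension has extent 3 (a vector field).
#' @param spacing length-3 positive voxel spacing in mm. Default
#'   \code{c(1.2, 1.2, 1.2)}, the isotropic acquisition resolution.
#' @param origin length-3 world coordinate (mm) of the 0-index voxel.
#' @return An object of class \code{voxel_grid} with fields \code{data},
#'   \code{spacing}, \code{origin}, \code{shape}.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 8)))
#' world_coords(g, rbind(c(0, 0, 0), c(1, 2, 3)))
#' @export
voxel_grid <- function(data, spacing = c(1.2, 1.2, 1.2), origin = c(0, 0, 0)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D array or a 4D array with last extent 3")
  if (length(dim(data)) == 4L && dim(data)[4] != 3L)
    stop("vector-valued grids must have a fourth dimension of extent 3")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be 3 positive lengths (mm)")
  if (length(origin) != 3L) stop("`origin` must be a length-3 world coordinate (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 shape = dim(data)[1:3]),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  kind <- if (length(dim(x$data)) == 4L) "3-vector" else storage.mode(x$data)
  cat(sprintf("<voxel_grid> %s, shape %s, spacing (%s) mm, origin (%s) mm\n",
              kind, paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' World coordinates of 0-based voxel indices
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param index0 n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
world_coords <- function(grid, index0) {
  index0 <- rbind(index0)
  sweep(sweep(index0, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' 0-based voxel indices of world coordinates (inverse of [world_coords()])
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @param world n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
index_coords <- function(grid, world) {
  world <- rbind(world)
  sweep(sweep(world, 2, grid$origin, `-`), 2, grid$spacing, `/`)
}

#' Grid of world coordinates for every voxel
#'
#' @param grid a \code{\link{voxel_grid}}.
#' @return list of three 3D arrays (x, y, z world coordinate per voxel, mm).
#' @keywords internal
#' @noRd
world_mesh <- function(grid) {
  d <- grid$shape
  wx <- grid$origin[1] + (0:(d[1] - 1)) * grid$spacing[1]
  wy <- grid$origin[2] + (0:(d[2] - 1)) * grid$spacing[2]
  wz <- grid$origin[3] + (0:(d[3] - 1)) * grid$spacing[3]
  list(x = array(wx, d),
       y = array(rep(wy, each = d[1]), d),
       z = array(rep(wz, each = d[1] * d[2]), d))
}

# A grid with the same geometry but new data.
#' @noRd
grid_like <- function(grid, data) voxel_grid(data, grid$spacing, grid$origin)

#' Sample a scalar voxel grid at world coordinates (trilinear)
#'
#' @param grid a scalar \code{\link{voxel_grid}}.
#' @param world n x 3 matrix of world coordinates (mm).
#' @return numeric vector; NA outside the grid.
#' @export
sample_grid <- function(grid, world) {
  idx <- index_coords(grid, world) + 1  # to 1-based subscripts
  interp_trilinear(grid$data, idx[, 1], idx[, 2], idx[, 3])
}
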