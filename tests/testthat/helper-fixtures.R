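# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

tube_phantom <- function() cached("tube", function()
  build_phantom(straight_tube_spec(15), c(48, 48, 48)))

stenosed_phantom <- function() cached("stenosed", function()
  build_phantom(stenosed_tube_spec(10, 0.5, 22.8), c(48, 48, 48)))

curved_phantom <- function() cached("curved", function()
  build_phantom(curved_two_vessel_spec(), c(48, 48, 48)))

tube_path <- function() cached("tube_path", function()
  build_centerline(straight_tube_spec()[[1]]$control_points, 100))

# Construct an encoded study directly from an arbitrary per-voxel velocity
# array (cm/s) by the defining phase model -- the independent route used to
# check the decoder against ground truth.
study_from_field <- function(varr, scheme = encoding_scheme("balanced"),
                             venc = 50, mag = NULL) {
  shape <- dim(varr)[1:3]
  mag <- mag %||% array(1, shape)
  vmat <- matrix(varr, prod(shape), 3)
  vols <- lapply(1:4, function(k) {
    ph <- (pi / venc) * as.vector(vmat %*% scheme$matrix[k, ])
    voxel_grid(array(mag * exp(1i * ph), shape))
  })
  encoded_study(vols, acq_params(venc = venc), scheme)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A chunky tube for coarse 16^3 grids at 3.6 mm spacing (54 mm box).
coarse_tube_spec <- function(peak_speed) {
  c0 <- 8 * 3.6
  list(vessel_spec("tube", rbind(c(c0, c0, 16), c(c0, c0, 27), c(c0, c0, 38)),
                   radius_profile = 5, peak_speed = peak_speed))
}

coarse_phantom <- function(peak_speed)
  build_phantom(coarse_tube_spec(peak_speed), c(16, 16, 16),
                spacing = rep(3.6, 3))
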