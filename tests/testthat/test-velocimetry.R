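test_that("decoding inverts the worked balanced-scheme example", {
  varr <- array(0, c(4, 4, 4, 3)); varr[, , , 1] <- 25
  st <- study_from_field(varr, encoding_scheme("balanced"), venc = 50)
  dec <- decode_velocity(st)
  expect_equal(dec$v$data[2, 2, 2, ], c(25, 0, 0), tolerance = 1e-9)
  # zero phases decode to zero velocity
  st0 <- study_from_field(array(0, c(4, 4, 4, 3)))
  expect_equal(max(abs(decode_velocity(st0)$v$data)), 0, tolerance = 1e-12)
})

test_that("background fit recovers an injected quadratic exactly", {
  ph <- build_phantom(straight_tube_spec(15), c(48, 48, 48),
                      myocardium = list(center = c(27.6, 27.6, 27.6), radius = 16))
  eddy <- function(W) cbind(2e-3 * W[, 1]^2, 0 * W[, 1], 1e-3 * W[, 3]^2)
  st <- encode_study(ph, noise_snr = Inf, eddy_velocity = eddy)
  f <- decode_velocity(st)
  static <- voxel_grid(ph$magnitude$data > 0.15 & ph$magnitude$data < 0.7,
                       ph$magnitude$spacing, ph$magnitude$origin)
  fb <- fit_background(f, static, lumen_mask = ph$lumen_mask)
  expect_equal(fb$model$coeffs[5, 1], 2e-3, tolerance = 1e-6)
  expect_equal(fb$model$coeffs[7, 3], 1e-3, tolerance = 1e-6)
  expect_lt(fb$model$static_residual_rms, 1e-9)
  # corrected field equals truth inside the lumen
  lum <- rep(ph$lumen_mask$data, 3)
  expect_lt(max(abs((fb$corrected$v$data - ph$truth$v$data)[lum])), 1e-9)
  # zero-velocity static region: zero coefficients, field unchanged
  st2 <- encode_study(ph, noise_snr = Inf)
  fb2 <- fit_background(decode_velocity(st2), static)
  expect_lt(max(abs(fb2$model$coeffs)), 1e-12)
  expect_error(fit_background(f, voxel_grid(array(FALSE, c(48, 48, 48)))),
               "static voxels")
})

test_that("displacement correction relocates by v * dt and is conservative", {
  shp <- c(16, 16, 16)
  v <- array(0, c(shp, 3)); m <- array(0.05, shp)
  m[5:12, 5:12, 5:12] <- 1
  v[, , , 2][m == 1] <- 20
  fld <- velocity_field(voxel_grid(v), voxel_grid(m))
  # 20 cm/s * 6 ms = 1.2 mm = exactly one voxel at 1.2 mm spacing
  fc <- displacement_correct(fld, acq_params(axis_time_offsets = c(0, 6, 0)))
  expect_true(all(fc$v$data[8, 4:11, 8, 2] == 20))
  expect_true(all(fc$v$data[8, 1:3, 8, 2] == 0))
  reloc <- attr(fc, "relocation")
  expect_equal(unname(reloc["carried_weight_in"]), unname(reloc["carried_weight_out"]))
  # zero velocity and zero offsets are both the identity
  f0 <- velocity_field(voxel_grid(array(0, c(shp, 3))), voxel_grid(m))
  expect_equal(displacement_correct(f0, acq_params())$v$data, f0$v$data)
  fi <- displacement_correct(fld, acq_params(axis_time_offsets = c(0, 0, 0)))
  expect_identical(fi$v$data, fld$v$data)
})

test_that("correcting a displaced acquisition restores the lumen position", {
  # emulate the artifact by displacing with negated time offsets, then correct
  shp <- c(16, 16, 16)
  v <- array(0, c(shp, 3)); m <- array(0.05, shp)
  m[5:12, 5:12, 5:12] <- 1
  v[, , , 2][m == 1] <- 18       # 18 cm/s * 6 ms = 1.08 mm, a sub-voxel shift
  fld <- velocity_field(voxel_grid(v), voxel_grid(m))
  displaced <- displacement_correct(fld, acq_params(axis_time_offsets = c(0, -6, 0)))
  corrected <- displacement_correct(displaced, acq_params(axis_time_offsets = c(0, 6, 0)))
  centroid_y <- function(f) {
    s <- f$speed$data
    sum(s * slice.index(s, 2)) / sum(s)
  }
  truth_c <- centroid_y(fld)
  expect_lt(abs(centroid_y(corrected) - truth_c),
            abs(centroid_y(displaced) - truth_c))
})
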