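test_that("parabolic profile: no-slip boundary, centerline speed, flux", {
  # fine grid so numeric integration resolves the profile
  vs <- list(vessel_spec("t", rbind(c(12, 12, 4), c(12, 12, 12), c(12, 12, 20)),
                         radius_profile = 2, peak_speed = 15))
  ph <- build_phantom(vs, c(40, 40, 40), spacing = c(0.6, 0.6, 0.6))
  vz <- ph$truth$v$data[, , 20, 3]
  x <- (0:39) * 0.6
  rho <- sqrt(outer((x - 12)^2, (x - 12)^2, `+`))
  expect_equal(max(vz), 15, tolerance = 1e-6)          # centerline value
  expect_true(all(vz[rho > 2] == 0))                   # no slip outside R
  expect_equal(vz[rho <= 1.9], 15 * (1 - (rho[rho <= 1.9] / 2)^2),
               tolerance = 1e-6)
  flux <- sum(vz) * 0.6^2
  expect_equal(flux, 15 * pi * 4 / 2, tolerance = 0.03)  # v_c pi R^2 / 2
})

test_that("stenosis narrows the lumen and scales speed by continuity", {
  ph <- stenosed_phantom()    # 50% area reduction, v_c = 10
  tc <- sample_truth_curve(ph, "tube", n_slices = 100)
  expect_length(tc$vmax, 100L)
  expect_equal(max(tc$vmax), 10 / (1 - 0.5), tolerance = 0.02)   # 2 v_c at slice sampling
  expect_equal(tc$arc[which.max(tc$vmax)], 22.8, tolerance = diff(tc$arc[1:2]))
  # away from the stenosis the curve is the base speed
  expect_equal(tc$vmax[tc$arc < 10], rep(10, sum(tc$arc < 10)), tolerance = 1e-9)
})

test_that("flux is conserved through stenosed and straight cross-sections", {
  # fine grid so the narrowed lumen is resolved by the numeric integration
  vs <- list(vessel_spec("t", rbind(c(12, 12, 4), c(12, 12, 12), c(12, 12, 20)),
                         radius_profile = 2, peak_speed = 10,
                         stenoses = list(list(at = 8, length = 6, severity = 0.5))))
  ph <- build_phantom(vs, c(40, 40, 40), spacing = rep(0.6, 3))
  vz <- ph$truth$v$data[, , , 3]
  flux_at <- function(k) sum(vz[, , k]) * 0.6^2
  f_straight <- flux_at(8)    # z = 4.2 mm, upstream
  f_sten <- flux_at(21)       # z = 12 mm = stenosis center (arc 8)
  expect_equal(f_sten / f_straight, 1, tolerance = 0.05)
})

test_that("velocity is parallel to the centerline tangent", {
  ph <- curved_phantom()
  lum <- ph$lumen_mask$data
  v <- matrix(ph$truth$v$data, ncol = 3)[lum, ]
  sp <- sqrt(rowSums(v^2))
  # compare against tangents of the owning vessel via nearest point
  vs <- ph$vessels[[1]]
  cl <- build_centerline(vs$control_points, 200)
  # only voxels clearly owned by vessel 1 (far from vessel 2)
  W <- which(lum, arr.ind = TRUE)
  wpts <- world_coords(ph$magnitude, W - 1)
  d1 <- apply(wpts, 1, function(p) min(sqrt(rowSums((cl$points - rep(p, each = nrow(cl$points)))^2))))
  own <- d1 < 1.8 & sp > 1
  ok <- vapply(which(own), function(i) {
    j <- which.min(rowSums((cl$points - matrix(wpts[i, ], nrow(cl$points), 3, byrow = TRUE))^2))
    abs(sum(v[i, ] * cl$tangents[j, ])) >= 0.99 * sp[i]
  }, logical(1))
  expect_gt(mean(ok), 0.98)
})

test_that("geometry guards and vessel spec JSON round trip", {
  bad <- vessel_spec("out", rbind(c(0, 0, 0), c(100, 100, 100)), 2, 10)
  expect_error(build_phantom(list(bad), c(16, 16, 16)), "exits the grid")
  expect_error(sample_truth_curve(tube_phantom(), "nope"), "unknown vessel")
  expect_error(vessel_spec("s", rbind(c(0, 0, 0), c(1, 1, 1)), 2, 10,
                           stenoses = list(list(at = 1, length = 2, severity = 1))),
               "severity")
  f <- withr::local_tempfile(fileext = ".json")
  write_vessel_spec(stenosed_tube_spec(), f)
  back <- read_vessel_spec(f)
  expect_equal(back[[1]]$control_points, stenosed_tube_spec()[[1]]$control_points)
  expect_equal(back[[1]]$stenoses[[1]]$severity, 0.5)
})
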