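test_that("centerlines: straight lines, circles, uniform arc spacing", {
  cl <- build_centerline(rbind(c(0, 0, 0), c(10, 0, 0)), 100)
  expect_equal(cl$arc[100], 10, tolerance = 0.01)
  expect_true(all(abs(cl$tangents %*% c(1, 0, 0) - 1) < 1e-9))
  # markers on a circle: tangents perpendicular to radius vectors within 1 degree
  th <- seq(0, pi / 2, length.out = 14)
  mk <- cbind(20 * cos(th), 20 * sin(th), 0)
  cc <- build_centerline(mk, 50)
  radial <- cc$points / sqrt(rowSums(cc$points^2))
  ang <- abs(90 - acos(pmin(pmax(rowSums(radial * cc$tangents), -1), 1)) * 180 / pi)
  expect_lt(max(ang[2:49]), 1)
  # equal arc spacing within 1%
  sp <- diff(cc$arc)
  expect_lt((max(sp) - min(sp)) / mean(sp), 0.01)
  expect_error(build_centerline(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicate")
})

test_that("segmentation follows the tube and the magnitude threshold", {
  ph <- tube_phantom()
  path <- tube_path()
  mk <- segment_vessel(ph$magnitude, path, radius_mm = 2.5, threshold_frac = 0.5)
  dice <- 2 * sum(mk$mask$data & ph$lumen_mask$data) /
    (sum(mk$mask$data) + sum(ph$lumen_mask$data))
  expect_gte(dice, 0.8)
  # threshold 0: the full fixed-radius tube, a superset of the lumen
  tube_full <- segment_vessel(ph$magnitude, path, 2.5, 0)
  expect_true(all(mk$mask$data <= tube_full$mask$data))
  expect_gt(sum(tube_full$mask$data), sum(mk$mask$data))
  expect_error(segment_vessel(ph$magnitude, path, 2.5, 1.1), "empty")
})

test_that("curve extraction recovers uniform, parabolic and stenosed profiles", {
  ph <- tube_phantom()
  path <- tube_path()
  mk <- segment_vessel(ph$magnitude, path, 2.5, 0.5)
  # uniform speed inside the mask -> vmax = 10 everywhere sampled
  u <- array(0, c(48, 48, 48, 3)); u[, , , 3][mk$mask$data] <- 10
  uf <- velocity_field(voxel_grid(u), ph$magnitude)
  cu <- extract_curve(uf, path, mk)
  expect_equal(stats::na.omit(unique(round(cu$vmax, 9))), 10, ignore_attr = TRUE)
  # parabolic truth field: interior slices within 10% of v_c
  ct <- extract_curve(ph$truth, path, mk)
  interior <- ct$arc > 5 & ct$arc < max(ct$arc) - 5
  expect_lt(max(abs(ct$vmax[interior] - 15) / 15, na.rm = TRUE), 0.10)
  # stenosed phantom: argmax within 2 mm of the stenosis center
  ps <- stenosed_phantom()
  cs <- extract_curve(ps$truth, path, segment_vessel(ps$magnitude, path, 2.5, 0.5))
  expect_lt(abs(cs$arc[which.max(cs$vmax)] - 22.8), 2)
})

test_that("extracted curves agree with the analytic truth curve", {
  ph <- stenosed_phantom()
  path <- tube_path()
  cs <- extract_curve(ph$truth, path, segment_vessel(ph$magnitude, path, 2.5, 0.5))
  tc <- sample_truth_curve(ph, "tube", 100)
  interior <- cs$arc > 5 & cs$arc < max(cs$arc) - 5 & !is.na(cs$vmax)
  rel <- abs(cs$vmax[interior] - tc$vmax[interior]) / tc$vmax[interior]
  expect_lt(stats::median(rel), 0.15)
})

test_that("curves are invariant to a rigid translation of study and markers", {
  ph <- tube_phantom()
  path <- tube_path()
  c1 <- extract_curve(ph$truth, path, segment_vessel(ph$magnitude, path, 2.5, 0.5))
  shift <- c(2.4, -2.4, -1.2)
  ph2 <- build_phantom(list(vessel_spec("tube",
    sweep(straight_tube_spec()[[1]]$control_points, 2, shift, `+`),
    2, 15)), c(48, 48, 48), origin = c(0, 0, 0))
  path2 <- build_centerline(sweep(path$markers, 2, shift, `+`), 100)
  c2 <- extract_curve(ph2$truth, path2, segment_vessel(ph2$magnitude, path2, 2.5, 0.5))
  ok <- !is.na(c1$vmax) & !is.na(c2$vmax)
  expect_lt(max(abs(c1$vmax[ok] - c2$vmax[ok]) / pmax(c1$vmax[ok], 1)), 0.02)
})

test_that("ostium pruning follows the fixed-window rule", {
  # hand-evaluable case: arc step 0.5 mm, leading overshoot 30,28,20,12,11
  arc <- seq(0, by = 0.5, length.out = 100)
  v <- c(30, 28, 20, 12, 11, rep(10, 95))
  w <- which(arc >= 10 & arc <= 25)
  v[w[5]] <- 11                       # one 11 inside the reference window
  pr <- prune_ostium(velocity_curve(arc, v))
  # independent evaluation: vmean = 311/31, sigma = sd of the window,
  # threshold ~ 10.212, so 11 at index 4 is non-compliant and n = 5
  expect_equal(pr$vmean_ref, mean(v[w]))
  expect_equal(pr$sigma_ref, stats::sd(v[w]))
  expect_identical(pr$prune_n, 5L)
  expect_equal(pr$arc[1], 0)
  expect_equal(pr$vmax[1], 10)        # first kept slice was at old arc 2.5 mm
  expect_length(pr$vmax, 95L)
  # post-prune property: first three slices comply whenever pruning happened
  expect_true(all(pr$vmax[1:3] <= pr$vmean_ref + pr$sigma_ref))
  # already-compliant curve is untouched
  flat <- velocity_curve(arc, rep(10, 100))
  expect_identical(prune_ostium(flat)$prune_n, 0L)
  # nothing compliant within max_n: unchanged plus a warning
  high <- velocity_curve(arc, c(rep(50, 12), rep(10, 88)))
  expect_warning(ph2 <- prune_ostium(high, max_n = 8), "unchanged")
  expect_identical(ph2$prune_n, 0L)
  expect_error(prune_ostium(velocity_curve(c(0, 1, 2), c(1, 1, 1))), "window")
})

test_that("proximal summaries: constants, ramps, truth-curve identity", {
  arc <- seq(0, 25, length.out = 51)
  expect_equal(summary(velocity_curve(arc, rep(10, 51))),
               c(peak = 10, average = 10))
  ramp <- summary(velocity_curve(arc, seq(0, 20, length.out = 51)))
  expect_equal(ramp[["peak"]], 20)
  expect_equal(ramp[["average"]], 10, tolerance = 1e-9)
  tc <- sample_truth_curve(stenosed_phantom(), "tube", 100)
  s <- summary(tc)
  sel <- tc$arc <= 25
  expect_equal(s[["peak"]], max(tc$vmax[sel]))
  expect_equal(s[["average"]], mean(tc$vmax[sel]))
})
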