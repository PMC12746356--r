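test_that("Bland-Altman arithmetic: identities, hand case, antisymmetry", {
  ba0 <- bland_altman(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  # differences 1, 2, 3 -> bias 2, sd 1, LOA 2 -/+ 1.96
  ba <- bland_altman(c(11, 12, 13), c(10, 10, 10))
  expect_equal(ba$bias, 2); expect_equal(ba$sd, 1)
  expect_equal(unname(ba$loa), c(0.04, 3.96))
  expect_equal(ba$mean_level, mean(c(10.5, 11, 11.5)))
  # antisymmetry and LOA width
  set.seed(51)
  a <- runif(20, 5, 15); b <- runif(20, 5, 15)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(f$bias, -r$bias)
  expect_equal(f$sd, r$sd)
  expect_equal(diff(f$loa), 2 * 1.96 * f$sd, ignore_attr = TRUE)
  # missing slices are dropped pairwise
  a[3] <- NA
  expect_equal(bland_altman(a, b)$n, 19L)
  expect_error(bland_altman(c(1, NA, NA), c(1, 2, 3)), "3 paired")
})

test_that("published limits of agreement reproduce from bias and SD", {
  ref <- scan_rescan_reference()
  cons <- ref[ref$self_consistent, ]
  expect_gte(nrow(cons), 3L)
  for (i in seq_len(nrow(cons))) {
    expect_equal(round(cons$bias[i] - 1.96 * cons$sd[i], 2), cons$loa_lower[i])
    expect_equal(round(cons$bias[i] + 1.96 * cons$sd[i], 2), cons$loa_upper[i])
  }
  # the worked row: bias 0.37, sd 1.55 -> LOA (-2.67, 3.41)
  v4 <- ref[ref$subject == "volunteer4" & ref$vessel == "RCA", ]
  expect_equal(round(v4$bias + c(-1.96, 1.96) * v4$sd, 2), c(-2.67, 3.41))
})

test_that("paired t-test matches the textbook computation and guards degeneracy", {
  set.seed(52)
  a <- rnorm(15, 10, 2); b <- a + rnorm(15, 0.5, 1)
  res <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(d) - 1)
  expect_equal(unname(res["t"]), t_oracle, tolerance = 1e-12)
  expect_lt(abs(res["p"] - p_oracle), 1e-9)
  # a large offset at low noise is always significant
  res2 <- paired_ttest(a + 5, a + rnorm(15, 0, 0.01))
  expect_lt(res2["p"], 0.05)
  expect_error(paired_ttest(a, a), "degenerate")
})

test_that("FFR arc lengths are cumulative Euclidean distances", {
  expect_equal(align_ffr_arc(rbind(c(1, 2, 3))), 0)
  expect_equal(align_ffr_arc(rbind(c(0, 0, 0), c(3, 4, 0))), c(0, 5))
  set.seed(53)
  pts <- matrix(rnorm(30), 10, 3)
  brute <- c(0, cumsum(vapply(2:10, function(i)
    sqrt(sum((pts[i, ] - pts[i - 1, ])^2)), numeric(1))))
  expect_lt(max(abs(align_ffr_arc(pts) - brute)), 1e-12)
  # translation and rotation invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(align_ffr_arc(pts %*% R + 5), align_ffr_arc(pts), tolerance = 1e-12)
  tr <- ffr_trace(pts, seq(1, 0.6, length.out = 10))
  expect_equal(tr$arc, brute)
  expect_error(ffr_trace(pts, rep(1.2, 10)))
})

test_that("MIP takes in-mask maxima and honors visibility toggles", {
  shp <- c(10, 12, 14)
  v <- array(0, c(shp, 3))
  v[, , , 1][3, 4, 5] <- 7
  v[, , , 1][8, 9, 10] <- 9
  fld <- velocity_field(voxel_grid(v), voxel_grid(array(1, shp)))
  m1 <- voxel_grid(array(FALSE, shp)); m1$data[3, 4, 5] <- TRUE
  m2 <- voxel_grid(array(FALSE, shp)); m2$data[8, 9, 10] <- TRUE
  mip <- render_mip(fld, list(m1, m2), axis = 3)
  expect_equal(dim(mip), c(10, 12))
  expect_equal(mip[3, 4], 7); expect_equal(mip[8, 9], 9)
  expect_equal(max(mip), max(fld$speed$data[m1$data | m2$data]))
  # hiding the second vessel reproduces the single-vessel MIP
  mip1 <- render_mip(fld, list(m1, m2), axis = 3, visible = c(TRUE, FALSE))
  expect_equal(mip1, render_mip(fld, list(m1), axis = 3))
  expect_warning(blank <- render_mip(fld, list(voxel_grid(array(FALSE, shp)))),
                 "empty")
  expect_equal(max(blank), 0)
})

test_that("scan-rescan report layout and identical-pair degeneracy", {
  arc <- seq(0, 30, length.out = 40)
  c1 <- velocity_curve(arc, 10 + sin(arc))
  c2 <- velocity_curve(arc, 10 + sin(arc) + 0.3)
  rep1 <- scan_rescan_report(list(LCA = list(c1, c1), RCA = list(c1, c2)))
  expect_equal(nrow(rep1), 3L)   # pairs + summary row
  expect_equal(rep1$avg_dev[1], 0)
  expect_equal(rep1$bias[1], 0)
  expect_equal(rep1$bias[2], -0.3, tolerance = 1e-9)  # first minus second scan
  expect_equal(rep1$avg_dev[2], -0.3, tolerance = 1e-9)
})

test_that("simulated rescans agree within a cohort mean deviation of 1 cm/s", {
  # ten replicate scan-rescan pairs of the same phantom, fresh noise each
  ph <- tube_phantom()
  path <- tube_path()
  one_scan <- function(seed) {
    st <- encode_study(ph, noise_snr = 30, seed = seed)
    f <- decode_velocity(st)
    mk <- segment_vessel(f$magnitude, path, 2.5, 0.5)
    summary(prune_ostium(extract_curve(f, path, mk)))[["average"]]
  }
  devs <- vapply(1:10, function(k) one_scan(2 * k) - one_scan(2 * k + 1),
                 numeric(1))
  expect_lt(abs(mean(devs)), 1)
})
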