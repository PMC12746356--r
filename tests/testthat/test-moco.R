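test_that("edge filter: constant image has no edges; output is deterministic", {
  flat <- voxel_grid(array(1, c(12, 12, 12)))
  e <- canny3d(flat)
  expect_equal(sum(e$edges$data), 0L)
  ph <- tube_phantom()
  e1 <- canny3d(ph$magnitude); e2 <- canny3d(ph$magnitude)
  expect_identical(e1$edges$data, e2$edges$data)
  expect_error(canny3d(flat, low = 0.2, high = 0.1))
})

test_that("sphere edges lie on the analytic shell", {
  d <- c(24, 24, 24)
  ctr <- (d + 1) / 2
  x <- array(0, d)
  idx <- which(x == 0, arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  x[r <= 8] <- 1
  e <- canny3d(voxel_grid(x), sigma = 1, low = 0.1, high = 0.2)
  ei <- which(e$edges$data, arr.ind = TRUE)
  expect_gt(nrow(ei), 100)
  re <- sqrt(rowSums(sweep(ei, 2, ctr)^2))
  expect_lt(max(abs(re - 8)), 1.5)
})

test_that("registration: identity, integer shifts, sign convention", {
  ph <- curved_phantom()
  e <- canny3d(ph$magnitude)
  id <- estimate_translation(e, e)
  expect_equal(unname(id$t), c(0, 0, 0))
  # moving = reference shifted by (+2.4, -1.2, +3.6) mm -> t is its negative
  st <- encode_study(ph, translations = rbind(c(0, 0, 0), c(2.4, -1.2, 3.6),
                                              matrix(0, 2, 3)),
                     noise_snr = Inf)
  mags <- lapply(st$volumes[1:2], function(g) voxel_grid(Mod(g$data), g$spacing, g$origin))
  sh <- estimate_translation(canny3d(mags[[2]]), canny3d(mags[[1]]), search_mm = 6)
  expect_equal(unname(sh$t), c(-2.4, 1.2, -3.6), tolerance = 1e-8)
  flat48 <- canny3d(voxel_grid(array(1, c(48, 48, 48))))
  expect_error(estimate_translation(flat48, e), "nonempty")
})

test_that("sub-voxel shifts are recovered within 0.3 voxel at SNR 30", {
  ph <- curved_phantom()
  st <- encode_study(ph, translations = rbind(c(0, 0, 0), c(0.48, 0, 0),
                                              matrix(0, 2, 3)),
                     noise_snr = 30, seed = 13)
  mags <- lapply(st$volumes[1:2], function(g) voxel_grid(Mod(g$data), g$spacing, g$origin))
  sh <- estimate_translation(canny3d(mags[[2]]), canny3d(mags[[1]]), search_mm = 6)
  expect_lt(max(abs(sh$t - c(-0.48, 0, 0)) / 1.2), 0.3)
})

test_that("registration is inverse-consistent on noise-free pairs", {
  ph <- curved_phantom()
  st <- encode_study(ph, translations = rbind(c(0, 0, 0), c(1.8, -0.9, 2.1),
                                              matrix(0, 2, 3)),
                     noise_snr = Inf)
  mags <- lapply(st$volumes[1:2], function(g) voxel_grid(Mod(g$data), g$spacing, g$origin))
  eA <- canny3d(mags[[1]]); eB <- canny3d(mags[[2]])
  ab <- estimate_translation(eB, eA); ba <- estimate_translation(eA, eB)
  expect_lt(max(abs(ab$t + ba$t) / 1.2), 0.1)
})

test_that("apply_correction aligns volumes, preserves the reference, sharpens", {
  ph <- curved_phantom()
  set.seed(41)
  tr <- rbind(0, matrix(runif(9, -3, 3), 3, 3))
  st <- encode_study(ph, translations = tr, noise_snr = 30, seed = 17)
  sh <- estimate_study_shifts(st, search_mm = 6)
  cor <- apply_correction(st, sh)
  expect_identical(cor$volumes[[1]]$data, st$volumes[[1]]$data)
  # residual misalignment after correction <= 0.3 voxel
  resid <- estimate_study_shifts(cor, search_mm = 6)
  for (k in 1:3) expect_lt(max(abs(resid[[k]]$t) / 1.2), 0.3)
  # corrected average is at least as sharp as the uncorrected one
  sharp <- function(a) {
    d <- dim(a)
    mean(abs(a[-1, , ] - a[-d[1], , ]))
  }
  avg_unc <- Reduce(`+`, lapply(st$volumes, function(g) Mod(g$data))) / 4
  expect_gte(sharp(cor$avg_magnitude$data), sharp(avg_unc))
  # zero shifts leave the study unchanged
  zero <- lapply(1:3, function(k) structure(list(t = c(0, 0, 0), score = 1,
                                                 search_mm = 6), class = "rigid_shift"))
  same <- apply_correction(st, zero)
  for (k in 1:4) expect_equal(same$volumes[[k]]$data, st$volumes[[k]]$data)
})
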