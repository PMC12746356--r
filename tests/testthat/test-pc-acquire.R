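test_that("null flow, no noise, no motion gives four identical zero-phase volumes", {
  ph <- coarse_phantom(0)
  st <- encode_study(ph, noise_snr = Inf)
  for (k in 2:4)
    expect_equal(st$volumes[[k]]$data, st$volumes[[1]]$data, tolerance = 1e-12)
  expect_lt(max(abs(Arg(st$volumes[[1]]$data))), 1e-12)
})

test_that("balanced scheme phases match the encoding matrix arithmetic", {
  # uniform v = (25, 0, 0) cm/s at VENC 50 -> phases (-pi/4, pi/4, pi/4, -pi/4)
  varr <- array(0, c(4, 4, 4, 3)); varr[, , , 1] <- 25
  st <- study_from_field(varr, encoding_scheme("balanced"), venc = 50)
  ph <- vapply(1:4, function(k) Arg(st$volumes[[k]]$data[2, 2, 2]), numeric(1))
  expect_equal(ph, c(-pi / 4, pi / 4, pi / 4, -pi / 4), tolerance = 1e-12)
})

test_that("noise-free encode then decode is the identity for both schemes", {
  set.seed(21)
  for (nm in c("balanced", "referenced")) {
    sc <- encoding_scheme(nm)
    v <- array(runif(6 * 6 * 6 * 3, -1, 1), c(6, 6, 6, 3))
    n <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
    scl <- 0.9 * 50 / max(n)
    v <- v * scl                       # |v| <= 0.9 VENC
    st <- study_from_field(v, sc)
    dec <- decode_velocity(st)
    expect_lt(max(abs(dec$v$data - v)), 1e-9)
  }
})

test_that("sampling masks are calibrated, deterministic, and guarded", {
  m <- make_mask(c(192, 192), accel = 14, calib_size = 24, seed = 7)
  expect_gte(m$fraction, 0.06); expect_lte(m$fraction, 0.09)
  m2 <- make_mask(c(192, 192), accel = 14, calib_size = 24, seed = 7)
  expect_identical(m$mask, m2$mask)
  m3 <- make_mask(c(192, 192), accel = 14, calib_size = 24, seed = 8)
  expect_false(identical(m$mask, m3$mask))
  expect_true(all(make_mask(c(32, 32), accel = 1, calib_size = 8)$mask))
  expect_error(make_mask(c(32, 32), accel = 4, calib_size = 32), "calib_size")
})

test_that("speeds beyond VENC set the wrap flag and alias under unit moments", {
  ph <- coarse_phantom(60)
  expect_true(ph$venc_exceeded)
  # referenced scheme: phase pi*v/VENC wraps for |v| > VENC, so 60 cm/s
  # aliases to -40 cm/s and the study is flagged
  st <- encode_study(ph, scheme = encoding_scheme("referenced"), noise_snr = Inf)
  dec <- decode_velocity(st)
  expect_true(dec$wrap_flag)
  ctr <- which(ph$truth$speed$data == max(ph$truth$speed$data))[1]
  expect_equal(dec$v$data[, , , 3][ctr], -40, tolerance = 1e-6)
})

test_that("inter-scan translation is applied exactly for integer shifts", {
  ph <- coarse_phantom(12)
  tr <- rbind(c(0, 0, 0), c(3.6, 0, -7.2), c(0, 0, 0), c(0, 0, 0))
  st <- encode_study(ph, translations = tr, noise_snr = Inf)
  a <- st$volumes[[1]]$data; b <- st$volumes[[2]]$data
  expect_lt(max(Mod(b[5, , 3] - a[4, , 5])), 1e-9)
})
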