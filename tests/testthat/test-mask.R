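test_that("FWHM/sigma conversion is exact, linear, and guarded", {
  expect_equal(fwhm_to_sigma(4), 1.69864, tolerance = 1e-5)
  expect_equal(fwhm_to_sigma(2.35482), 1, tolerance = 1e-5)
  expect_equal(fwhm_to_sigma(8), 2 * fwhm_to_sigma(4))
  expect_error(fwhm_to_sigma(0), "positive")
  expect_error(fwhm_to_sigma(-1), "positive")
})

test_that("2-D blur conserves in-slice mass and reproduces the impulse kernel", {
  m <- array(0, dim = c(19, 19, 3))
  m[8:11, 8:11, 2] <- 1                    # interior block, kernel stays inside
  b <- blur_parcel_2d(m, fwhm_mm = 4, voxel_size_mm = 1.2)
  expect_equal(sum(b[, , 2]), sum(m[, , 2]), tolerance = 1e-6)
  expect_equal(sum(b[, , 1]), 0)           # slice-wise: no leakage across slices
  expect_true(all(b >= 0 & b <= 1))

  # impulse response = outer product of the discrete 1-D kernels
  imp <- array(0, dim = c(15, 15, 1)); imp[8, 8, 1] <- 1
  bi <- blur_parcel_2d(imp, fwhm_mm = 4, voxel_size_mm = 1.2)
  sig <- fwhm_to_sigma(4) / 1.2
  r <- ceiling(4 * sig)
  k <- dnorm(seq(-r, r), sd = sig); k <- k / sum(k)
  expect_equal(bi[(8 - r):(8 + r), (8 - r):(8 + r), 1], outer(k, k),
               tolerance = 1e-12)

  # vanishing FWHM: identity
  b0 <- blur_parcel_2d(m, fwhm_mm = 1e-8, voxel_size_mm = 1.2)
  expect_equal(b0, m, tolerance = 1e-12)

  expect_warning(blur_parcel_2d(array(0, dim = c(5, 5, 2))), "empty parcel")
})

test_that("blur matches the direct convolution oracle to 1e-10", {
  set.seed(21)
  m <- array(rbinom(16^3, 1, 0.2), dim = c(16, 16, 16))
  for (fwhm in c(2, 4)) {
    fast <- blur_parcel_2d(m, fwhm_mm = fwhm, voxel_size_mm = 1.2)
    slow <- blur2d_direct(m, fwhm_mm = fwhm, voxel_size_mm = 1.2)
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
})

test_that("blur is shift-equivariant away from boundaries", {
  m <- array(0, dim = c(20, 20, 2)); m[8:10, 8:10, 1] <- 1
  shifted <- array(0, dim = c(20, 20, 2)); shifted[10:12, 9:11, 1] <- 1
  b <- blur_parcel_2d(m, 4, 1.2)
  bs <- blur_parcel_2d(shifted, 4, 1.2)
  # compare on the common interior window
  expect_equal(bs[5:16, 5:16, 1], b[3:14, 4:15, 1], tolerance = 1e-12)
})

test_that("increasing FWHM never shrinks the adjacent-WM support", {
  ph <- simulate_phantom(phantom_spec(n_regions = 2))
  parcel <- ph$labels == 2L
  sup <- lapply(c(2, 4, 6), function(f) {
    w <- adjacent_wm_mask(blur_parcel_2d(parcel, f, 1.2), ph$labels,
                          ph$label_table)
    which(w > 1e-12)
  })
  expect_true(all(sup[[1]] %in% sup[[2]]))
  expect_true(all(sup[[2]] %in% sup[[3]]))
})

test_that("adjacent-WM masks live only on white matter within kernel reach", {
  ph <- simulate_phantom(phantom_spec(n_regions = 2))
  parcel <- ph$labels == 2L
  b <- blur_parcel_2d(parcel, 4, 1.2)
  w <- adjacent_wm_mask(b, ph$labels, ph$label_table)
  expect_true(all(w[ph$labels != 1L] == 0))        # zero off WM (incl. GM, bg)
  expect_gt(max(w), 1e-6)
  # support is inside the kernel-reach dilation of the parcel
  r <- ceiling(4 * fwhm_to_sigma(4) / 1.2)
  pos <- which(w > 0, arr.ind = TRUE)
  pv <- which(parcel, arr.ind = TRUE)
  cheb <- apply(pos, 1, function(v)
    min(apply(abs(t(pv) - v), 2, function(d) max(d[1:2]) + 1e9 * (d[3] > 0))))
  expect_true(all(cheb <= r))

  # parcel surrounded by background only: no adjacent WM
  iso <- array(0L, dim = c(10, 10, 3)); iso[5, 5, 2] <- 2L
  lt <- data.frame(label = c(1L, 2L), region = c("wm_core", "p"),
                   hemisphere = c(NA, "left"), tissue_class = c("wm", "gm"))
  bi <- blur_parcel_2d(iso == 2L, 4, 1.2)
  expect_error(adjacent_wm_mask(bi, iso, lt), "no adjacent white matter")
})

test_that("weighted regional means reduce correctly and see only nearby WM", {
  ph <- simulate_phantom(phantom_spec(n_regions = 2))
  w <- array(runif(length(ph$mwf)), dim = dim(ph$mwf))
  v <- ph$mwf
  expect_equal(weighted_mean_map(v, w), sum(w * v) / sum(w))
  expect_equal(weighted_mean_map(v, w * 7.3), weighted_mean_map(v, w))
  u <- array(0, dim = dim(v)); u[ph$labels == 1L] <- 1
  expect_equal(weighted_mean_map(v, u), mean(v[ph$labels == 1L]))
  expect_error(weighted_mean_map(v, u * 0), "zero")

  # two WM pools: 0.10 near the parcel, 0.20 beyond kernel reach -> mean 0.10
  d <- c(24, 10, 5)
  labs <- array(0L, dim = d)
  labs[11:12, 4:7, 2:4] <- 2L          # parcel
  labs[13:16, 4:7, 2:4] <- 1L          # near WM slab
  labs[22:24, 4:7, 2:4] <- 1L          # far WM slab (>= 6 voxels away)
  mwf <- array(0, dim = d)
  mwf[13:16, , ] <- 0.10; mwf[22:24, , ] <- 0.20
  lt <- data.frame(label = 1:2, region = c("wm_core", "p"),
                   hemisphere = c(NA, "left"), tissue_class = c("wm", "gm"))
  b <- blur_parcel_2d(labs == 2L, fwhm_mm = 2, voxel_size_mm = 1.2)
  wmask <- adjacent_wm_mask(b, labs, lt)
  expect_true(all(wmask[22:24, , ] == 0))
  expect_equal(weighted_mean_map(mwf, wmask), 0.10, tolerance = 1e-12)
})

test_that("cortical regional means match hand values and the generator", {
  labs <- array(0L, dim = c(4, 4, 1)); labs[1:2, 1, 1] <- 5L
  m <- array(0.08, dim = dim(labs))
  expect_equal(cortical_regional_mean(m, labs, 5L),
               c(mean = 0.08, sd = 0))
  m[1, 1, 1] <- 0.0; m[2, 1, 1] <- 0.2
  expect_equal(cortical_regional_mean(m, labs, 5L)[["mean"]], 0.1)
  expect_error(cortical_regional_mean(m, labs, 9L), "empty parcel")

  spec <- phantom_spec(n_regions = 3, mwf_gm = c(0.03, 0.06, 0.09))
  ph <- simulate_phantom(spec)
  ex <- extract_regional_measures(ph)
  expect_equal(ex$cortical_mwf, c(0.03, 0.06, 0.09))
  expect_equal(ex$cortical_mwf_sd, rep(0, 3))
  expect_equal(ex$adjacent_mwf, rep(0.12, 3))
  expect_equal(ex$adjacent_t1_ms, rep(900, 3))
})
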