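test_that("sphere phantoms voxelize with the documented geometry", {
  sp <- phantom_spec(c(40, 40, 30),
                     data.frame(cx = 20, cy = 20, cz = 16, radius = 8,
                                intensity = 100))
  ph <- make_phantom(sp)
  expect_equal(dim(ph$data), c(40, 40, 30))
  # frames beyond the sphere extent are exactly empty
  expect_true(all(ph$data[, , 1] == 0))
  expect_equal(frame_rank(ph$data[, , 1]), 0L)
  # central frame is a disk of the sphere's radius
  disk <- ph$data[, , 16]
  expect_equal(disk[20, 20], 100)
  expect_equal(disk[20, 20 + 8], 100)
  expect_equal(disk[20, 20 + 9], 0)
  # two non-overlapping spheres add up
  s2 <- phantom_spec(c(40, 40, 30),
                     data.frame(cx = c(10, 30), cy = c(10, 30),
                                cz = c(10, 20), radius = c(5, 5),
                                intensity = c(50, 80)))
  both <- make_phantom(s2)$data
  one <- make_phantom(phantom_spec(c(40, 40, 30),
    data.frame(cx = 10, cy = 10, cz = 10, radius = 5, intensity = 50)))$data
  two <- make_phantom(phantom_spec(c(40, 40, 30),
    data.frame(cx = 30, cy = 30, cz = 20, radius = 5, intensity = 80)))$data
  expect_identical(both, one + two)
  expect_error(phantom_spec(c(20, 20, 20),
                            data.frame(cx = 2, cy = 10, cz = 10, radius = 5,
                                       intensity = 1)), "outside")
})

test_that("random phantom specs are deterministic in the seed", {
  a <- random_phantom_spec(7, volume_shape = c(32, 32, 24), n_spheres = 3)
  b <- random_phantom_spec(7, volume_shape = c(32, 32, 24), n_spheres = 3)
  expect_identical(a$spheres, b$spheres)
  expect_identical(make_phantom(a)$data, make_phantom(b)$data)
})

test_that("the theoretical PSF is normalized, symmetric and peaked in focus", {
  psf <- make_psf(psf_spec(shape = c(21, 21, 9)))
  expect_equal(sum(psf$data), 1, tolerance = 1e-6)
  # xy inversion symmetry about the centre pixel
  expect_lt(max(abs(psf$data - psf$data[21:1, 21:1, ])), 1e-10)
  peak <- which(psf$data == max(psf$data), arr.ind = TRUE)
  expect_equal(as.vector(peak), c(11, 11, 5))
  # intensity integrated per frame drops away from focus
  prof <- integrated_intensity(psf)
  expect_true(all(prof[5] >= prof))
  expect_error(psf_spec(na = 1.6, refractive_index = 1.515), "NA")
})

test_that("convolution preserves identity kernels, intensity and emptiness", {
  set.seed(5)
  st <- image_stack(array(runif(9 * 9 * 7), c(9, 9, 7)), "z", 1)
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  out <- convolve_stack(st, delta)
  expect_equal(out$data, st$data, tolerance = 1e-10)
  zero <- image_stack(array(0, c(9, 9, 7)) , "z", 1)
  expect_error(convolve_stack(zero, delta), NA)
  expect_true(all(abs(convolve_stack(zero, delta)$data) < 1e-14))
  # interior structure conserves total intensity within 2%
  sp <- phantom_spec(c(40, 40, 30),
                     data.frame(cx = c(15, 27), cy = c(14, 28),
                                cz = c(13, 19), radius = c(6, 5),
                                intensity = c(10, 8)))
  ph <- make_phantom(sp)
  cv <- convolve_stack(ph, make_psf(psf_spec(shape = c(11, 11, 7))))
  expect_lt(abs(sum(cv$data) / sum(ph$data) - 1), 0.02)
  # blurring concentrates spectral energy in the leading singular values
  top5 <- function(s) {
    d <- singular_spectrum(s)$values
    sum(d[1:5]^2) / sum(d^2)
  }
  expect_gt(top5(cv), top5(ph))
  # and raises the rank of formerly-empty frames
  expect_equal(frame_rank(ph$data[, , 1]), 0L)
  expect_gt(frame_rank(cv$data[, , 1]), 0L)
  expect_error(convolve_stack(st, array(1, c(20, 2, 2))), "support")
})

test_that("Poisson corruption follows the photon-count law", {
  lam5 <- image_stack(array(5, c(100, 100, 10)), "time", 1)
  noisy <- add_poisson(lam5, photon_scale = 1, seed = 3)
  n <- length(noisy$data)
  # sample mean of 1e5 draws at intensity 5 is 5 within 3 sigma / sqrt(N)
  expect_lt(abs(mean(noisy$data) - 5), 3 * sqrt(5 / n))
  # variance ~ mean for Poisson
  expect_gt(var(as.vector(noisy$data)) / 5, 0.8)
  expect_lt(var(as.vector(noisy$data)) / 5, 1.2)
  # zero intensity stays exactly zero; same seed reproduces
  z <- image_stack(array(0, c(4, 4, 2)), "time", 1)
  expect_true(all(add_poisson(z, 1, 1)$data == 0))
  expect_identical(add_poisson(lam5, 2, 11)$data,
                   add_poisson(lam5, 2, 11)$data)
  neg <- image_stack(array(1, c(2, 2, 2)), "time", 1)
  neg$data[1] <- -1
  expect_error(add_poisson(neg, 1, 1), "negative")
  # photon_scale sets the SNR: higher scale, lower relative noise
  r1 <- sd(add_poisson(lam5, 1, 5)$data - 5)
  r10 <- sd(add_poisson(lam5, 10, 5)$data - 5)
  expect_gt(r1, 2.5 * r10)
})

test_that("series generators match their closed forms", {
  bl <- make_series(series_spec("bleach", decay_rate = 0.02))
  prof <- integrated_intensity(bl$truth)
  expect_equal(prof[10] / prof[1], exp(-0.18), tolerance = 1e-12)

  po <- make_series(series_spec("polarimetry", theta0 = 100))
  expect_equal(n_frames(po$truth), 36L)
  expect_equal(po$truth$axis_kind, "angle")
  # analytic maxima at theta0 and theta0 + 180
  prof_p <- integrated_intensity(po$truth)
  angles <- frame_coords(po$truth)
  # remove the slight bleach trend before reading off the peaks
  base <- exp(-po$truth$step * 0)  # per-frame decay divides out below
  k <- seq_along(angles)
  detrended <- prof_p / exp(-0.005 * (k - 1))
  pk <- angles[which(diff(sign(diff(detrended))) == -2) + 1]
  expect_true(any(abs(pk - 100) <= 10))
  expect_true(any(abs(pk - 280) <= 10))

  # determinism: identical spec -> bit-identical observation
  s1 <- make_series(series_spec("bleach", seed = 2))
  s2 <- make_series(series_spec("bleach", seed = 2))
  expect_identical(s1$observed$data, s2$observed$data)

  # sidecar round trip
  pre <- withr::local_tempfile()
  write_synthetic(bl$truth, series_spec("bleach"), pre)
  expect_true(file.exists(paste0(pre, ".tif")))
  side <- yaml::read_yaml(paste0(pre, "_spec.yaml"))
  expect_equal(side$kind, "bleach")
  expect_equal(side$decay_rate, 0.02)
})
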