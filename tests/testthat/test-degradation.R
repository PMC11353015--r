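# Disk blur and SNR-parameterized Gaussian noise.

test_that("disk kernel has unit-disk support, exact normalization and symmetry", {
  k <- disk_kernel(1)
  expect_equal(dim(k), c(3L, 3L))
  expect_lt(abs(sum(k) - 1), 1e-12)
  expect_equal(k, t(k), tolerance = 1e-15)                     # transpose
  expect_equal(k, k[3:1, ], tolerance = 1e-15)                 # vertical flip
  expect_equal(k, k[, 3:1], tolerance = 1e-15)                 # horizontal flip
  expect_equal(k, t(k[3:1, ]), tolerance = 1e-15)              # 90 deg rotation
  # center pixel fully inside the unit disk: area fraction 1/pi
  expect_equal(k[2, 2], 1 / pi, tolerance = 1e-3)
  k2 <- disk_kernel(2.5)
  expect_equal(dim(k2), c(7L, 7L))
  expect_lt(abs(sum(k2) - 1), 1e-12)
  expect_equal(disk_kernel(0), matrix(1, 1, 1))
  expect_error(disk_kernel(-1), ">= 0")
})

test_that("replicate-boundary blur is exact on constants and impulses", {
  k <- disk_kernel(1)
  cimg <- matrix(3.7, 16, 16)
  expect_equal(blur(cimg, k), cimg, tolerance = 1e-12)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- blur(imp, k)
  expect_equal(out[7:9, 7:9], k, tolerance = 1e-12)
  expect_lt(max(abs(out[-(7:9), ])), 1e-12)
  expect_error(blur(matrix(0, 2, 2), k), "larger")
})

test_that("blur computes the 2-D correlation (hand-computed interior pixel)", {
  img <- matrix(c(1, 2, 3, 4, 5,
                  6, 7, 8, 9, 10,
                  11, 12, 13, 14, 15,
                  16, 17, 18, 19, 20,
                  21, 22, 23, 24, 25), 5, 5, byrow = TRUE)
  ker <- matrix(c(0.1, 0.2, 0,
                  0.3, 0.2, 0.1,
                  0, 0.1, 0), 3, 3, byrow = TRUE)
  # correlation at (3,3): sum over kernel entries times the aligned window
  want <- 0.1 * 7 + 0.2 * 8 + 0 * 9 +
          0.3 * 12 + 0.2 * 13 + 0.1 * 14 +
          0 * 17 + 0.1 * 18 + 0 * 19
  expect_equal(blur(img, ker)[3, 3], want, tolerance = 1e-10)
  # interior mean preserved exactly on this linear ramp (symmetric kernel)
  got <- blur(img, disk_kernel(1))
  expect_lt(abs(mean(got[2:4, 2:4]) - mean(img[2:4, 2:4])), 1e-10)
})

test_that("added noise matches the dB definition of SNR", {
  p <- optical_params()
  img <- render_scene(sample_scene(2, p, rng_seed = 5))
  ps <- var(as.vector(img))
  noisy <- add_noise(img, noise_spec(30, seed = 9))
  eps <- noisy - img
  # sigma^2 = P_s / 1000 at 30 dB; 64x64 MC estimate
  expect_equal(var(as.vector(eps)), ps / 1000, tolerance = 0.1)
  # NOISE_FREE is the identity
  expect_identical(add_noise(img, noise_spec(NOISE_FREE)), img)
  expect_error(add_noise(matrix(1, 8, 8), noise_spec(10)), "constant")
  # reproducible under seed, not clipped
  expect_identical(add_noise(img, noise_spec(1, seed = 4)),
                   add_noise(img, noise_spec(1, seed = 4)))
})

test_that("measured SNR inverts the injection and is scale-invariant", {
  set.seed(21)
  img <- matrix(rnorm(256 * 256, mean = 5), 256, 256)
  ps <- var(as.vector(img))
  noisy <- img + matrix(rnorm(256^2, sd = sqrt(ps / 10)), 256, 256)
  expect_equal(measure_snr(img, noisy), 10, tolerance = 0.05)
  expect_identical(measure_snr(img, img), Inf)
  expect_equal(measure_snr(3 * img, 3 * noisy), measure_snr(img, noisy),
               tolerance = 1e-9)
  expect_error(measure_snr(img, matrix(0, 2, 2)), "shape")
})

test_that("noise realizations under different seeds are independent", {
  img <- matrix(seq_len(256 * 256) / 65536, 256, 256)
  e1 <- add_noise(img, noise_spec(10, seed = 1)) - img
  e2 <- add_noise(img, noise_spec(10, seed = 2)) - img
  expect_lt(abs(cor(as.vector(e1), as.vector(e2))), 0.05)
})

test_that("degradation pipeline is blur-then-noise (SNR exact w.r.t. blurred signal)", {
  p <- optical_params()
  img <- render_scene(sample_scene(3, p, rng_seed = 8))
  spec <- noise_spec(15, 1, seed = 33)
  out <- degrade(img, spec)
  blurred <- blur(img, disk_kernel(1))
  # the residual relative to the *blurred* image is pure injected noise with
  # variance var(blurred)/10^1.5
  resid <- out - blurred
  expect_equal(var(as.vector(resid)),
               var(as.vector(blurred)) / 10^1.5, tolerance = 0.1)
})
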