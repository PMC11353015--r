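# Hybrid dataset builder: sample generation, manifests, splits, write-out.

test_that("labels follow the 0-9 plus 'others' rule", {
  expect_identical(spmcount:::label_for_count(0:20),
                   c(0:9, rep(10L, 11)))
  s <- make_sample_m1(12, noise_spec(NOISE_FREE, 0), small_optics(), seed = 1)
  expect_identical(s$label, 10L)
  expect_identical(s$n_particles, 12L)
})

test_that("Method-1 samples carry full provenance and hit the degenerate cases", {
  p <- optical_params()
  s0 <- make_sample_m1(0, noise_spec(NOISE_FREE, 1), p, seed = 2)
  expect_lt(diff(range(s0$image)), 1e-12)          # blank scene stays constant
  expect_identical(s0$label, 0L)
  s3 <- make_sample_m1(3, noise_spec(20, 1), p, seed = 3)
  expect_identical(nrow(unique(s3$provenance$particles[, c("x", "y")])), 3L)
  # same seed, same sample
  expect_identical(make_sample_m1(3, noise_spec(20, 1), p, seed = 3)$image,
                   s3$image)
})

test_that("Method-2 compositing is exact and reduces to Method 1 on a flat background", {
  p <- optical_params()
  spec <- noise_spec(15, 1)
  m1 <- make_sample_m1(3, spec, p, seed = 7)
  m2 <- make_sample_m2(3, matrix(1, 64, 64), p, spec, seed = 7)
  expect_equal(m2$image, m1$image, tolerance = 1e-12)
  expect_error(make_sample_m2(1, matrix(1, 8, 8), p, spec, seed = 1), "shape")
  # n = 0: output is exactly the degraded background
  bg <- gen_background(background_spec(seed = 4), c(64, 64))
  m2z <- make_sample_m2(0, bg, p, spec, seed = 8)
  want <- spmcount:::with_seed(8, degrade(bg, noise_spec(15, 1)))
  expect_equal(m2z$image, want, tolerance = 1e-12)
  # pixelwise compositing identity at spot-checked pixels (no degradation)
  m2r <- make_sample_m2(2, bg, p, noise_spec(NOISE_FREE, 0), seed = 9,
                        degrade_output = FALSE)
  clean <- render_scene(m2r$provenance)
  for (px in list(c(5L, 5L), c(30L, 50L), c(61L, 2L)))
    expect_equal(m2r$image[px[1], px[2]],
                 bg[px[1], px[2]] + clean[px[1], px[2]] - 1, tolerance = 1e-12)
})

test_that("patch library crops are labelled, particle-centered extrema", {
  p <- optical_params()
  lib <- build_patch_library(25, p, amplitude_range = c(1, 1), patch_side = 21,
                             seed = 11, snr_db = NOISE_FREE)
  expect_length(lib$patches, 25)
  expect_true(all(lib$labels >= 1))
  expect_true(all(vapply(lib$patches, function(q) all(dim(q) == 21), logical(1))))
  ctr <- 11L
  off <- vapply(lib$patches, function(q) {
    dev <- abs(q - median(q))
    w <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    sqrt(sum((w - ctr)^2))
  }, numeric(1))
  # strongest deviation from background sits within 2 px of the patch center
  expect_true(all(off <= 2))
  expect_error(build_patch_library(3, p, patch_side = 100), "smaller")
})

test_that("Method-3 pasting accumulates additively with border-mean removal", {
  p <- optical_params()
  lib <- build_patch_library(10, p, patch_side = 15, seed = 12)
  bg <- gen_background(background_spec(seed = 13), c(64, 64))
  expect_equal(make_sample_m3(0, lib, bg, seed = 14)$image, bg)
  s2 <- make_sample_m3(2, lib, bg, seed = 15)
  expect_identical(s2$n_particles, 2L)
  expect_length(s2$provenance$patches, 2L)
  # single paste: window mean shift equals patch mean minus its border mean
  s1 <- make_sample_m3(1, lib, bg, seed = 16)
  at <- s1$provenance$positions[1, ]
  j <- s1$provenance$patches[1]
  win <- s1$image[at[1]:(at[1] + 14), at[2]:(at[2] + 14)] -
    bg[at[1]:(at[1] + 14), at[2]:(at[2] + 14)]
  pm <- mean(lib$patches[[j]])
  bm <- spmcount:::patch_border_mean(lib$patches[[j]])
  expect_lt(abs(mean(win) - (pm - bm)), 1e-10)
})

test_that("hybrid manifests have exact per-method counts and are bit-deterministic", {
  cfg <- hybrid_config(m1_per_noise = 6, m2_count = 4, m3_count = 3,
                       n_backgrounds = 5, patch_library_size = 8,
                       master_seed = 21)
  man <- build_hybrid_dataset(cfg)
  tab <- table(man$label, man$method)
  expect_true(all(tab[, "M1"] == 6 * 7))
  expect_true(all(tab[, "M2"] == 4))
  expect_true(all(tab[, "M3"] == 3))
  expect_false(any(duplicated(man$path)))
  expect_true(all(spmcount:::label_for_count(man$n_particles) == man$label))
  expect_true(all(man$n_particles[man$label == 10] %in% 10:14))
  man2 <- build_hybrid_dataset(cfg)
  expect_identical(spmcount:::object_hash(man), spmcount:::object_hash(man2))
  # a different master seed changes the record seeds
  man3 <- build_hybrid_dataset(hybrid_config(m1_per_noise = 6, m2_count = 4,
                                             m3_count = 3, n_backgrounds = 5,
                                             patch_library_size = 8,
                                             master_seed = 22))
  expect_false(identical(man$seed, man3$seed))
})

test_that("records re-render identically from the manifest alone", {
  cfg <- hybrid_config(m1_per_noise = 1, m2_count = 2, m3_count = 2,
                       n_backgrounds = 3, patch_library_size = 6,
                       patch_side = 15, master_seed = 31)
  man <- build_hybrid_dataset(cfg)
  lib <- manifest_patch_library(man)
  for (i in c(1, 8, 10, 12)) {
    a <- render_record(man, i, patch_library = lib)
    b <- render_record(man, i, patch_library = lib)
    expect_identical(a$image, b$image)
    expect_identical(a$label, man$label[i])
  }
})

test_that("splits are stratified, disjoint and exhaustive with floor rounding", {
  cfg <- hybrid_config(m1_per_noise = 10, m2_count = 5, m3_count = 6,
                       master_seed = 41)
  man <- split_manifest(build_hybrid_dataset(cfg), seed = 42)
  expect_false(any(is.na(man$split)))
  per <- table(man$label, man$split)  # 81 per class -> 8/8 val/test, 65 train
  expect_true(all(per[, "val"] == 8))
  expect_true(all(per[, "test"] == 8))
  expect_true(all(per[, "train"] == 65))
  small <- build_hybrid_dataset(hybrid_config(m1_per_noise = 1, m2_count = 0,
                                              m3_count = 0, master_seed = 1))
  expect_error(split_manifest(small), "at least 10")
})

test_that("written images are 224x224 3-channel PNGs with full dynamic range", {
  cfg <- hybrid_config(classes = 0:1, m1_per_noise = 1,
                       noise_grid = c(NOISE_FREE, 20), m2_count = 0,
                       m3_count = 0, master_seed = 51)
  man <- build_hybrid_dataset(cfg)
  td <- withr::local_tempdir()
  write_images(man, td)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  expect_true(file.exists(file.path(td, "config.json")))
  a <- png::readPNG(file.path(td, man$path[man$label == 1 & is.finite(man$snr_db)]))
  expect_equal(dim(a), c(224, 224, 3))
  expect_identical(a[, , 1], a[, , 3])                 # replicated grayscale
  expect_equal(range(a * 255), c(0, 255), tolerance = 1e-6)  # min-max span
  # class-0 noise-free record is constant -> written as mid-gray 128
  blank <- png::readPNG(file.path(td, man$path[man$label == 0 & !is.finite(man$snr_db)]))
  expect_true(all(abs(blank * 255 - 128) < 0.5))
  expect_equal(quantize_image(matrix(2, 4, 4)), matrix(128, 4, 4))
  q <- quantize_image(matrix(c(1, 2, 3, 4), 2))
  expect_equal(range(q), c(0, 255))
})
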