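# Classifier profiles, training behaviour, inference contracts.

test_that("profiles expose the stated topology and 11-way output", {
  b0 <- arch_profile("b0")
  expect_identical(b0$n_stages, 9L)            # stem + 7 MBConv stages + head
  expect_identical(nrow(b0$stages), 7L)
  expect_identical(sort(unique(b0$stages$kernel)), c(3, 5))
  expect_identical(b0$n_classes, 11L)
  desk <- build_model(arch_profile("desk"), seed = 1)
  pr <- predict(desk, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_identical(ncol(pr), 11L)
  expect_error(arch_profile("vgg"))
})

test_that("the b0-style network matches the canonical parameter budget", {
  m11 <- build_model(arch_profile("b0"), seed = 1)
  m1000 <- build_model(arch_profile("b0", n_classes = 1000L), seed = 1)
  # canonical figure for this topology with its 1000-class head: ~5.3M
  expect_lt(abs(count_params(m1000) - 5.3e6) / 5.3e6, 0.10)
  # the 11-class head drops the classifier weights only
  expect_identical(count_params(m1000) - count_params(m11),
                   1280 * (1000 - 11) + (1000 - 11))
  # forward pass emits an 11-way distribution
  pr <- predict(m11, array(runif(224 * 224 * 3), c(224, 224, 3, 1)))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})

test_that("identical seeds give identical initializations; different seeds differ", {
  a <- build_model(arch_profile("desk"), seed = 7)
  b <- build_model(arch_profile("desk"), seed = 7)
  c <- build_model(arch_profile("desk"), seed = 8)
  expect_identical(spmcount:::param_checksum(a), spmcount:::param_checksum(b))
  expect_false(identical(spmcount:::param_checksum(a), spmcount:::param_checksum(c)))
})

test_that("training reduces the loss and can overfit a small fixture", {
  fix <- make_m1_stack(rep(c(0:9, 12), each = 5), snr_db = 30, seed = 61)
  m <- build_model(arch_profile("desk"), seed = 5)
  m <- spm_train(m, list(x = fix$x, labels = fix$labels), epochs = 50,
                 batch_size = 16, seed = 6)
  expect_lt(m$log$loss[5], m$log$loss[1])
  expect_identical(mean(predict(m, fix$x, type = "class") == fix$labels), 1)
  expect_true(m$trained)
})

test_that("training is reproducible under a fixed seed", {
  fix <- make_m1_stack(rep(c(0, 5, 9), each = 12), snr_db = 25, seed = 71)
  val <- make_m1_stack(rep(c(0, 5, 9), each = 4), snr_db = 25, seed = 72)
  run <- function() {
    m <- build_model(arch_profile("desk"), seed = 9)
    spm_train(m, list(x = fix$x, labels = fix$labels, xval = val$x,
                      val_labels = val$labels), epochs = 3, seed = 10)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$log, m2$log)
  expect_identical(spmcount:::param_checksum(m1), spmcount:::param_checksum(m2))
})

test_that("separating blank from crowded scenes is learnable to >= 99%", {
  # no-noise two-class restriction (N in {0, 9}): total scattered energy
  # dominates, so the reduced profile must solve it almost perfectly
  tr <- make_m1_stack(rep(c(0, 9), 200), snr_db = NOISE_FREE, seed = 81)
  te <- make_m1_stack(rep(c(0, 9), 50), snr_db = NOISE_FREE, seed = 82)
  m <- build_model(arch_profile("desk"), seed = 11)
  m <- spm_train(m, list(x = tr$x, labels = tr$labels), epochs = 6, seed = 12)
  expect_gte(mean(predict(m, te$x, type = "class") == te$labels), 0.99)
})

test_that("prediction contracts: normalization, batching invariance, tie-break, resize", {
  m <- build_model(arch_profile("desk"), seed = 13)
  x <- array(runif(64 * 64 * 1 * 7, 0, 255), c(64, 64, 1, 7))
  pr <- predict(m, x)
  expect_equal(rowSums(pr), rep(1, 7), tolerance = 1e-6)
  one_by_one <- t(vapply(1:7, function(i)
    predict(m, x[, , , i, drop = FALSE])[1, ], numeric(11)))
  expect_equal(unname(pr), unname(one_by_one), tolerance = 1e-9)
  expect_identical(predict(m, x, type = "class"),
                   unname(apply(pr, 1, which.max)) - 1L)
  # oversized input is resized down to the profile input
  big <- array(runif(128 * 128 * 3), c(128, 128, 3, 2))
  expect_identical(dim(predict(m, big)), c(2L, 11L))
  # checkpoint round-trip preserves predictions
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  expect_equal(predict(load_model(f), x), pr, tolerance = 1e-12)
  unlink(f)
})
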