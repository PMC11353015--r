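# Simulator physics: plane wave, scattered wave, coherent rendering.

test_that("plane wave has unit-amplitude modulus and the stated phase structure", {
  p <- optical_params()  # lambda 0.6 um, pitch 0.1 um -> half period = 3 px
  pw <- plane_wave_field(p)
  expect_equal(Mod(pw), matrix(1, 64, 64), tolerance = 1e-12)
  expect_equal(pw[1, 1], 1 + 0i, tolerance = 1e-12)          # zero phase at origin
  expect_equal(pw[1, 4], -1 + 0i, tolerance = 1e-12)         # half period along +x
  # E0 scales the whole field
  p2 <- optical_params(background_amplitude = 2.5)
  expect_equal(Mod(plane_wave_field(p2))[10, 20], 2.5, tolerance = 1e-12)
  expect_error(optical_params(sp_wavelength = -1), "positive")
  expect_error(optical_params(prop_direction = c(1, 1)), "unit")
})

test_that("scattered wave has the decaying cylindrical envelope with clamp", {
  p <- optical_params(image_shape = c(64L, 256L), decay_length = 2)
  part <- particle_spec(x = 0, y = 0, amplitude = 1, phase = 0)
  s <- scattered_field(p, part)
  # at rho = L (20 px along x from the particle): modulus e^-1 / sqrt(L)
  expect_equal(Mod(s)[1, 21], exp(-1) / sqrt(2), tolerance = 1e-12)
  # inside the clamp disk the field equals its value at rho = min_distance
  expect_equal(s[1, 1], s[1, 2], tolerance = 1e-12)
  # modulus is monotone non-increasing with rho beyond the clamp
  m <- Mod(s)[1, ]
  expect_true(all(diff(m[-1]) <= 1e-15))
})

test_that("rendering matches independent complex arithmetic at chosen pixels", {
  p <- optical_params()
  part <- particle_spec(x = 2.03, y = 3.17, amplitude = 0.7, phase = 1.1)
  img <- render_scene(spm_scene(p, part))
  k <- 2 * pi / p$sp_wavelength
  for (px in list(c(1L, 1L), c(20L, 45L), c(33L, 12L))) {
    x <- (px[2] - 1) * p$pixel_pitch
    y <- (px[1] - 1) * p$pixel_pitch
    rho <- max(sqrt((x - part$x)^2 + (y - part$y)^2), p$min_distance)
    want <- Mod(exp(1i * k * x) +
                  0.7 * exp(1i * (k * rho + 1.1)) * exp(-rho / 10) / sqrt(rho))^2
    expect_equal(img[px[1], px[2]], want, tolerance = 1e-12)
  }
})

test_that("renders are non-negative, linear in scattered fields, and mirror-symmetric", {
  p <- optical_params()
  expect_equal(render_scene(spm_scene(p)), matrix(1, 64, 64), tolerance = 1e-15)
  # linearity: multi-particle scattered field is the sum of singles (exact)
  parts <- particle_spec(x = c(1.5, 4.2, 3.3), y = c(2.5, 1.1, 5.0),
                         amplitude = c(0.5, 0.8, 0.3), phase = c(0, 2, 4))
  total <- Reduce(`+`, lapply(1:3, function(j)
    scattered_field(p, parts[j, , drop = FALSE])))
  img <- render_scene(spm_scene(p, parts))
  expect_equal(img, Mod(plane_wave_field(p) + total)^2, tolerance = 1e-12)
  expect_true(all(img >= 0))
  # one particle on the propagation axis: reflection symmetry about its row
  part <- particle_spec(x = 3.0, y = 3.0, amplitude = 1, phase = 0.4)
  im1 <- render_scene(spm_scene(p, part))
  y0 <- 31  # 0-based row 30 is y = 3.0
  for (d in c(3, 9, 17))
    expect_equal(im1[y0 + d, ], im1[y0 - d, ], tolerance = 1e-12)
})

test_that("one-particle intensity obeys the constructive/destructive bounds", {
  p <- optical_params()
  part <- particle_spec(x = 2.9, y = 3.4, amplitude = 0.9, phase = 2.2)
  img <- render_scene(spm_scene(p, part))
  s <- Mod(scattered_field(p, part))
  e0 <- p$background_amplitude
  expect_true(all(img >= e0^2 - 2 * e0 * s - 1e-12))
  expect_true(all(img <= e0^2 + 2 * e0 * s + s^2 + 1e-12))
})

test_that("interference phase is constant along a parabola focused on the particle", {
  # With propagation +x, the relative phase k*(rho - x) has parabolic level
  # sets. Pixels exactly on the parabola rho = c + (x - x0), c = 5 px:
  # v = {5,15,25,35} px -> u = {0,20,60,120} px.
  p <- optical_params(image_shape = c(96L, 144L))
  x0 <- 4L; y0 <- 48L  # 0-based pixel indices of the particle
  part <- particle_spec(x = x0 * 0.1, y = y0 * 0.1, amplitude = 1, phase = 0.7)
  s <- scattered_field(p, part)
  pw <- plane_wave_field(p)
  u <- c(0L, 20L, 60L, 120L); v <- c(5L, 15L, 25L, 35L)
  ph <- Arg(s[cbind(y0 + v + 1L, x0 + u + 1L)] *
              Conj(pw[cbind(y0 + v + 1L, x0 + u + 1L)]))
  ph <- c(ph, Arg(s[cbind(y0 - v + 1L, x0 + u + 1L)] *
                    Conj(pw[cbind(y0 - v + 1L, x0 + u + 1L)])))
  delta <- (ph - ph[1]) %% (2 * pi)
  delta <- pmin(delta, 2 * pi - delta)
  expect_true(all(delta < 1e-9))
})

test_that("whole-image render matches a naive per-pixel loop oracle", {
  p <- small_optics()
  sc <- sample_scene(3, p, position_margin = 3, rng_seed = 7)
  img <- render_scene(sc)
  k <- 2 * pi / p$sp_wavelength
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    x <- (j - 1) * p$pixel_pitch; y <- (i - 1) * p$pixel_pitch
    f <- exp(1i * k * x)
    for (q in seq_len(nrow(sc$particles))) {
      pt <- sc$particles[q, ]
      rho <- max(sqrt((x - pt$x)^2 + (y - pt$y)^2), p$min_distance)
      f <- f + pt$amplitude * exp(1i * (k * rho + pt$phase)) *
        exp(-rho / p$decay_length) / sqrt(rho)
    }
    oracle[i, j] <- Mod(f)^2
  }
  expect_lt(max(abs(img - oracle)), 1e-10)
})

test_that("scene sampling is reproducible, margin-bounded and uniform", {
  p <- optical_params()
  expect_equal(nrow(sample_scene(0, p, rng_seed = 1)$particles), 0)
  s1 <- sample_scene(5, p, rng_seed = 11)
  s2 <- sample_scene(5, p, rng_seed = 11)
  expect_identical(scene_to_json(s1), scene_to_json(s2))
  expect_error(sample_scene(2, p, position_margin = 40), "placement")

  big <- sample_scene(10000, p, position_margin = 4, rng_seed = 13)
  ext <- 63 * 0.1; m <- 4 * 0.1
  expect_true(all(big$particles$x >= m & big$particles$x <= ext - m))
  expect_true(all(big$particles$y >= m & big$particles$y <= ext - m))
  expect_true(all(big$particles$phase >= 0 & big$particles$phase < 2 * pi))
  # two-sided uniformity: chi-square over 20 equal bins per axis
  for (v in list(big$particles$x, big$particles$y)) {
    h <- table(cut(v, breaks = seq(m, ext - m, length.out = 21)))
    expect_gt(stats::chisq.test(h)$p.value, 0.01)
  }
})

test_that("scenes serialize to JSON losslessly and deterministically", {
  sc <- sample_scene(4, optical_params(), rng_seed = 3)
  js <- scene_to_json(sc)
  back <- scene_from_json(js)
  expect_equal(back$particles, sc$particles, tolerance = 0)
  expect_equal(back$params, sc$params)
  expect_identical(scene_to_json(back), js)
  expect_error(spm_scene(optical_params(), particle_spec(x = 99, y = 1)),
               "extent")
})
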