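# Synthetic background generator. Real SPM backgrounds are non-uniform
# because the intensity and angle of incidence vary over the sample surface
# and vibration leaves streak-like motion artifacts; this module emulates
# those features (planar illumination gradient, band-limited speckle, 1-D
# streaks) so composited training images carry realistic background structure.
# The generator is a documented synthetic stand-in: crops from real
# experimental images can be dropped in through the same interface.

#' Background specification
#'
#' @param gradient_amplitude amplitude of the planar illumination gradient
#'   (peak deviation from the 1.0 baseline at the image corners).
#' @param speckle_amplitude standard deviation of the band-limited speckle
#'   field.
#' @param speckle_correlation_length 1/e width of the speckle autocorrelation,
#'   pixels.
#' @param streak_amplitude standard deviation of the 1-D streak pattern.
#' @param streak_direction `"horizontal"` (streaks run along rows; value
#'   varies with row index) or `"vertical"`.
#' @param seed integer seed; the background is deterministic given the spec.
#' @return An object of class `background_spec`.
#' @export
background_spec <- function(gradient_amplitude = 0.05, speckle_amplitude = 0.04,
                            speckle_correlation_length = 8,
                            streak_amplitude = 0.02,
                            streak_direction = c("horizontal", "vertical"),
                            seed = 1L) {
  if (gradient_amplitude < 0 || speckle_amplitude < 0 || streak_amplitude < 0)
    stop_param("amplitudes must be >= 0")
  if (speckle_correlation_length <= 0)
    stop_param("speckle_correlation_length must be positive")
  structure(list(gradient_amplitude = gradient_amplitude,
                 speckle_amplitude = speckle_amplitude,
                 speckle_correlation_length = speckle_correlation_length,
                 streak_amplitude = streak_amplitude,
                 streak_direction = match.arg(streak_direction),
                 seed = as.integer(seed)),
            class = "background_spec")
}

gaussian_kernel_1d <- function(sigma, half = ceiling(3 * sigma)) {
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Generate a synthetic background image
#'
#' Baseline 1.0 plus a planar gradient of random orientation, plus Gaussian
#' speckle low-pass filtered to the configured correlation length (a white
#' field convolved with a Gaussian of sigma = length/2 has autocorrelation
#' `exp(-d^2 / length^2)`, i.e. 1/e at the correlation length), plus 1-D
#' streaks along the configured direction.
#'
#' @param spec a [background_spec()].
#' @param shape integer (rows, cols).
#' @return A background intensity matrix.
#' @export
gen_background <- function(spec, shape = c(64L, 64L)) {
  stopifnot(inherits(spec, "background_spec"))
  nr <- shape[1]; nc <- shape[2]
  with_seed(spec$seed, {
    img <- matrix(1, nr, nc)
    if (spec$gradient_amplitude > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      u <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
      v <- matrix(seq(-1, 1, length.out = nr), nr, nc)
      img <- img + spec$gradient_amplitude * (cos(theta) * u + sin(theta) * v)
    }
    if (spec$speckle_amplitude > 0) {
      sigma <- spec$speckle_correlation_length / 2
      k1 <- gaussian_kernel_1d(sigma)
      k <- outer(k1, k1)
      # keep the kernel smaller than the image for very small grids
      if (any(dim(k) > c(nr, nc))) {
        half <- min((nr - 1) %/% 2, (nc - 1) %/% 2)
        k1 <- gaussian_kernel_1d(sigma, half = half)
        k <- outer(k1, k1)
      }
      w <- matrix(stats::rnorm(nr * nc), nr, nc)
      s <- blur(w, k)
      s <- s - mean(s)
      sdv <- stats::sd(as.vector(s))
      if (sdv > 0) img <- img + spec$speckle_amplitude * s / sdv
    }
    if (spec$streak_amplitude > 0) {
      n1 <- if (spec$streak_direction == "horizontal") nr else nc
      w1 <- stats::rnorm(n1)
      k1 <- gaussian_kernel_1d(2)
      s1 <- stats::filter(c(rev(w1[seq_len(length(k1))]), w1,
                            rev(w1[n1 - seq_len(length(k1)) + 1])),
                          k1, sides = 2)
      s1 <- s1[length(k1) + seq_len(n1)]
      s1 <- s1 - mean(s1)
      sdv <- stats::sd(s1)
      if (sdv > 0) s1 <- spec$streak_amplitude * s1 / sdv else s1 <- s1 * 0
      img <- img + if (spec$streak_direction == "horizontal")
        matrix(s1, nr, nc) else matrix(s1, nr, nc, byrow = TRUE)
    }
    img
  })
}
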