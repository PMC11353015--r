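# Image degradation: disk blur followed by additive Gaussian noise at a
# target signal-to-noise ratio (SNR) in dB. The order is fixed as
# blur-then-noise so the stated SNR is exact with respect to the blurred
# signal; the order is recorded in every dataset manifest.

#' Sentinel for the noise-free condition
#'
#' Represented as `Inf` dB: infinite signal-to-noise ratio means no noise is
#' added.
#' @export
NOISE_FREE <- Inf

#' Noise/blur specification
#'
#' @param snr_db target signal-to-noise ratio in dB, or [NOISE_FREE].
#' @param blur_radius radius of the disk blur kernel, pixels (>= 0; 0 disables
#'   blurring).
#' @param boundary boundary handling for the blur; only `"replicate"` (edge
#'   pixels extended outward) is supported.
#' @param seed integer seed for the noise realization.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = NOISE_FREE, blur_radius = 1,
                       boundary = "replicate", seed = NA_integer_) {
  boundary <- match.arg(boundary, "replicate")
  if (blur_radius < 0) stop_param("blur_radius must be >= 0")
  if (is.na(snr_db) || is.nan(snr_db)) stop_param("snr_db must be finite or NOISE_FREE")
  structure(list(snr_db = snr_db, blur_radius = blur_radius,
                 boundary = boundary, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Disk blur kernel
#'
#' Kernel of side `2*ceiling(radius) + 1` whose entry (i, j) is proportional
#' to the area of overlap between the disk of the given radius (centered on
#' the kernel center) and pixel (i, j)'s unit square; entries sum to 1. The
#' overlap areas are computed by sub-pixel supersampling (`supersample^2`
#' points per pixel), which preserves the disk's 4-fold symmetry exactly.
#'
#' @param radius disk radius in pixels (>= 0). Radius 0 yields the identity
#'   1x1 kernel.
#' @param supersample sub-pixel sampling density per axis.
#' @return A normalized non-negative matrix of odd side length.
#' @export
disk_kernel <- function(radius, supersample = 256L) {
  if (radius < 0) stop_param("radius must be >= 0")
  if (radius == 0) return(matrix(1, 1, 1))
  half <- ceiling(radius)
  side <- 2L * half + 1L
  # sub-pixel center offsets within one pixel, symmetric about 0
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  centers <- -half:half
  # fraction of each 1-D pixel strip covered, combined per pixel pair via
  # the disk condition x^2 + y^2 <= r^2 on the supersampled grid
  xs <- as.vector(outer(off, centers, "+"))        # all sub-x positions
  k <- matrix(0, side, side)
  r2 <- radius^2
  for (i in seq_len(side)) {
    ys <- off + centers[i]
    # count sub-points inside the disk for row i against all columns at once
    inside <- outer(ys^2, xs^2, "+") <= r2
    cnt <- colSums(inside)
    k[i, ] <- .colSums(matrix(cnt, supersample, side), supersample, side)
  }
  k / sum(k)
}

#' Blur an image with a kernel under replicate boundary handling
#'
#' 2-D correlation of the image with the kernel; edge pixels are extended
#' outward (replicate padding), so a constant image is exactly invariant.
#'
#' @param image numeric matrix.
#' @param kernel normalized kernel of odd side, no larger than the image.
#' @param boundary only `"replicate"`.
#' @return The blurred image, same dimensions as the input.
#' @export
blur <- function(image, kernel = disk_kernel(1), boundary = "replicate") {
  boundary <- match.arg(boundary, "replicate")
  if (any(dim(kernel) > dim(image)))
    stop_param("kernel larger than image")
  if (all(dim(kernel) == c(1L, 1L))) return(image * kernel[1, 1])
  # EBImage::filter2 applies the flipped kernel (convolution); flip it so the
  # result is the correlation the blur is defined as.
  kf <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))), drop = FALSE]
  out <- EBImage::filter2(image, kf, boundary = "replicate")
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}

#' Add Gaussian noise at a target SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `var(image) / 10^(snr_db / 10)`, where the signal power is the variance of
#' the clean image about its mean (the flat background does not inflate the
#' SNR). The output is not clipped. With `snr_db = NOISE_FREE` the image is
#' returned unchanged.
#'
#' @param image numeric matrix; must be non-constant when `snr_db` is finite.
#' @param spec a [noise_spec()]; if its `seed` is not `NA` the noise is drawn
#'   under that seed, otherwise from the current RNG stream.
#' @return The noisy image.
#' @export
add_noise <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.finite(spec$snr_db)) return(image)
  ps <- stats::var(as.vector(image))
  if (ps == 0) stop_param("constant image: signal power undefined for finite snr_db")
  sigma <- sqrt(ps / 10^(spec$snr_db / 10))
  draw <- function() image + matrix(stats::rnorm(length(image), sd = sigma),
                                    nrow(image), ncol(image))
  if (!is.na(spec$seed)) with_seed(spec$seed, draw()) else draw()
}

#' Measure the SNR of a degraded image against its clean reference
#'
#' `10 * log10(var(clean) / mean((degraded - clean)^2))`; returns `Inf` when
#' the residual is exactly zero.
#'
#' @param clean,degraded numeric matrices of identical dimensions.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, degraded) {
  if (!all(dim(clean) == dim(degraded))) stop_param("shape mismatch")
  mse <- mean((degraded - clean)^2)
  if (mse == 0) return(Inf)
  10 * log10(stats::var(as.vector(clean)) / mse)
}

#' Apply the full degradation pipeline (blur, then noise)
#'
#' @param image clean intensity image.
#' @param spec a [noise_spec()].
#' @return The degraded image.
#' @export
degrade <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$blur_radius > 0)
    image <- blur(image, disk_kernel(spec$blur_radius), spec$boundary)
  add_noise(image, spec)
}
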