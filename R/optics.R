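# Physical model of surface plasmon microscopy (SPM) image formation.
#
# A surface plasmon (SP) plane wave of wavelength `sp_wavelength` propagates
# along `prop_direction`; each nanoparticle on the metal film scatters it as an
# in-plane decaying cylindrical wave. The camera sees the squared modulus of
# the coherent sum, which produces the characteristic parabolic-tailed fringe
# pattern of single particles in SPM images.

#' Optical parameters for SPM image simulation
#'
#' Bundles the physical and geometric constants that determine how a scene is
#' rendered: the surface plasmon (SP) wavelength (spatial period of the
#' propagating plane wave), the 1/e amplitude decay length of the scattered
#' wave, the propagation direction, the background field amplitude, and the
#' pixel grid.
#'
#' Coordinate convention: the pixel grid is row-major with the origin at the
#' center of pixel (0, 0); x increases with column index, y with row index,
#' and particle positions are continuous (sub-pixel), in micrometers.
#'
#' @param sp_wavelength SP wavelength in micrometers (spatial period of the
#'   plane wave). Must be positive.
#' @param decay_length 1/e decay length of the scattered-wave amplitude
#'   envelope, micrometers. Must be positive.
#' @param prop_direction unit 2-vector (x, y) giving the SP propagation
#'   direction; normalized within 1e-9 or rejected.
#' @param background_amplitude dimensionless plane-wave field amplitude E0 > 0.
#' @param pixel_pitch physical size of one pixel, micrometers.
#' @param image_shape integer (rows, cols) of the simulation grid.
#' @param min_distance clamp radius in micrometers applied to the distance from
#'   a particle before evaluating its scattered wave, so the 1/sqrt(rho)
#'   envelope stays finite at the particle position. Must be at least half a
#'   pixel; defaults to one pixel pitch.
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(sp_wavelength = 0.6, decay_length = 10,
                           prop_direction = c(1, 0), background_amplitude = 1,
                           pixel_pitch = 0.1, image_shape = c(64L, 64L),
                           min_distance = pixel_pitch) {
  if (!is.numeric(sp_wavelength) || sp_wavelength <= 0)
    stop_param("sp_wavelength must be positive")
  if (decay_length <= 0) stop_param("decay_length must be positive")
  if (background_amplitude <= 0) stop_param("background_amplitude must be positive")
  if (pixel_pitch <= 0) stop_param("pixel_pitch must be positive")
  if (length(prop_direction) != 2 || abs(sqrt(sum(prop_direction^2)) - 1) > 1e-9)
    stop_param("prop_direction must be a unit 2-vector (|norm - 1| <= 1e-9)")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 1))
    stop_param("image_shape must be two positive integers (rows, cols)")
  if (min_distance < pixel_pitch / 2)
    stop_param("min_distance must be at least pixel_pitch/2")
  structure(list(sp_wavelength = sp_wavelength, decay_length = decay_length,
                 prop_direction = as.numeric(prop_direction),
                 background_amplitude = background_amplitude,
                 pixel_pitch = pixel_pitch, image_shape = image_shape,
                 min_distance = min_distance),
            class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat("SPM optical parameters\n")
  cat(sprintf("  SP wavelength : %g um   decay length: %g um\n",
              x$sp_wavelength, x$decay_length))
  cat(sprintf("  direction     : (%g, %g)   E0: %g\n",
              x$prop_direction[1], x$prop_direction[2], x$background_amplitude))
  cat(sprintf("  grid          : %d x %d px at %g um/px (clamp %g um)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_pitch, x$min_distance))
  invisible(x)
}

# Physical extent of the grid: pixel centers span [0, (n-1) * pitch] on each
# axis.
image_extent <- function(params) {
  c(x = (params$image_shape[2] - 1) * params$pixel_pitch,
    y = (params$image_shape[1] - 1) * params$pixel_pitch)
}

#' Particle specifications
#'
#' A particle list is a data frame with columns `x`, `y` (position in
#' micrometers, continuous), `amplitude` (dimensionless scattering amplitude
#' A >= 0) and `phase` (radians in \[0, 2*pi)).
#'
#' @param x,y particle positions, micrometers, inside the image extent.
#' @param amplitude scattering amplitudes, >= 0.
#' @param phase scattering phases, radians.
#' @return A data frame of particle specifications.
#' @export
particle_spec <- function(x, y, amplitude = 1, phase = 0) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   amplitude = rep_len(as.numeric(amplitude), length(x)),
                   phase = rep_len(as.numeric(phase), length(x)))
  if (any(df$amplitude < 0)) stop_param("amplitude must be >= 0")
  df$phase <- df$phase %% (2 * pi)
  df
}

#' Construct a scene
#'
#' A scene is the full deterministic description of one clean SPM image:
#' optical parameters, a particle list, and the seed it was sampled from.
#'
#' @param params an [optical_params()] object.
#' @param particles a particle data frame (see [particle_spec()]); may have
#'   zero rows.
#' @param seed integer provenance seed (informational; rendering is
#'   deterministic given `params` and `particles`).
#' @return An object of class `spm_scene`.
#' @export
spm_scene <- function(params, particles = particle_spec(numeric(0), numeric(0)),
                      seed = NA_integer_) {
  stopifnot(inherits(params, "optical_params"))
  if (nrow(particles) > 0) {
    ext <- image_extent(params)
    if (any(particles$x < 0 | particles$x > ext["x"] |
            particles$y < 0 | particles$y > ext["y"]))
      stop_param("particle positions must lie inside the image extent")
  }
  structure(list(params = params, particles = particles,
                 seed = as.integer(seed)),
            class = "spm_scene")
}

#' @export
print.spm_scene <- function(x, ...) {
  cat(sprintf("SPM scene: %d particle(s) on a %d x %d grid (seed %s)\n",
              nrow(x$particles), x$params$image_shape[1],
              x$params$image_shape[2], x$seed))
  if (nrow(x$particles)) print(utils::head(x$particles, 10))
  invisible(x)
}

# Pixel-center coordinate matrices in micrometers.
coord_grids <- function(params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  xs <- (seq_len(nc) - 1) * params$pixel_pitch
  ys <- (seq_len(nr) - 1) * params$pixel_pitch
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Plane surface-plasmon wave field
#'
#' Complex field E0 * exp(i * k_sp * (r . d)) of the propagating SP plane
#' wave, with k_sp = 2*pi / sp_wavelength and d the propagation direction.
#' The phase is zero at the center of pixel (0, 0).
#'
#' @param params an [optical_params()] object.
#' @return A complex matrix of dimension `image_shape`.
#' @export
plane_wave_field <- function(params) {
  stopifnot(inherits(params, "optical_params"))
  g <- coord_grids(params)
  k <- 2 * pi / params$sp_wavelength
  phase <- k * (g$x * params$prop_direction[1] + g$y * params$prop_direction[2])
  params$background_amplitude * exp(1i * phase)
}

#' Scattered wave field of a single particle
#'
#' In-plane decaying cylindrical wave
#' `A * exp(i * (k_sp * rho + phi)) * exp(-rho / L) / sqrt(rho)`, where `rho`
#' is the distance to the particle. Inside the clamp disk (`rho <
#' min_distance`) the clamped distance is used throughout, so the field is
#' constant-modulus there and finite at the particle position.
#'
#' @param params an [optical_params()] object.
#' @param particle a one-row particle data frame.
#' @return A complex matrix of dimension `image_shape`.
#' @export
scattered_field <- function(params, particle) {
  stopifnot(inherits(params, "optical_params"), nrow(particle) == 1)
  g <- coord_grids(params)
  k <- 2 * pi / params$sp_wavelength
  rho <- sqrt((g$x - particle$x)^2 + (g$y - particle$y)^2)
  rho <- pmax(rho, params$min_distance)
  particle$amplitude * exp(1i * (k * rho + particle$phase)) *
    exp(-rho / params$decay_length) / sqrt(rho)
}

#' Render a scene to a clean intensity image
#'
#' Coherently sums the plane wave and all scattered waves and takes the
#' squared modulus per pixel: `I = |P + sum_j S_j|^2`.
#'
#' @param scene an [spm_scene()] object.
#' @return A non-negative intensity matrix of dimension `image_shape`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "spm_scene"))
  field <- plane_wave_field(scene$params)
  p <- scene$particles
  if (nrow(p) > 0)
    for (j in seq_len(nrow(p)))
      field <- field + scattered_field(scene$params, p[j, , drop = FALSE])
  Mod(field)^2
}

#' Sample a random scene
#'
#' Draws particle positions i.i.d. uniformly in the margin-inset placement
#' rectangle, amplitudes uniformly in `amplitude_range`, and phases uniformly
#' in \[0, 2*pi).
#'
#' @param n_particles number of particles (>= 0).
#' @param params an [optical_params()] object.
#' @param position_margin margin in pixels kept free on every side of the
#'   placement rectangle.
#' @param amplitude_range length-2 numeric range for the scattering amplitude.
#' @param rng_seed integer seed; if `NULL` the current RNG stream is used.
#' @return An [spm_scene()] object.
#' @export
sample_scene <- function(n_particles, params = optical_params(),
                         position_margin = 4, amplitude_range = c(0.2, 1),
                         rng_seed = NULL) {
  if (n_particles < 0) stop_param("n_particles must be >= 0")
  if (2 * position_margin >= min(params$image_shape))
    stop_param("position_margin leaves no placement region")
  if (!is.null(rng_seed))
    return(with_seed(rng_seed, sample_scene(n_particles, params,
                                            position_margin, amplitude_range,
                                            rng_seed = NULL)))
  ext <- image_extent(params)
  m <- position_margin * params$pixel_pitch
  n <- as.integer(n_particles)
  particles <- particle_spec(
    x = stats::runif(n, m, ext["x"] - m),
    y = stats::runif(n, m, ext["y"] - m),
    amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]),
    phase = stats::runif(n, 0, 2 * pi))
  spm_scene(params, particles,
            seed = if (is.null(rng_seed)) NA_integer_ else rng_seed)
}

#' Serialize a scene to JSON (and back)
#'
#' The JSON document carries explicit unit annotations and full-precision
#' numbers so that a scene round-trips losslessly; the same scene always
#' serializes to byte-identical JSON.
#'
#' @param scene an [spm_scene()] object.
#' @return `scene_to_json()`: a JSON string; `scene_from_json()`: an
#'   [spm_scene()].
#' @export
scene_to_json <- function(scene) {
  stopifnot(inherits(scene, "spm_scene"))
  p <- scene$params
  doc <- list(
    units = list(length = "micrometer", angle = "radian"),
    params = list(sp_wavelength = p$sp_wavelength,
                  decay_length = p$decay_length,
                  prop_direction = p$prop_direction,
                  background_amplitude = p$background_amplitude,
                  pixel_pitch = p$pixel_pitch,
                  image_shape = p$image_shape,
                  min_distance = p$min_distance),
    particles = scene$particles,
    seed = scene$seed)
  as.character(jsonlite::toJSON(doc, digits = I(17), na = "null",
                                auto_unbox = TRUE, dataframe = "columns"))
}

#' @rdname scene_to_json
#' @param json a JSON string produced by `scene_to_json()`.
#' @export
scene_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  p <- doc$params
  params <- optical_params(sp_wavelength = p$sp_wavelength,
                           decay_length = p$decay_length,
                           prop_direction = p$prop_direction,
                           background_amplitude = p$background_amplitude,
                           pixel_pitch = p$pixel_pitch,
                           image_shape = p$image_shape,
                           min_distance = p$min_distance)
  parts <- doc$particles
  particles <- if (length(parts) == 0 || is.null(parts$x))
    particle_spec(numeric(0), numeric(0))
  else particle_spec(parts$x, parts$y, parts$amplitude, parts$phase)
  spm_scene(params, particles,
            seed = if (is.null(doc$seed)) NA_integer_ else doc$seed)
}
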