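# Hybrid labelled-dataset builder. Three generation methods:
#   M1 - pure physics simulation (sampled scene, rendered, degraded);
#   M2 - simulated particle interference composited onto a background image;
#   M3 - pre-rendered particle patches pasted onto a background.
# A manifest records every image's provenance (method, count, label, SNR,
# seeds), so any record re-renders bit-identically from the manifest alone.

label_for_count <- function(n) pmin(as.integer(n), 10L)

new_image_sample <- function(image, n_particles, method, snr_db, seed,
                             provenance = NULL) {
  structure(list(image = image, n_particles = as.integer(n_particles),
                 label = label_for_count(n_particles), method = method,
                 snr_db = snr_db, seed = as.integer(seed),
                 provenance = provenance),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("SPM image sample [%s]: %d particle(s), label %d, SNR %s dB, seed %d\n",
              x$method, x$n_particles, x$label,
              if (is.finite(x$snr_db)) format(x$snr_db) else "none", x$seed))
  invisible(x)
}

#' Generate a Method-1 sample (pure simulation)
#'
#' Samples a random scene with `n` particles, renders it, and applies the
#' blur-then-noise degradation.
#'
#' @param n particle count (the class label is `min(n, 10)`).
#' @param snr a [noise_spec()]; its `seed` field is ignored (the sample seed
#'   governs the whole generation).
#' @param optics an [optical_params()] object.
#' @param seed integer seed making the sample fully reproducible.
#' @param position_margin,amplitude_range passed to [sample_scene()].
#' @return An `image_sample` (image, count, label, provenance).
#' @export
make_sample_m1 <- function(n, snr = noise_spec(), optics = optical_params(),
                           seed = 1L, position_margin = 4,
                           amplitude_range = c(0.2, 1)) {
  stopifnot(n >= 0)
  spec <- noise_spec(snr$snr_db, snr$blur_radius, snr$boundary, NA_integer_)
  with_seed(seed, {
    scene <- sample_scene(n, optics, position_margin, amplitude_range)
    scene$seed <- as.integer(seed)
    img <- degrade(render_scene(scene), spec)
    new_image_sample(img, n, "M1", spec$snr_db, seed, provenance = scene)
  })
}

#' Generate a Method-2 sample (simulated particles on a background)
#'
#' The zero-mean particle interference term `render - E0^2` is added onto the
#' background image, then the degradation pipeline is applied (by default).
#' With a flat background equal to `E0^2` this reduces exactly to Method 1.
#'
#' @param n particle count.
#' @param background background image, same shape as the rendering grid.
#' @param optics an [optical_params()] object.
#' @param snr a [noise_spec()].
#' @param seed integer seed.
#' @param degrade_output apply blur+noise to the composite (default `TRUE`).
#' @param position_margin,amplitude_range passed to [sample_scene()].
#' @return An `image_sample`.
#' @export
make_sample_m2 <- function(n, background, optics = optical_params(),
                           snr = noise_spec(), seed = 1L,
                           degrade_output = TRUE, position_margin = 4,
                           amplitude_range = c(0.2, 1)) {
  if (!all(dim(background) == optics$image_shape))
    stop_param("background shape must match the rendering grid")
  spec <- noise_spec(snr$snr_db, snr$blur_radius, snr$boundary, NA_integer_)
  with_seed(seed, {
    scene <- sample_scene(n, optics, position_margin, amplitude_range)
    scene$seed <- as.integer(seed)
    img <- background + (render_scene(scene) - optics$background_amplitude^2)
    if (degrade_output) img <- degrade(img, spec)
    new_image_sample(img, n, "M2", spec$snr_db, seed, provenance = scene)
  })
}

#' Build a particle patch library
#'
#' Renders single-particle scenes at high SNR and crops a `patch_side` x
#' `patch_side` window centered on the particle. Each patch is labelled with
#' its particle count (1). This is a synthetic stand-in for a library of
#' particle crops taken from experimental images; real crops can be
#' substituted through the same structure.
#'
#' @param n_patches number of patches (>= 1).
#' @param optics an [optical_params()] object.
#' @param amplitude_range scattering-amplitude range for the patch particles.
#' @param patch_side patch window side in pixels (< the rendering grid side).
#' @param seed integer seed.
#' @param snr_db SNR of the rendered patches (default 30 dB, i.e. high SNR).
#' @param blur_radius blur radius applied before cropping.
#' @return An object of class `patch_library` with elements `patches` (list of
#'   matrices), `labels` (integer counts) and `config`.
#' @export
build_patch_library <- function(n_patches, optics = optical_params(),
                                amplitude_range = c(0.2, 1), patch_side = 25L,
                                seed = 1L, snr_db = 30, blur_radius = 1) {
  if (n_patches < 1) stop_param("n_patches must be >= 1")
  patch_side <- as.integer(patch_side)
  if (patch_side >= min(optics$image_shape))
    stop_param("patch_side must be smaller than the rendering grid")
  lo <- (patch_side - 1L) %/% 2L
  hi <- patch_side - 1L - lo
  nr <- optics$image_shape[1]; nc <- optics$image_shape[2]
  spec <- noise_spec(snr_db, blur_radius, seed = NA_integer_)
  with_seed(seed, {
    patches <- vector("list", n_patches)
    for (i in seq_len(n_patches)) {
      pr <- sample(lo:(nr - 1L - hi), 1)      # particle pixel (row, col)
      pc <- sample(lo:(nc - 1L - hi), 1)
      particle <- particle_spec(
        x = (pc + stats::runif(1, -0.5, 0.5)) * optics$pixel_pitch,
        y = (pr + stats::runif(1, -0.5, 0.5)) * optics$pixel_pitch,
        amplitude = stats::runif(1, amplitude_range[1], amplitude_range[2]),
        phase = stats::runif(1, 0, 2 * pi))
      img <- degrade(render_scene(spm_scene(optics, particle)), spec)
      patches[[i]] <- img[(pr - lo):(pr + hi) + 1L, (pc - lo):(pc + hi) + 1L]
    }
    structure(list(patches = patches, labels = rep(1L, n_patches),
                   config = list(patch_side = patch_side, snr_db = snr_db,
                                 blur_radius = blur_radius,
                                 amplitude_range = amplitude_range,
                                 seed = as.integer(seed))),
              class = "patch_library")
  })
}

#' @export
print.patch_library <- function(x, ...) {
  cat(sprintf("SPM patch library: %d patch(es) of %d x %d px (counts: %s)\n",
              length(x$patches), x$config$patch_side, x$config$patch_side,
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

# Mean over the 1-pixel border frame of a patch.
patch_border_mean <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  mean(c(patch[1, ], patch[nr, ],
         patch[2:(nr - 1), 1], patch[2:(nr - 1), nc]))
}

#' Generate a Method-3 sample (patch compositing)
#'
#' Selects patches whose labels sum to `n` and pastes each onto the background
#' at a uniform-random position by adding `patch - border_mean(patch)` into
#' the target window; overlapping pastes accumulate additively.
#'
#' @param n target particle count.
#' @param library a [build_patch_library()] result (non-empty).
#' @param background background image.
#' @param seed integer seed.
#' @param degrade_spec optional [noise_spec()] applied to the composite;
#'   `NULL` (default) leaves the composite as pasted, since the patches carry
#'   their own noise.
#' @return An `image_sample`.
#' @export
make_sample_m3 <- function(n, library, background, seed = 1L,
                           degrade_spec = NULL) {
  stopifnot(inherits(library, "patch_library"), length(library$patches) >= 1)
  w <- library$config$patch_side
  nr <- nrow(background); nc <- ncol(background)
  if (w > min(nr, nc)) stop_param("patches larger than the background")
  with_seed(seed, {
    img <- background
    remaining <- as.integer(n)
    used <- integer(0); at <- NULL
    while (remaining > 0) {
      ok <- which(library$labels <= remaining)
      if (!length(ok)) stop_param("no patch combination sums to n")
      j <- ok[sample.int(length(ok), 1)]
      r0 <- sample.int(nr - w + 1L, 1)
      c0 <- sample.int(nc - w + 1L, 1)
      p <- library$patches[[j]]
      img[r0:(r0 + w - 1L), c0:(c0 + w - 1L)] <-
        img[r0:(r0 + w - 1L), c0:(c0 + w - 1L)] + (p - patch_border_mean(p))
      remaining <- remaining - library$labels[j]
      used <- c(used, j); at <- rbind(at, c(r0, c0))
    }
    if (!is.null(degrade_spec)) img <- degrade(img, degrade_spec)
    new_image_sample(img, n, "M3",
                     if (is.null(degrade_spec)) NA_real_ else degrade_spec$snr_db,
                     seed, provenance = list(patches = used, positions = at))
  })
}

## ---- hybrid dataset ---------------------------------------------------------

#' Hybrid dataset configuration
#'
#' Defaults follow the study design: per class, Method 1 contributes 1000
#' images under each of seven noise conditions (no noise, 30, 25, 20, 15, 8,
#' 1 dB) = 7000 images; Method 2 contributes 1000 (noise conditions cycled
#' over the same grid); Method 3 contributes 100; 8100 images per class for
#' the 11 classes. The "others" class draws its particle count uniformly from
#' `others_range`.
#'
#' @param classes class labels (0-9 plus the "others" class 10).
#' @param m1_per_noise Method-1 images per (class, noise) cell.
#' @param noise_grid SNR conditions in dB ([NOISE_FREE] for no noise).
#' @param m2_count,m3_count Method-2/3 images per class.
#' @param degrade_m2 apply blur+noise to Method-2 composites.
#' @param degrade_m3 apply blur+noise to Method-3 composites (default off:
#'   the patches already carry noise).
#' @param others_range integer range the "others" class count is drawn from.
#' @param n_backgrounds size of the synthetic background library.
#' @param background a [background_spec()] template (its seed is replaced by
#'   per-background seeds).
#' @param patch_library_size,patch_side patch library parameters.
#' @param optics an [optical_params()] object (simulation grid).
#' @param blur_radius disk blur radius, pixels.
#' @param position_margin,amplitude_range scene sampling parameters.
#' @param master_seed master seed; the whole dataset is a pure function of
#'   the configuration including this seed.
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(classes = 0:10, m1_per_noise = 1000,
                          noise_grid = c(NOISE_FREE, 30, 25, 20, 15, 8, 1),
                          m2_count = 1000, m3_count = 100,
                          degrade_m2 = TRUE, degrade_m3 = FALSE,
                          others_range = 10:14, n_backgrounds = 300,
                          background = background_spec(),
                          patch_library_size = 200, patch_side = 25L,
                          optics = optical_params(), blur_radius = 1,
                          position_margin = 4, amplitude_range = c(0.2, 1),
                          master_seed = 1L) {
  if (m1_per_noise < 0 || m2_count < 0 || m3_count < 0)
    stop_param("counts must be >= 0")
  structure(list(classes = as.integer(classes), m1_per_noise = m1_per_noise,
                 noise_grid = noise_grid, m2_count = m2_count,
                 m3_count = m3_count, degrade_m2 = degrade_m2,
                 degrade_m3 = degrade_m3, others_range = as.integer(others_range),
                 n_backgrounds = n_backgrounds, background = background,
                 patch_library_size = patch_library_size,
                 patch_side = as.integer(patch_side), optics = optics,
                 blur_radius = blur_radius, position_margin = position_margin,
                 amplitude_range = amplitude_range,
                 master_seed = as.integer(master_seed),
                 degradation_order = "blur_then_noise",
                 snr_signal_power = "variance_of_clean_image"),
            class = "hybrid_config")
}

#' Build the hybrid dataset manifest
#'
#' Lays out every record of the hybrid dataset — per-class Method-1 cells over
#' the noise grid, Method-2 and Method-3 counts — with one reproducibility
#' seed per record, background assignments, relative output paths, and the
#' configuration hash. Rendering happens on demand ([render_record()],
#' [write_images()]); the manifest itself is a pure function of the
#' configuration, so two builds with the same master seed are identical.
#'
#' @param config a [hybrid_config()].
#' @return An object of class `spm_manifest` (a data frame with one row per
#'   image and attributes `config`, `config_hash`, `bg_seeds`, `patch_seed`).
#' @export
build_hybrid_dataset <- function(config = hybrid_config()) {
  stopifnot(inherits(config, "hybrid_config"))
  per_class <- config$m1_per_noise * length(config$noise_grid) +
    config$m2_count + config$m3_count
  n_total <- per_class * length(config$classes)
  seeds <- derive_seeds(config$master_seed,
                        n_total + config$n_backgrounds + 2L)
  bg_seeds <- seeds[n_total + seq_len(config$n_backgrounds)]
  patch_seed <- seeds[n_total + config$n_backgrounds + 1L]
  others_seed <- seeds[n_total + config$n_backgrounds + 2L]

  rows <- vector("list", length(config$classes))
  offset <- 0L
  for (ci in seq_along(config$classes)) {
    cls <- config$classes[ci]
    method <- c(rep("M1", config$m1_per_noise * length(config$noise_grid)),
                rep("M2", config$m2_count), rep("M3", config$m3_count))
    snr_m3 <- if (config$m3_count == 0) numeric(0)
              else if (config$degrade_m3)
                rep_len(config$noise_grid, config$m3_count)
              else rep(NA_real_, config$m3_count)
    snr <- c(rep(config$noise_grid, each = config$m1_per_noise),
             rep_len(config$noise_grid, config$m2_count), snr_m3)
    k <- length(method)
    bg <- rep(NA_integer_, k)
    needs_bg <- method != "M1"
    rows[[ci]] <- data.frame(
      id = offset + seq_len(k),
      path = sprintf("class_%02d/%s_%05d.png", cls, tolower(method), seq_len(k)),
      label = cls, n_particles = cls, method = method, snr_db = snr,
      bg = bg, seed = seeds[offset + seq_len(k)],
      split = NA_character_, stringsAsFactors = FALSE)
    offset <- offset + k
  }
  manifest <- do.call(rbind, rows)

  with_seed(others_seed, {
    needs_bg <- manifest$method != "M1"
    manifest$bg[needs_bg] <- sample.int(config$n_backgrounds,
                                        sum(needs_bg), replace = TRUE)
    oth <- manifest$label == 10L
    if (any(oth))
      manifest$n_particles[oth] <- sample(config$others_range, sum(oth),
                                          replace = TRUE)
  })
  manifest$label <- label_for_count(manifest$n_particles)

  structure(manifest, config = config, config_hash = object_hash(config),
            bg_seeds = bg_seeds, patch_seed = patch_seed,
            class = c("spm_manifest", "data.frame"))
}

#' @export
print.spm_manifest <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("SPM dataset manifest: %d records, %d classes (config %s)\n",
              nrow(x), length(unique(x$label)),
              substr(attr(x, "config_hash"), 1, 8)))
  print(table(label = x$label, method = x$method))
  if (!all(is.na(x$split))) print(table(split = x$split))
  invisible(x)
}

#' Patch library declared by a manifest's configuration
#'
#' @param manifest an [build_hybrid_dataset()] manifest.
#' @return The [build_patch_library()] result its Method-3 records use.
#' @export
manifest_patch_library <- function(manifest) {
  cfg <- attr(manifest, "config")
  build_patch_library(cfg$patch_library_size, cfg$optics, cfg$amplitude_range,
                      cfg$patch_side, seed = attr(manifest, "patch_seed"),
                      blur_radius = cfg$blur_radius)
}

manifest_background <- function(manifest, i) {
  cfg <- attr(manifest, "config")
  bs <- cfg$background
  bs$seed <- attr(manifest, "bg_seeds")[manifest$bg[i]]
  gen_background(bs, cfg$optics$image_shape)
}

#' Render one manifest record
#'
#' Re-creates the image of record `i` bit-identically from its seed and the
#' manifest configuration.
#'
#' @param manifest an `spm_manifest`.
#' @param i record index.
#' @param patch_library optional pre-built patch library (otherwise built on
#'   demand for Method-3 records).
#' @return An `image_sample`.
#' @export
render_record <- function(manifest, i, patch_library = NULL) {
  cfg <- attr(manifest, "config")
  rec <- manifest[i, ]
  spec <- noise_spec(if (is.na(rec$snr_db)) NOISE_FREE else rec$snr_db,
                     cfg$blur_radius)
  switch(rec$method,
    M1 = make_sample_m1(rec$n_particles, spec, cfg$optics, rec$seed,
                        cfg$position_margin, cfg$amplitude_range),
    M2 = make_sample_m2(rec$n_particles, manifest_background(manifest, i),
                        cfg$optics, spec, rec$seed, cfg$degrade_m2,
                        cfg$position_margin, cfg$amplitude_range),
    M3 = {
      if (is.null(patch_library)) patch_library <- manifest_patch_library(manifest)
      make_sample_m3(rec$n_particles, patch_library,
                     manifest_background(manifest, i), rec$seed,
                     degrade_spec = if (cfg$degrade_m3) spec else NULL)
    },
    stop_param("unknown method: ", rec$method))
}

#' Assign stratified train/validation/test splits
#'
#' Per-class stratified random split at the given ratio; validation and test
#' sizes are floored, the remainder goes to the training split.
#'
#' @param manifest an `spm_manifest`.
#' @param ratio length-3 positive weights for train/val/test (default 8:1:1).
#' @param seed integer seed for the per-class permutations.
#' @return The manifest with its `split` column filled.
#' @export
split_manifest <- function(manifest, ratio = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratio) == 3, all(ratio > 0))
  counts <- table(manifest$label)
  if (any(counts < 10)) stop_param("every class needs at least 10 records to split")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (cls in sort(unique(manifest$label))) {
      idx <- which(manifest$label == cls)
      n <- length(idx)
      nval <- floor(n * ratio[2] / sum(ratio))
      ntest <- floor(n * ratio[3] / sum(ratio))
      perm <- sample(idx)
      manifest$split[perm[seq_len(nval)]] <- "val"
      manifest$split[perm[nval + seq_len(ntest)]] <- "test"
      manifest$split[perm[(nval + ntest + 1):n]] <- "train"
    }
  })
  manifest
}

## ---- image write-out --------------------------------------------------------

#' Quantize an intensity image to 8 bits
#'
#' Per-image min-max normalization to \[0, 255\] and rounding; a constant
#' image maps to mid-gray 128.
#'
#' @param image numeric matrix.
#' @return An integer-valued matrix in \[0, 255\].
#' @export
quantize_image <- function(image) {
  rng <- range(image)
  # images constant up to numerical ripple (e.g. FFT round-off after blurring
  # a blank scene) are treated as constant
  if (rng[2] - rng[1] <= 1e-9 * max(1, abs(rng[2])))
    return(matrix(128, nrow(image), ncol(image)))
  round(255 * (image - rng[1]) / (rng[2] - rng[1]))
}

resize_image <- function(image, size) {
  if (all(dim(image) == size)) return(image)
  out <- EBImage::resize(image, w = size, h = size)
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}

#' Write a dataset to disk
#'
#' Renders every record, resizes to `size` x `size` (bilinear), applies
#' per-image min-max quantization to 8 bits (so the written image spans the
#' full \[0, 255\] range), replicates the grayscale channel to 3 channels,
#' and writes PNG files plus a CSV manifest and a JSON configuration sidecar.
#'
#' @param manifest an `spm_manifest`.
#' @param out_dir output directory (created if missing).
#' @param size output image side in pixels (default 224).
#' @param verbose print progress.
#' @return Invisibly, the manifest CSV path.
#' @export
write_images <- function(manifest, out_dir, size = 224L, verbose = FALSE) {
  cfg <- attr(manifest, "config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- if (any(manifest$method == "M3")) manifest_patch_library(manifest)
  for (d in unique(dirname(manifest$path)))
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    s <- render_record(manifest, i, patch_library = lib)
    q <- quantize_image(resize_image(s$image, size))
    arr <- array(q / 255, dim = c(nrow(q), ncol(q), 3))
    png::writePNG(arr, file.path(out_dir, manifest$path[i]))
    if (verbose && i %% 500 == 0)
      message(sprintf("  wrote %d / %d images", i, nrow(manifest)))
  }
  csv <- file.path(out_dir, "manifest.csv")
  write.csv(manifest[, c("path", "n_particles", "label", "method", "snr_db",
                         "seed", "split")], csv, row.names = FALSE)
  sidecar <- list(config_hash = attr(manifest, "config_hash"),
                  master_seed = cfg$master_seed,
                  degradation_order = cfg$degradation_order,
                  snr_signal_power = cfg$snr_signal_power,
                  normalization = "per_image_min_max_8bit",
                  image_size = size,
                  noise_grid = cfg$noise_grid,
                  classes = cfg$classes,
                  others_range = cfg$others_range)
  jsonlite::write_json(sidecar, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(csv)
}

#' Render manifest records into an in-memory image array
#'
#' Convenience loader used by training and evaluation: renders (or re-renders)
#' records, quantizes each image to 8 bits, optionally resizes, and stacks
#' them into an (H, W, 1, N) array.
#'
#' @param manifest an `spm_manifest`.
#' @param split optional split name to subset on.
#' @param size optional output side length (defaults to the rendering grid).
#' @param verbose print progress.
#' @return A list with `x` (array), `labels` (integer vector) and `index`
#'   (row indices into the manifest).
#' @export
load_manifest_images <- function(manifest, split = NULL, size = NULL,
                                 verbose = FALSE) {
  idx <- if (is.null(split)) seq_len(nrow(manifest))
         else which(manifest$split == split)
  if (!length(idx)) stop_param("no records in split '", split, "'")
  cfg <- attr(manifest, "config")
  side <- if (is.null(size)) cfg$optics$image_shape else c(size, size)
  lib <- if (any(manifest$method[idx] == "M3")) manifest_patch_library(manifest)
  x <- array(0, dim = c(side[1], side[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    s <- render_record(manifest, idx[j], patch_library = lib)
    img <- if (is.null(size)) s$image else resize_image(s$image, size)
    x[, , 1L, j] <- quantize_image(img)
    if (verbose && j %% 500 == 0)
      message(sprintf("  rendered %d / %d images", j, length(idx)))
  }
  list(x = x, labels = manifest$label[idx], index = idx)
}
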