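# Shared fixtures. The desk-scale trained classifier is expensive (several
# minutes), so it is trained once per test session and memoized together with
# its held-out test data.

.fixture_cache <- new.env(parent = emptyenv())

small_optics <- function(shape = c(32L, 32L)) {
  optical_params(image_shape = shape)
}

# Reduced simulated-dataset study: 500 images/class (Method 1 only) across
# the seven-condition mixed-noise grid, 8:1:1 split, desk-profile training.
desk_study_config <- function() {
  hybrid_config(m1_per_noise = 72, m2_count = 0, m3_count = 0,
                n_backgrounds = 1, patch_library_size = 1, master_seed = 101)
}

trained_desk_fixture <- function() {
  if (!is.null(.fixture_cache$desk)) return(.fixture_cache$desk)
  man <- split_manifest(build_hybrid_dataset(desk_study_config()), seed = 102)
  tr <- load_manifest_images(man, "train")
  va <- load_manifest_images(man, "val")
  te <- load_manifest_images(man, "test")
  model <- build_model(arch_profile("desk"), seed = 103)
  model <- spm_train(model, list(x = tr$x, labels = tr$labels, xval = va$x,
                                 val_labels = va$labels),
                     epochs = 10, seed = 104)
  .fixture_cache$desk <- list(model = model, test = te, manifest = man)
  .fixture_cache$desk
}

# Small labelled Method-1 image stack for quick classifier tests.
make_m1_stack <- function(counts, snr_db = 30, seed = 301,
                          optics = optical_params()) {
  seeds <- spmcount:::derive_seeds(seed, length(counts))
  x <- array(0, c(optics$image_shape, 1L, length(counts)))
  lab <- integer(length(counts))
  for (i in seq_along(counts)) {
    s <- make_sample_m1(counts[i], noise_spec(snr_db, 1), optics, seeds[i])
    x[, , 1L, i] <- quantize_image(s$image)
    lab[i] <- s$label
  }
  list(x = x, labels = lab)
}
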