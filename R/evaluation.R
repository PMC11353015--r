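# Evaluation surfaces: row-normalized confusion matrices, per-class accuracy
# curves across noise conditions, a non-learned peak-counting baseline, and
# seeded bootstrap comparisons between counters.

#' Row-normalized confusion matrix
#'
#' Counts (true class x predicted class) and normalizes each row by its
#' support; rows with zero support are left as zero and flagged.
#'
#' @param true_labels,predicted_labels equal-length integer vectors with
#'   values in `0:(n_classes-1)`.
#' @param n_classes number of classes (default 11).
#' @return An object of class `spm_confusion`: list with `matrix` (row
#'   normalized), `counts`, `support` and `empty_rows`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes = 11L) {
  if (length(true_labels) != length(predicted_labels))
    stop_param("label vectors must have equal length")
  lv <- 0:(n_classes - 1)
  if (any(!true_labels %in% lv) || any(!predicted_labels %in% lv))
    stop_param("labels must lie in 0..", n_classes - 1)
  counts <- table(factor(true_labels, levels = lv),
                  factor(predicted_labels, levels = lv))
  counts <- matrix(as.numeric(counts), n_classes, n_classes,
                   dimnames = list(true = lv, predicted = lv))
  support <- rowSums(counts)
  m <- counts
  nz <- support > 0
  m[nz, ] <- m[nz, ] / support[nz]
  structure(list(matrix = m, counts = counts, support = support,
                 empty_rows = lv[!nz]),
            class = "spm_confusion")
}

#' @export
print.spm_confusion <- function(x, digits = 3, ...) {
  cat("Row-normalized confusion matrix (true x predicted):\n")
  print(round(x$matrix, digits))
  cat("support:", x$support, "\n")
  if (length(x$empty_rows))
    cat("rows with zero support:", x$empty_rows, "\n")
  invisible(x)
}

#' @export
plot.spm_confusion <- function(x, main = "Confusion matrix", ...) {
  k <- nrow(x$matrix)
  graphics::image(0:(k), 0:(k), t(x$matrix[k:1, ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = main, ...)
  graphics::axis(1, at = seq_len(k) - 0.5, labels = colnames(x$matrix))
  graphics::axis(2, at = seq_len(k) - 0.5, labels = rev(rownames(x$matrix)))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (x$matrix[i, j] > 0.005)
      graphics::text(j - 0.5, k - i + 0.5, sprintf("%.2f", x$matrix[i, j]),
                     cex = 0.6,
                     col = if (x$matrix[i, j] > 0.5) "white" else "black")
  invisible(x)
}

#' Per-class accuracy (confusion-matrix diagonal)
#'
#' @param cm an [confusion_matrix()] result.
#' @return Named numeric vector of per-class accuracies with a `support`
#'   attribute.
#' @export
accuracy_by_class <- function(cm) {
  stopifnot(inherits(cm, "spm_confusion"))
  acc <- diag(cm$matrix)
  names(acc) <- rownames(cm$matrix)
  attr(acc, "support") <- cm$support
  acc
}

#' Accuracy-versus-count curves across noise conditions
#'
#' Generates fresh Method-1 test images for every (class, noise) cell,
#' predicts with the model, and returns one per-class accuracy curve per
#' condition plus the mixed-condition curve (all cells pooled).
#'
#' @param model a trained `spm_cnn`.
#' @param optics an [optical_params()] object.
#' @param noise_grid SNR conditions in dB ([NOISE_FREE] for no noise).
#' @param n_per_cell images generated per (class, condition) cell.
#' @param seed integer seed (the test set is reproducible).
#' @param classes class labels to evaluate (default 0-10; class 10 draws its
#'   count from `others_range`).
#' @param others_range count range for the "others" class.
#' @param blur_radius,position_margin,amplitude_range generation parameters.
#' @return An object of class `spm_noise_sweep`: per-condition curves, the
#'   mixed curve, per-condition confusion matrices, and the raw labels.
#' @export
noise_sweep <- function(model, optics = optical_params(),
                        noise_grid = c(NOISE_FREE, 30, 25, 20, 15, 8, 1),
                        n_per_cell = 100L, seed = 1L, classes = 0:10,
                        others_range = 10:14, blur_radius = 1,
                        position_margin = 4, amplitude_range = c(0.2, 1)) {
  stopifnot(inherits(model, "spm_cnn"))
  cond_name <- function(s) if (is.finite(s)) sprintf("%gdB", s) else "noise-free"
  n_cells <- length(noise_grid) * length(classes)
  seeds <- derive_seeds(seed, n_cells * n_per_cell + 1L)
  counts_seed <- seeds[n_cells * n_per_cell + 1L]
  curves <- list(); cms <- list()
  all_true <- integer(0); all_pred <- integer(0); all_cond <- character(0)
  si <- 0L
  for (g in seq_along(noise_grid)) {
    spec <- noise_spec(noise_grid[g], blur_radius)
    stack <- vector("list", length(classes) * n_per_cell)
    labs <- integer(length(stack)); k <- 0L
    for (cls in classes) {
      ns <- if (cls == 10L)
        with_seed(counts_seed + g * 1000L + cls,
                  sample(others_range, n_per_cell, replace = TRUE))
      else rep(cls, n_per_cell)
      for (j in seq_len(n_per_cell)) {
        si <- si + 1L; k <- k + 1L
        s <- make_sample_m1(ns[j], spec, optics, seeds[si], position_margin,
                            amplitude_range)
        stack[[k]] <- quantize_image(s$image)
        labs[k] <- s$label
      }
    }
    x <- array(unlist(stack), c(optics$image_shape, 1L, k))
    pred <- predict(model, x, type = "class")
    cm <- confusion_matrix(labs, pred, model$profile$n_classes)
    nm <- cond_name(noise_grid[g])
    curves[[nm]] <- accuracy_by_class(cm)
    cms[[nm]] <- cm
    all_true <- c(all_true, labs); all_pred <- c(all_pred, pred)
    all_cond <- c(all_cond, rep(nm, k))
  }
  mixed_cm <- confusion_matrix(all_true, all_pred, model$profile$n_classes)
  structure(list(curves = curves, mixed = accuracy_by_class(mixed_cm),
                 confusion = cms, mixed_confusion = mixed_cm,
                 labels = data.frame(true = all_true, predicted = all_pred,
                                     condition = all_cond),
                 n_per_cell = n_per_cell, seed = seed),
            class = "spm_noise_sweep")
}

#' @export
print.spm_noise_sweep <- function(x, ...) {
  cat(sprintf("Accuracy-vs-count sweep (%d images per cell):\n", x$n_per_cell))
  tab <- rbind(do.call(rbind, lapply(x$curves, as.vector)),
               mixed = as.vector(x$mixed))
  colnames(tab) <- names(x$mixed)
  print(round(tab, 3))
  invisible(x)
}

#' @export
plot.spm_noise_sweep <- function(x, ...) {
  k <- length(x$mixed)
  cols <- grDevices::hcl.colors(length(x$curves) + 1, "Dark 3")
  plot(NULL, xlim = c(0, k - 1), ylim = c(0, 1), xlab = "particle count class",
       ylab = "accuracy", main = "Accuracy vs particle number", ...)
  for (i in seq_along(x$curves))
    graphics::lines(0:(k - 1), x$curves[[i]], col = cols[i], type = "b", pch = 16)
  graphics::lines(0:(k - 1), x$mixed, col = cols[length(cols)], type = "b",
                  pch = 17, lwd = 2)
  graphics::legend("bottomleft", c(names(x$curves), "mixed"), col = cols,
                   lty = 1, pch = c(rep(16, length(x$curves)), 17), cex = 0.7)
  invisible(x)
}

#' Non-learned peak-counting baseline
#'
#' Simplified stand-in for reconstruction-based counting: smooths the image
#' with a disk kernel, subtracts the median, thresholds at `k` median
#' absolute deviations, and counts local extrema with a minimum separation
#' radius (greedy non-maximum suppression in decreasing order of strength).
#' With uniformly random scattering phases particles can appear as intensity
#' peaks or dips, so the default detection image is the absolute deviation
#' from the median (`polarity = "abs"`); `polarity = "bright"` detects
#' positive deviations only.
#'
#' @param image 2-D intensity image.
#' @param kernel_radius disk smoothing radius, pixels.
#' @param k threshold in median absolute deviations above the median.
#' @param min_separation minimum distance between accepted peaks, pixels.
#' @param polarity `"abs"` or `"bright"`.
#' @return Integer particle count.
#' @export
peak_count_baseline <- function(image, kernel_radius = 2, k = 6,
                                min_separation = 5, polarity = c("abs", "bright")) {
  polarity <- match.arg(polarity)
  sm <- if (kernel_radius > 0) blur(image, disk_kernel(kernel_radius)) else image
  med <- stats::median(sm)
  dev <- sm - med
  det <- if (polarity == "abs") abs(dev) else dev
  s <- stats::mad(as.vector(sm))
  if (s == 0) return(0L)
  cand <- which(det > k * s, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  ord <- order(det[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    # local maximum of the detection image in its 8-neighbourhood
    rr <- max(1, p[1] - 1):min(nrow(det), p[1] + 1)
    cc <- max(1, p[2] - 1):min(ncol(det), p[2] + 1)
    if (det[p[1], p[2]] < max(det[rr, cc])) next
    if (nrow(kept) &&
        any((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 < min_separation^2))
      next
    kept <- rbind(kept, p)
  }
  nrow(kept)
}

#' Bootstrap comparison of two counters
#'
#' Paired bootstrap over test images of the accuracy difference between two
#' label vectors against the truth.
#'
#' @param truth true labels.
#' @param pred_a,pred_b predicted labels of the two methods.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return List with the observed accuracies, the accuracy difference
#'   (a minus b), and its bootstrap quantiles (2.5, 5, 50, 95, 97.5 percent).
#' @export
bootstrap_accuracy_diff <- function(truth, pred_a, pred_b, n_boot = 500L,
                                    seed = 1L) {
  n <- length(truth)
  stopifnot(length(pred_a) == n, length(pred_b) == n)
  hit_a <- pred_a == truth
  hit_b <- pred_b == truth
  diffs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    mean(hit_a[idx]) - mean(hit_b[idx])
  }, numeric(1)))
  list(accuracy_a = mean(hit_a), accuracy_b = mean(hit_b),
       diff = mean(hit_a) - mean(hit_b),
       quantiles = stats::quantile(diffs, c(0.025, 0.05, 0.5, 0.95, 0.975)),
       n = n, n_boot = n_boot)
}
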