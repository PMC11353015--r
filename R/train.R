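# Model fitting and inference. `spm_train()` is the fitting front end: it
# takes an untrained model and either a split manifest or in-memory arrays,
# minimizes multi-class cross-entropy with Adam under a cosine learning-rate
# schedule, logs per-epoch train loss and validation accuracy, and returns
# the checkpoint with the best validation accuracy as a classed object with
# print/summary/predict/plot methods.

# Conform images to a profile's input: channel handling (replicated grayscale
# <-> single channel), optional resize, then per-image standardization to
# zero mean / unit variance (constant images map to all zeros).
images_to_input <- function(images, profile) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L, 1L))
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (d[3] != profile$input_channels) {
    if (d[3] == 3L && profile$input_channels == 1L) {
      images <- images[, , 1L, , drop = FALSE]   # replicated grayscale
    } else if (d[3] == 1L && profile$input_channels == 3L) {
      images <- images[, , c(1L, 1L, 1L), , drop = FALSE]
    } else stop_param("cannot conform ", d[3], " channels to profile input")
    d <- dim(images)
  }
  if (d[1] != profile$input_size || d[2] != profile$input_size) {
    out <- array(0, c(profile$input_size, profile$input_size, d[3], d[4]))
    for (n in seq_len(d[4]))
      for (c in seq_len(d[3]))
        out[, , c, n] <- resize_image(images[, , c, n], profile$input_size)
    images <- out
    d <- dim(images)
  }
  hw <- d[1] * d[2] * d[3]
  m <- matrix(images, hw, d[4])
  mu <- .colMeans(m, hw, d[4])
  sdv <- sqrt(pmax(.colMeans(m * m, hw, d[4]) - mu^2, 0))
  sdv[sdv == 0] <- 1
  m <- (m - rep(mu, each = hw)) / rep(sdv, each = hw)
  array(m, d)
}

model_forward <- function(model, x, training = FALSE) {
  nn_forward_layers(model$layers, x, training)
}

#' Train a particle-count classifier
#'
#' @param model an untrained (or previously trained) [build_model()] object.
#' @param data either a split [spm_manifest][build_hybrid_dataset()] (its
#'   `train` and `val` records are rendered), or a list with elements `x`
#'   (H, W, C, N array), `labels` (integer classes), and optionally `xval`,
#'   `val_labels`.
#' @param epochs number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param lr base Adam learning rate (cosine-decayed over epochs).
#' @param seed integer seed for shuffling (initialization is seeded by
#'   [build_model()]).
#' @param verbose print per-epoch progress.
#' @return The trained `spm_cnn`: parameters from the epoch with the best
#'   validation accuracy, and a per-epoch `log` data frame (train loss,
#'   validation accuracy).
#' @export
spm_train <- function(model, data, epochs = 12L, batch_size = 64L, lr = 1e-3,
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "spm_cnn"), epochs >= 1, lr > 0)
  if (inherits(data, "spm_manifest")) {
    if (!any(data$split == "train", na.rm = TRUE))
      stop_param("manifest has no train split; call split_manifest() first")
    size <- if (attr(data, "config")$optics$image_shape[1] ==
                model$profile$input_size) NULL else model$profile$input_size
    tr <- load_manifest_images(data, "train", size = size)
    va <- if (any(data$split == "val", na.rm = TRUE))
      load_manifest_images(data, "val", size = size)
    data <- list(x = tr$x, labels = tr$labels,
                 xval = if (!is.null(va)) va$x,
                 val_labels = if (!is.null(va)) va$labels)
  }
  if (length(data$labels) == 0) stop_param("empty training split")
  x <- images_to_input(data$x, model$profile)
  y <- as.integer(data$labels)
  has_val <- !is.null(data$xval) && length(data$val_labels) > 0
  if (has_val) {
    xval <- images_to_input(data$xval, model$profile)
    yval <- as.integer(data$val_labels)
  }
  n <- dim(x)[4]
  layers <- model$layers
  state <- adam_init_layers(layers)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  best <- list(acc = -Inf, layers = layers)
  t_global <- 0L
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      lr_e <- lr * 0.5 * (1 + cos(pi * (e - 1) / epochs))
      perm <- sample.int(n)
      losses <- numeric(0)
      for (b in seq_len(ceiling(n / batch_size))) {
        idx <- perm[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- nn_forward_layers(layers, xb, training = TRUE)
        layers <- fw$layers
        sx <- softmax_xent(fw$y, y[idx])
        losses <- c(losses, sx$loss)
        bw <- nn_backward_layers(layers, fw$caches, sx$dlogits)
        t_global <- t_global + 1L
        up <- adam_step_layers(layers, bw$grads, state, lr_e, t_global)
        layers <- up$layers
        state <- up$state
      }
      acc <- if (has_val) {
        tmp <- model; tmp$layers <- layers
        mean(predict_classes_internal(tmp, xval, batch_size) == yval)
      } else NA_real_
      log <- rbind(log, data.frame(epoch = e, loss = mean(losses),
                                   val_accuracy = acc))
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  val acc %s", e, mean(losses),
                        ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
      if (!has_val || acc >= best$acc) {
        best$acc <- if (has_val) acc else e
        best$layers <- layers
      }
    }
  })
  model$layers <- best$layers
  model$trained <- TRUE
  model$log <- log
  model$train_config <- list(epochs = epochs, batch_size = batch_size,
                             lr = lr, seed = as.integer(seed),
                             optimizer = "adam", schedule = "cosine")
  model
}

# Forward on already-conformed input; returns 0-based class labels.
predict_classes_internal <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- integer(n)
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    fw <- nn_forward_layers(model$layers, x[, , , idx, drop = FALSE], FALSE)
    out[idx] <- max.col(t(fw$y), ties.method = "first") - 1L
  }
  out
}

#' Predict particle-count classes or probabilities
#'
#' @param object a trained `spm_cnn`.
#' @param images an (H, W, C, N) array, an (H, W, N) array, or a single image
#'   matrix. Images are conformed to the profile input (channel replication,
#'   bilinear resize, per-image standardization).
#' @param type `"prob"` for an N x K matrix of class probabilities (rows sum
#'   to 1) or `"class"` for 0-based predicted labels (argmax, lowest-index
#'   tie-break).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return A probability matrix or an integer vector.
#' @export
predict.spm_cnn <- function(object, images, type = c("prob", "class"),
                            batch_size = 64L, ...) {
  type <- match.arg(type)
  x <- images_to_input(images, object$profile)
  n <- dim(x)[4]
  probs <- matrix(0, n, object$profile$n_classes,
                  dimnames = list(NULL, object$classes))
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    fw <- nn_forward_layers(object$layers, x[, , , idx, drop = FALSE], FALSE)
    logits <- fw$y
    mx <- apply(logits, 2, max)
    e <- exp(sweep(logits, 2, mx))
    probs[idx, ] <- t(sweep(e, 2, colSums(e), "/"))
  }
  if (type == "prob") probs
  else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.spm_cnn <- function(x, ...) {
  cat(sprintf("SPM particle-count classifier ('%s' profile, %s)\n",
              x$profile$name, if (x$trained) "trained" else "untrained"))
  cat(sprintf("  input %dx%dx%d -> %d classes, %s parameters\n",
              x$profile$input_size, x$profile$input_size,
              x$profile$input_channels, x$profile$n_classes,
              format(count_params(x), big.mark = ",")))
  if (x$trained && !is.null(x$log)) {
    i <- which.max(x$log$val_accuracy)
    if (length(i) && !all(is.na(x$log$val_accuracy)))
      cat(sprintf("  best val accuracy %.3f at epoch %d (of %d)\n",
                  x$log$val_accuracy[i], x$log$epoch[i], max(x$log$epoch)))
  }
  invisible(x)
}

#' @export
summary.spm_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("\nTraining log:\n")
    print(object$log, row.names = FALSE)
  }
  invisible(object$log)
}

#' @export
plot.spm_cnn <- function(x, ...) {
  if (is.null(x$log)) stop_param("model has no training log")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "train loss", main = "Cross-entropy", ...)
  if (!all(is.na(x$log$val_accuracy)))
    plot(x$log$epoch, x$log$val_accuracy, type = "b", pch = 16,
         xlab = "epoch", ylab = "validation accuracy", ylim = c(0, 1),
         main = "Validation accuracy", ...)
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is a self-describing list (profile, parameters, training
#' log, package version) serialized with [saveRDS()].
#'
#' @param model an `spm_cnn`.
#' @param path checkpoint file path.
#' @return `save_model()`: the path, invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "spm_cnn"))
  saveRDS(list(format = "spmcount_checkpoint", version = "1",
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spmcount_checkpoint"))
    stop_param("not an spmcount checkpoint")
  structure(obj$model, class = "spm_cnn")
}
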