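# Classifier architectures. Two profiles share one code path:
#   "b0"   - an EfficientNet-B0-style network: 3x3 stem, seven stages of
#            mobile inverted bottleneck (MBConv) blocks alternating 3x3 and
#            5x5 kernels with squeeze-excitation, a 1x1 head convolution,
#            global average pooling and an 11-way fully connected head
#            (nine stages in total), for 224x224 3-channel input;
#   "desk" - a reduced CNN (three conv/pool blocks and a dense head) for
#            64x64 single-channel input, sized so every experiment runs on a
#            single CPU.

b0_stage_table <- function() {
  # expand ratio, kernel, stride, output channels, repeats (canonical B0)
  data.frame(expand = c(1, 6, 6, 6, 6, 6, 6),
             kernel = c(3, 3, 5, 3, 5, 5, 3),
             stride = c(1, 2, 2, 2, 1, 2, 1),
             out = c(16, 24, 40, 80, 112, 192, 320),
             repeats = c(1, 2, 2, 3, 3, 4, 1))
}

#' Architecture profile
#'
#' @param name `"b0"` (224x224, 3-channel, MBConv stages) or `"desk"`
#'   (64x64, 1-channel, three conv blocks).
#' @param n_classes number of output categories (default 11: counts 0-9 plus
#'   the "others" class).
#' @return An object of class `arch_profile` with the input geometry and, for
#'   `"b0"`, the stage table.
#' @export
arch_profile <- function(name = c("desk", "b0"), n_classes = 11L) {
  name <- match.arg(name)
  p <- list(name = name, n_classes = as.integer(n_classes),
            input_size = if (name == "b0") 224L else 64L,
            input_channels = if (name == "b0") 3L else 1L)
  if (name == "b0") {
    p$stages <- b0_stage_table()
    p$n_stages <- nrow(p$stages) + 2L  # stem + MBConv stages + head
  } else {
    p$n_stages <- 5L                   # 3 conv blocks + flatten/dense head
  }
  structure(p, class = "arch_profile")
}

#' @export
print.arch_profile <- function(x, ...) {
  cat(sprintf("Architecture profile '%s': %dx%dx%d input, %d classes, %d stages\n",
              x$name, x$input_size, x$input_size, x$input_channels,
              x$n_classes, x$n_stages))
  invisible(x)
}

# One MBConv block: optional 1x1 expansion, depthwise conv, squeeze-
# excitation (reduction on the block input channels), 1x1 projection;
# identity skip when stride 1 and channels match.
mbconv_block <- function(cin, cout, expand, kernel, stride, se_ratio = 0.25) {
  mid <- cin * expand
  layers <- list()
  if (expand != 1) {
    layers <- c(layers, list(nn_conv(1, 1, cin, mid, bias = FALSE),
                             nn_bn(mid), nn_act("swish")))
  }
  layers <- c(layers, list(
    nn_conv(kernel, kernel, mid, mid, stride = stride, groups = mid, bias = FALSE),
    nn_bn(mid), nn_act("swish"),
    nn_se(mid, max(1L, as.integer(cin * se_ratio))),
    nn_conv(1, 1, mid, cout, bias = FALSE), nn_bn(cout)))
  nn_block(layers, skip = (stride == 1 && cin == cout))
}

build_b0_layers <- function(n_classes, input_channels = 3L) {
  layers <- list(nn_conv(3, 3, input_channels, 32, stride = 2, bias = FALSE),
                 nn_bn(32), nn_act("swish"))
  st <- b0_stage_table()
  cin <- 32
  for (s in seq_len(nrow(st))) {
    for (r in seq_len(st$repeats[s])) {
      stride <- if (r == 1) st$stride[s] else 1
      layers <- c(layers, list(mbconv_block(cin, st$out[s], st$expand[s],
                                            st$kernel[s], stride)))
      cin <- st$out[s]
    }
  }
  c(layers, list(nn_conv(1, 1, cin, 1280, bias = FALSE), nn_bn(1280),
                 nn_act("swish"), nn_gap(), nn_dense(1280, n_classes)))
}

build_desk_layers <- function(n_classes, input_size = 64L, input_channels = 1L) {
  feat <- (input_size %/% 8L)^2 * 32L
  list(nn_conv(3, 3, input_channels, 8), nn_act("relu"), nn_maxpool(2),
       nn_conv(3, 3, 8, 16), nn_act("relu"), nn_maxpool(2),
       nn_conv(3, 3, 16, 32), nn_act("relu"), nn_maxpool(2),
       nn_flatten(), nn_dense(feat, n_classes))
}

#' Build an (untrained) classifier model
#'
#' Constructs the network for the given profile with deterministic random
#' initialization under `seed`.
#'
#' @param profile an [arch_profile()] (or a profile name).
#' @param seed integer initialization seed.
#' @return An object of class `spm_cnn` (untrained).
#' @export
build_model <- function(profile = arch_profile("desk"), seed = 1L) {
  if (is.character(profile)) profile <- arch_profile(profile)
  stopifnot(inherits(profile, "arch_profile"))
  layers <- with_seed(seed, {
    if (profile$name == "b0")
      build_b0_layers(profile$n_classes, profile$input_channels)
    else
      build_desk_layers(profile$n_classes, profile$input_size,
                        profile$input_channels)
  })
  structure(list(profile = profile, layers = layers,
                 classes = seq_len(profile$n_classes) - 1L,
                 seed = as.integer(seed), trained = FALSE, log = NULL),
            class = "spm_cnn")
}

#' Number of parameters of a model
#'
#' @param model an `spm_cnn`.
#' @param learnable_only count only learnable parameters (exclude batch-norm
#'   running statistics).
#' @return Integer parameter count.
#' @export
count_params <- function(model, learnable_only = TRUE) {
  cnt <- function(layers) sum(vapply(layers, function(l) {
    n <- sum(vapply(l$par, length, integer(1)))
    if (!learnable_only && l$type == "bn")
      n <- n + length(l$buf$mean) + length(l$buf$var)
    if (l$type == "block") n <- n + cnt(l$layers)
    n
  }, numeric(1)))
  cnt(model$layers)
}

# Deterministic checksum of all learnable parameters (initialization /
# seeding contract checks).
param_checksum <- function(model) {
  acc <- function(layers) unlist(lapply(layers, function(l) {
    v <- unlist(l$par, use.names = FALSE)
    if (l$type == "block") v <- c(v, acc(l$layers))
    v
  }))
  object_hash(round(acc(model$layers), 12))
}
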