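# LC-Net-style counting network: the RGB image and its (normalized) leaf
# mask are concatenated into a 4-channel input; each stage applies one
# 1x1 Conv Block with a narrow bottleneck width followed by three 3x3
# Conv Blocks -- three 3x3 convolutions see a 5x5 receptive field (and
# beyond) at far fewer parameters than one wide 5x5 -- then 2x2 max
# pooling; global average pooling and a single linear unit regress the
# leaf count with no output activation.

#' Counting network configuration
#'
#' @param input_size `c(H, W)`; divisible by `2^length(stages)`.
#' @param channels 4 in combined (RGB + mask) mode, 3 in the image-only
#'   ablation mode.
#' @param stages List of `c(bottleneck_width, main_width)` pairs; the 1x1
#'   bottleneck must be narrower than the stage's 3x3 width.
#' @param preset `"desk"` (small CPU-scale network) or `"paper"`
#'   (224 x 224 input, width schedule (24,48),(48,96),(96,192),(192,416),
#'   whose parameter count rounds to 5 million). Explicit arguments
#'   override the preset.
#' @return A `count_config` object.
#' @export
count_config <- function(input_size = NULL, channels = 4L, stages = NULL,
                         preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(input_size)) {
    input_size <- if (preset == "paper") c(224, 224) else c(64, 64)
  }
  if (is.null(stages)) {
    stages <- if (preset == "paper") {
      list(c(24, 48), c(48, 96), c(96, 192), c(192, 416))
    } else {
      list(c(6, 12), c(12, 24), c(24, 48))
    }
  }
  check_range(input_size, "input_size", min = 1, integer = TRUE)
  if (!channels %in% c(3L, 4L)) {
    stop_config("'channels' must be 4 (combined input) or 3 (image only)")
  }
  if (!length(stages)) stop_config("at least one stage is required")
  for (s in stages) {
    if (length(s) != 2L || any(s < 1) || any(s != round(s))) {
      stop_config("each stage must be c(bottleneck, width), positive integers")
    }
    if (s[1] >= s[2]) {
      stop_config("1x1 must have less filter size than the 3x3 width (%d >= %d)",
                  s[1], s[2])
    }
  }
  div <- 2^length(stages)
  if (any(input_size %% div != 0)) {
    stop_config("input_size must be divisible by 2^%d = %d",
                length(stages), div)
  }
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 stages = lapply(stages, as.integer), preset = preset),
            class = "count_config")
}

#' Build the leaf-counting model
#'
#' Every Conv Block is convolution (no bias) -> batch normalization ->
#' ReLU. Stage s is one 1x1 block at the bottleneck width followed by
#' three 3x3 blocks at the main width and a 2x2 max-pool; the head is
#' global average pooling plus a single linear unit (no output
#' activation).
#'
#' @param config A [count_config()].
#' @param init_seed Seed for weight initialization.
#' @return An `lcnet_model` of type `"counter"`.
#' @export
build_lcnet <- function(config = count_config(), init_seed = 1L) {
  stopifnot(inherits(config, "count_config"))
  with_seed(init_seed, {
    layers <- list()
    cin <- config$channels
    for (s in config$stages) {
      p <- s[1]; w <- s[2]
      layers <- c(layers, list(conv_layer(1L, cin, p), bn_layer(p),
                               relu_layer()))
      cin <- p
      for (i in 1:3) {
        layers <- c(layers, list(conv_layer(3L, cin, w), bn_layer(w),
                                 relu_layer()))
        cin <- w
      }
      layers <- c(layers, list(pool_layer()))
    }
    layers <- c(layers, list(gap_layer(), linear_layer(cin, 1L)))
    new_model(layers, config, "counter")
  })
}

#' Smooth L1 (Huber) regression loss
#'
#' Mean over samples of `0.5 d^2` for `|d| < delta` and
#' `delta * (|d| - 0.5 delta)` otherwise, with `d = pred - target`;
#' `delta = 1` gives the standard smooth L1. Continuous and
#' once-differentiable at `|d| = delta`.
#'
#' @param pred,target Numeric vectors of equal length.
#' @param delta Transition point, > 0.
#' @return Non-negative scalar loss.
#' @export
smooth_l1 <- function(pred, target, delta = 1.0) {
  if (length(pred) != length(target)) {
    stop_config("pred and target lengths differ")
  }
  check_number(delta, "delta", min = 1e-12)
  d <- abs(pred - target)
  mean(ifelse(d < delta, 0.5 * d^2, delta * (d - 0.5 * delta)))
}

smooth_l1_grad <- function(pred, target, delta = 1.0) {
  d <- pred - target
  ifelse(abs(d) < delta, d, delta * sign(d)) / length(d)
}

#' Round a raw count prediction to a leaf count
#'
#' Round half away from zero, then clamp below at zero.
#'
#' @param raw Finite numeric vector of raw regression outputs.
#' @return Non-negative integer vector.
#' @export
round_count <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop_config("'raw' must be finite")
  }
  as.integer(pmax(sign(raw) * floor(abs(raw) + 0.5), 0))
}

# Assemble the [H,W,N,C] input batch for the counter: RGB channels plus,
# in combined mode, the normalized mask channel.
counter_input <- function(samples, channels, masks = NULL) {
  x <- stack_batch(lapply(samples, `[[`, "rgb"))
  if (channels == 3L) return(x)
  if (is.null(masks)) masks <- lapply(samples, `[[`, "mask")
  if (any(vapply(masks, is.null, TRUE))) {
    stop_config("combined input needs a mask for every sample")
  }
  m <- stack_batch(lapply(masks, normalize_mask))
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3], 4L))
  out[, , , 1:3] <- x
  out[, , , 4] <- m
  out
}

#' Train the counting model
#'
#' Minimizes the smooth L1 loss between the predicted real-valued count
#' and the integer ground truth with Adam. The mask channel comes either
#' from the ground-truth masks or from a trained segmentation model
#' (`cfg$mask_source`); in both cases masks pass through
#' [normalize_mask()] before concatenation, mirroring inference.
#' Deterministic given `cfg$seed`.
#'
#' @param model A [build_lcnet()] model.
#' @param manifest Manifest with counts (and masks in combined mode).
#' @param root Directory manifest paths are relative to.
#' @param cfg A [train_config()].
#' @param seg_model Trained [build_segnet()] model; required when
#'   `cfg$mask_source == "segmenter"` and the counter takes combined
#'   input.
#' @return List with `model` and `history` (per-epoch train loss,
#'   validation loss, validation absolute DiC and percentage agreement).
#' @export
train_counter <- function(model, manifest, root, cfg = train_config(),
                          seg_model = NULL) {
  stopifnot(inherits(model, "lcnet_counter"), inherits(cfg, "train_config"))
  manifest <- validate_manifest(manifest)
  if (any(is.na(manifest$count))) {
    stop_config("all records need leaf counts for counter training")
  }
  channels <- model$config$channels
  if (channels == 4L && cfg$mask_source == "segmenter" &&
      is.null(seg_model)) {
    stop_config("mask_source 'segmenter' requires a trained seg_model")
  }
  size <- model$config$input_size
  train <- load_samples(manifest, root, "train", target = size)
  val <- load_samples(manifest, root, "val", target = size)
  if (!length(train)) stop_config("train split is empty")
  get_masks <- function(samples) {
    if (channels == 3L) return(NULL)
    if (cfg$mask_source == "ground_truth") {
      masks <- lapply(samples, `[[`, "mask")
      if (any(vapply(masks, is.null, TRUE))) {
        stop_config("mask_source 'ground_truth' but records lack masks")
      }
      masks
    } else {
      predict_mask(seg_model, lapply(samples, `[[`, "rgb"))
    }
  }
  x_tr <- counter_input(train, channels, get_masks(train))
  y_tr <- vapply(train, `[[`, 1, "count")
  x_val <- if (length(val)) counter_input(val, channels, get_masks(val))
  y_val <- if (length(val)) vapply(val, `[[`, 1, "count")
  n <- length(train)
  nn_adam_init(model)
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    lr <- cfg$lr
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        sel <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- x_tr[, , sel, , drop = FALSE]
        yb <- y_tr[sel]
        p <- nn_forward(model, xb, training = TRUE)
        losses <- c(losses, smooth_l1(as.numeric(p), yb, cfg$huber_delta))
        dy <- matrix(smooth_l1_grad(as.numeric(p), yb, cfg$huber_delta),
                     ncol = 1)
        nn_backward(model, dy)
        nn_adam_step(model, lr)
      }
      row <- data.frame(epoch = ep, train_loss = mean(losses),
                        val_loss = NA_real_, val_abs_dic = NA_real_,
                        val_agreement = NA_real_)
      if (length(val)) {
        pv <- as.numeric(nn_infer(model, x_val))
        row$val_loss <- smooth_l1(pv, y_val, cfg$huber_delta)
        rc <- round_count(pv)
        row$val_abs_dic <- abs_dic(rc, y_val)
        row$val_agreement <- percentage_agreement(rc, y_val)
      }
      hist[[ep]] <- row
      if (cfg$verbose) {
        message(sprintf(
          "count epoch %d/%d  train %.4f  val %.4f  agree %.1f%%", ep,
          cfg$epochs, row$train_loss, row$val_loss, row$val_agreement))
      }
      lr <- lr * cfg$lr_decay
    }
  })
  nn_clear_cache(model)
  list(model = model, history = do.call(rbind, hist))
}

#' Predict a raw leaf count
#'
#' @param model A trained [build_lcnet()] model.
#' @param rgb One `H x W x 3` array or a list of them.
#' @param mask Matching probability mask(s); passed through
#'   [normalize_mask()]. Omit for a 3-channel (image-only) model.
#' @return Numeric vector of raw (unrounded, unclamped) predictions in
#'   input order; round with [round_count()].
#' @export
predict_count <- function(model, rgb, mask = NULL) {
  stopifnot(inherits(model, "lcnet_counter"))
  items <- if (!is.list(rgb)) list(rgb) else rgb
  size <- model$config$input_size
  for (x in items) {
    if (length(dim(x)) != 3L || !all(dim(x)[1:2] == size)) {
      stop_config("inputs must be %d x %d x 3", size[1], size[2])
    }
  }
  samples <- lapply(items, function(x) new_image_sample(x))
  masks <- if (!is.null(mask)) {
    if (!is.list(mask)) mask <- list(mask)
    if (length(mask) != length(items)) {
      stop_config("need one mask per image")
    }
    for (m in mask) {
      if (!all(dim(m)[1:2] == size)) {
        stop_config("masks must be %d x %d", size[1], size[2])
      }
    }
    mask
  }
  if (model$config$channels == 4L && is.null(masks)) {
    stop_config("combined-input model needs masks")
  }
  x <- counter_input(samples, model$config$channels, masks)
  out <- as.numeric(nn_infer(model, x))
  nn_clear_cache(model)
  out
}
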