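# SegNet-style encoder-decoder leaf segmentation. The encoder is a stack
# of [n_convs x (3x3 conv -> batch norm -> ReLU)] stages each followed by
# 2x2 max pooling that records its argmax indices; the decoder mirrors the
# stages and upsamples by placing values back at the recorded indices
# (index unpooling), which is what distinguishes this family from
# deconvolution-based decoders. A final 1x1 convolution and sigmoid yield
# a per-pixel leaf probability.

#' Segmentation network configuration
#'
#' @param input_size `c(H, W)` input size; both must be divisible by
#'   `2^length(stages)`.
#' @param stages List of `c(n_convs, width)` encoder stage specs, mirrored
#'   in the decoder.
#' @param preset `"desk"` (small network for CPU-scale experiments) or
#'   `"paper"` (VGG-style stage schedule: 2,2,3,3,3 convolutions with
#'   widths 64,128,256,512,512 at 224 x 224). Explicit `input_size`/`stages`
#'   override the preset.
#' @return A `seg_config` object.
#' @export
seg_config <- function(input_size = NULL, stages = NULL,
                       preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(input_size)) {
    input_size <- if (preset == "paper") c(224, 224) else c(64, 64)
  }
  if (is.null(stages)) {
    stages <- if (preset == "paper") {
      list(c(2, 64), c(2, 128), c(3, 256), c(3, 512), c(3, 512))
    } else {
      list(c(2, 16), c(2, 32))
    }
  }
  check_range(input_size, "input_size", min = 1, integer = TRUE)
  if (!length(stages)) stop_config("at least one stage is required")
  for (s in stages) {
    if (length(s) != 2L || any(s < 1) || any(s != round(s))) {
      stop_config("each stage must be c(n_convs, width) with positive integers")
    }
  }
  div <- 2^length(stages)
  if (any(input_size %% div != 0)) {
    stop_config("input_size must be divisible by 2^%d = %d",
                length(stages), div)
  }
  structure(list(input_size = as.integer(input_size),
                 stages = lapply(stages, as.integer), preset = preset),
            class = "seg_config")
}

#' Build a SegNet-style segmentation model
#'
#' Maps `H x W x 3` RGB input to an `H x W` leaf-probability mask. Encoder
#' stage i's pooling indices are reused by the mirrored decoder stage, and
#' every convolution is a Conv Block (3x3 convolution without bias, batch
#' normalization, ReLU) except the final 1x1 sigmoid prediction layer.
#'
#' @param config A [seg_config()].
#' @param init_seed Seed for weight initialization, so identical calls
#'   build identical models.
#' @return An `lcnet_model` of type `"segnet"`.
#' @export
build_segnet <- function(config = seg_config(), init_seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  with_seed(init_seed, {
    layers <- list()
    pools <- list()
    cin <- 3L
    widths <- vapply(config$stages, `[`, 1L, 2)
    for (s in seq_along(config$stages)) {
      n_convs <- config$stages[[s]][1]
      w <- widths[s]
      for (i in seq_len(n_convs)) {
        layers <- c(layers, list(conv_layer(3L, cin, w), bn_layer(w),
                                 relu_layer()))
        cin <- w
      }
      p <- pool_layer()
      pools[[s]] <- p
      layers <- c(layers, list(p))
    }
    for (s in rev(seq_along(config$stages))) {
      n_convs <- config$stages[[s]][1]
      w <- widths[s]
      w_out <- if (s > 1) widths[s - 1] else widths[1]
      layers <- c(layers, list(unpool_layer(pools[[s]])))
      for (i in seq_len(n_convs)) {
        wo <- if (i == n_convs) w_out else w
        layers <- c(layers, list(conv_layer(3L, cin, wo), bn_layer(wo),
                                 relu_layer()))
        cin <- wo
      }
    }
    layers <- c(layers, list(conv_layer(1L, cin, 1L, bias = TRUE),
                             sigmoid_layer()))
    new_model(layers, config, "segnet")
  })
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))` with predictions
#' clipped to `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param pred Predicted probabilities, any shape.
#' @param target Binary targets of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    stop_config("pred and target shapes differ")
  }
  if (!all(target %in% c(0, 1))) stop_config("targets must be binary")
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Predict leaf-probability masks
#'
#' @param model A trained [build_segnet()] model.
#' @param rgb One `H x W x 3` array, an `image_sample`, or a list of
#'   either; sizes must match the model input size.
#' @return One `H x W` probability matrix, or a list of them in input
#'   order.
#' @export
predict_mask <- function(model, rgb) {
  stopifnot(inherits(model, "lcnet_segnet"))
  single <- !is.list(rgb) || inherits(rgb, "image_sample")
  items <- if (single) list(rgb) else rgb
  items <- lapply(items, function(x) {
    if (inherits(x, "image_sample")) x <- x$rgb
    if (length(dim(x)) != 3L || dim(x)[3] != 3L ||
        !all(dim(x)[1:2] == model$config$input_size)) {
      stop_config("input must be %d x %d x 3",
                  model$config$input_size[1], model$config$input_size[2])
    }
    x
  })
  out <- nn_infer(model, stack_batch(items))
  masks <- lapply(seq_along(items), function(i) {
    m <- out[, , i, 1]
    dim(m) <- dim(out)[1:2]
    m
  })
  nn_clear_cache(model)
  if (single) masks[[1]] else masks
}

#' Normalization layer: threshold filter for probability masks
#'
#' Zeroes every mask value strictly below the threshold and passes values
#' at or above it through unchanged (values exactly at the threshold are
#' kept). This removes spurious low-confidence pixels -- from uneven
#' background or light reflections -- before the mask is consumed by the
#' counting network. Idempotent. With `binarize = TRUE` surviving values
#' are set to 1, producing a hard mask.
#'
#' @param mask Probability mask (matrix or array) with values in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`; default 0.5.
#' @param binarize Map surviving values to 1?
#' @return The filtered mask, same shape.
#' @export
normalize_mask <- function(mask, threshold = 0.5, binarize = FALSE) {
  check_number(threshold, "threshold", min = 0, max = 1)
  out <- mask
  out[out < threshold] <- 0
  if (binarize) out[out >= threshold] <- 1
  out
}

#' Training configuration
#'
#' Shared by the segmentation and counting trainers.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Seed controlling shuffling (and any other training-time
#'   randomness); two runs with the same seed produce identical histories.
#' @param huber_delta Smooth-L1 transition point delta > 0 (counting only).
#' @param mask_source `"ground_truth"` or `"segmenter"`: where the
#'   counter's mask channel comes from during training.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param verbose Print per-epoch progress?
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 10, batch_size = 16, lr = 1e-3,
                         seed = 1L, huber_delta = 1.0,
                         mask_source = c("segmenter", "ground_truth"),
                         lr_decay = 1.0, verbose = FALSE) {
  mask_source <- match.arg(mask_source)
  check_number(epochs, "epochs", min = 1, integer = TRUE)
  check_number(batch_size, "batch_size", min = 1, integer = TRUE)
  check_number(lr, "lr", min = 1e-12)
  check_number(huber_delta, "huber_delta", min = 1e-12)
  check_number(lr_decay, "lr_decay", min = 1e-6, max = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), huber_delta = huber_delta,
                 mask_source = mask_source, lr_decay = lr_decay,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the segmentation model
#'
#' Minimizes binary cross-entropy between predicted and ground-truth leaf
#' masks with Adam, logging per-epoch train/validation loss and
#' validation pixel accuracy / IoU / Dice (probabilities thresholded at
#' 0.5). Deterministic given `cfg$seed`.
#'
#' @param model A [build_segnet()] model.
#' @param manifest Manifest whose train (and optionally val) records have
#'   masks.
#' @param root Directory manifest paths are relative to.
#' @param cfg A [train_config()].
#' @return List with `model` (trained in place) and `history` (one row
#'   per epoch).
#' @export
train_segmenter <- function(model, manifest, root, cfg = train_config()) {
  stopifnot(inherits(model, "lcnet_segnet"), inherits(cfg, "train_config"))
  manifest <- validate_manifest(manifest)
  tr <- manifest[manifest$split == "train", ]
  if (!nrow(tr)) stop_config("train split is empty")
  if (any(is.na(tr$mask_path) | !nzchar(tr$mask_path))) {
    stop_config("all train records need masks for segmentation training")
  }
  size <- model$config$input_size
  train <- load_samples(manifest, root, "train", target = size)
  val <- load_samples(manifest, root, "val", target = size)
  x_tr <- stack_batch(lapply(train, `[[`, "rgb"))
  y_tr <- stack_batch(lapply(train, `[[`, "mask"))
  x_val <- if (length(val)) stack_batch(lapply(val, `[[`, "rgb"))
  y_val <- if (length(val)) stack_batch(lapply(val, `[[`, "mask"))
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
        yb <- y_tr[, , sel, , drop = FALSE]
        p <- nn_forward(model, xb, training = TRUE)
        losses <- c(losses, bce_loss(p, yb))
        # gradient w.r.t. the pre-sigmoid logits (fused, numerically stable)
        nn_backward(model, (p - yb) / length(p),
                    from = length(model$layers) - 1L)
        nn_adam_step(model, lr)
      }
      row <- data.frame(epoch = ep, train_loss = mean(losses),
                        val_loss = NA_real_, val_accuracy = NA_real_,
                        val_iou = NA_real_, val_dice = NA_real_)
      if (length(val)) {
        pv <- nn_infer(model, x_val)
        row$val_loss <- bce_loss(pv, y_val)
        pb <- (pv >= 0.5) * 1
        row$val_accuracy <- pixel_accuracy(pb, y_val)
        row$val_iou <- iou(pb, y_val)
        row$val_dice <- dice(pb, y_val)
      }
      hist[[ep]] <- row
      if (cfg$verbose) {
        message(sprintf(
          "seg epoch %d/%d  train %.4f  val %.4f  IoU %.3f", ep,
          cfg$epochs, row$train_loss, row$val_loss, row$val_iou))
      }
      lr <- lr * cfg$lr_decay
    }
  })
  nn_clear_cache(model)
  list(model = model, history = do.call(rbind, hist))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are written in R's native serialization with a sidecar
#' JSON file describing the configuration, so a checkpoint can be audited
#' without loading it.
#'
#' @param model An `lcnet_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `path` +
#'   `".json"`.
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`:
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "lcnet_model"))
  nn_clear_cache(model)
  state <- list(type = model$type, config = model$config,
                layers = lapply(model$layers, function(l) {
                  list(params = l$params,
                       running_mean = l$running_mean,
                       running_var = l$running_var)
                }))
  saveRDS(state, path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(type = model$type, config = cfg,
         n_parameters = count_parameters(model)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  model <- if (state$type == "segnet") {
    build_segnet(state$config)
  } else {
    build_lcnet(state$config)
  }
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    l$params <- state$layers[[i]]$params
    if (!is.null(state$layers[[i]]$running_mean)) {
      l$running_mean <- state$layers[[i]]$running_mean
      l$running_var <- state$layers[[i]]$running_var
    }
  }
  model
}
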