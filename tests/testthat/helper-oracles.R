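# Independent brute-force oracles: straight-loop arithmetic kept separate
# from the package implementations they check.

bf_dic <- function(pred, gt) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - gt[i])
  s / length(pred)
}

bf_abs_dic <- function(pred, gt) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - gt[i])
  s / length(pred)
}

bf_mse <- function(pred, gt) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - gt[i])^2
  s / length(pred)
}

bf_r2 <- function(pred, gt) {
  m <- 0
  for (i in seq_along(gt)) m <- m + gt[i]
  m <- m / length(gt)
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(gt)) {
    ss_res <- ss_res + (gt[i] - pred[i])^2
    ss_tot <- ss_tot + (gt[i] - m)^2
  }
  1 - ss_res / ss_tot
}

bf_agreement <- function(pred, gt) {
  hits <- 0
  for (i in seq_along(pred)) if (pred[i] == gt[i]) hits <- hits + 1
  100 * hits / length(pred)
}

bf_pixel_accuracy <- function(p, g) {
  hits <- 0
  for (i in seq_along(p)) if (p[i] == g[i]) hits <- hits + 1
  hits / length(p)
}

bf_iou <- function(p, g) {
  inter <- 0
  union <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && g[i] == 1) inter <- inter + 1
    if (p[i] == 1 || g[i] == 1) union <- union + 1
  }
  if (union == 0) return(1)
  inter / union
}

bf_dice <- function(p, g) {
  inter <- 0
  size <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && g[i] == 1) inter <- inter + 1
    size <- size + p[i] + g[i]
  }
  if (size == 0) return(1)
  2 * inter / size
}

# Direct per-pixel evaluation of the bilinear formula at target pixel
# centers (center-alignment convention).
bf_bilinear <- function(src, th, tw) {
  h <- nrow(src); w <- ncol(src)
  out <- matrix(0, th, tw)
  for (i in seq_len(th)) {
    for (j in seq_len(tw)) {
      sr <- min(max((i - 0.5) * h / th - 0.5, 0), h - 1)
      sc <- min(max((j - 0.5) * w / tw - 0.5, 0), w - 1)
      r0 <- floor(sr); c0 <- floor(sc)
      r1 <- min(r0 + 1, h - 1); c1 <- min(c0 + 1, w - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <-
        (1 - fr) * ((1 - fc) * src[r0 + 1, c0 + 1] + fc * src[r0 + 1, c1 + 1]) +
        fr * ((1 - fc) * src[r1 + 1, c0 + 1] + fc * src[r1 + 1, c1 + 1])
    }
  }
  out
}

# Layer-by-layer hand count of trainable parameters: 3x3 convolutions
# carry 9*cin*cout weights (no bias) plus 2*cout batch-norm terms; the
# decoder mirrors the encoder with the last conv of each decoder stage
# stepping down to the previous stage's width; final 1x1 conv has bias.
bf_segnet_params <- function(stages, cin = 3) {
  widths <- vapply(stages, `[`, 1, 2)
  total <- 0
  for (s in seq_along(stages)) {
    for (i in seq_len(stages[[s]][1])) {
      total <- total + 9 * cin * widths[s] + 2 * widths[s]
      cin <- widths[s]
    }
  }
  for (s in rev(seq_along(stages))) {
    w_out <- if (s > 1) widths[s - 1] else widths[1]
    for (i in seq_len(stages[[s]][1])) {
      wo <- if (i == stages[[s]][1]) w_out else widths[s]
      total <- total + 9 * cin * wo + 2 * wo
      cin <- wo
    }
  }
  total + cin * 1 + 1
}

# Hand count for the counting network: per stage one 1x1 block then three
# 3x3 blocks, head = single linear unit on the last width.
bf_lcnet_params <- function(stages, cin = 4) {
  total <- 0
  for (s in stages) {
    p <- s[1]; w <- s[2]
    total <- total + cin * p + 2 * p
    cin <- p
    for (i in 1:3) {
      total <- total + 9 * cin * w + 2 * w
      cin <- w
    }
  }
  total + cin + 1
}

mask_only_sample <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lcnet:::new_image_sample(array(0.5, c(h, w, 3)), mask, count = 1L)
}

# Tiny on-disk dataset shared by pipeline tests; built once per session.
.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    dir <- file.path(tempdir(), "lcnet-tiny")
    params <- sim_params(n_images = 24, count_range = c(2, 5),
                         canvas = c(32, 32), leaf_length_range = c(10, 14),
                         leaf_width_range = c(4, 6),
                         radial_offset_range = c(3, 6), seed = 99)
    manifest <- generate_dataset(params, dir)
    manifest <- split_dataset(manifest, c(16 / 24, 4 / 24, 4 / 24),
                              seed = 99)
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    .fixture_cache$tiny <- list(dir = dir, manifest = manifest,
                                params = params)
  }
  .fixture_cache$tiny
}
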