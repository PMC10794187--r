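# Manifest-based data pipeline: CSV manifests referencing PNG/JPEG images
# and PNG masks, bilinear image resizing (nearest-neighbour for masks),
# the square-dihedral augmentation ops, seeded splits, and merging.

MANIFEST_COLS <- c("image_path", "mask_path", "count", "source", "split")
SPLIT_LEVELS <- c("train", "val", "test", "unassigned")

new_image_sample <- function(rgb, mask = NULL, count = NA_integer_,
                             source = "unknown", split = "unassigned") {
  if (!is.null(mask)) {
    stopifnot(all(dim(rgb)[1:2] == dim(mask)[1:2]),
              all(mask %in% c(0, 1)))
  }
  structure(list(rgb = rgb, mask = mask,
                 count = if (is.na(count)) NA_integer_ else as.integer(count),
                 source = source, split = split),
            class = "image_sample")
}

#' Read and write dataset manifests
#'
#' A manifest is a CSV with header
#' `image_path,mask_path,count,source,split`; paths are relative to the
#' manifest's directory. Reading validates the schema, path uniqueness and
#' count non-negativity.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: a data frame with the five manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_config("manifest not found: '%s'", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(count = "integer"))
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  if (!is.data.frame(m) || !all(MANIFEST_COLS %in% names(m))) {
    stop_config("manifest must have columns %s",
                paste(MANIFEST_COLS, collapse = ", "))
  }
  m <- m[MANIFEST_COLS]
  if (anyDuplicated(m$image_path)) {
    stop_config("duplicate image paths in manifest: %s",
                paste(unique(m$image_path[duplicated(m$image_path)]),
                      collapse = ", "))
  }
  ok_count <- is.na(m$count) | (m$count >= 0 & m$count == round(m$count))
  if (!all(ok_count)) stop_config("counts must be non-negative integers")
  if (!all(m$split %in% SPLIT_LEVELS)) {
    stop_config("split must be one of %s", paste(SPLIT_LEVELS, collapse = ", "))
  }
  m
}

#' Read an image or mask file
#'
#' Images (PNG or JPEG) are returned as H x W x 3 arrays in `[0, 1]`;
#' masks are binarized at 0.5 to `{0, 1}` matrices.
#'
#' @param path File path.
#' @return Numeric array (image) or matrix (mask).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_config("image file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop_config("reading '%s' requires the 'jpeg' package", path)
    }
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), c(dim(img), 3))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_config("mask file not found: '%s'", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m >= 0.5) * 1
}

#' Load manifest records into memory
#'
#' @param manifest Manifest data frame.
#' @param root Directory the manifest paths are relative to.
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @param target Optional `c(H, W)`; samples are resized on load.
#' @return List of `image_sample` objects in manifest order.
#' @export
load_samples <- function(manifest, root, split = NULL, target = NULL) {
  manifest <- validate_manifest(manifest)
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    mask <- if (!is.na(rec$mask_path) && nzchar(rec$mask_path)) {
      read_mask(file.path(root, rec$mask_path))
    }
    s <- new_image_sample(read_image(file.path(root, rec$image_path)),
                          mask = mask, count = rec$count,
                          source = rec$source, split = rec$split)
    if (!is.null(target)) s <- resize_bilinear(s, target)
    out[[i]] <- s
  }
  out
}

# Bilinear resample one channel (matrix) to target size using the
# pixel-center alignment convention: target center t maps to source
# coordinate (t + 0.5) * size_ratio - 0.5, clamped to the grid.
resize_channel_bilinear <- function(ch, th, tw) {
  h <- nrow(ch); w <- ncol(ch)
  sr <- pmin(pmax((seq_len(th) - 0.5) * h / th - 0.5, 0), h - 1)
  sc <- pmin(pmax((seq_len(tw) - 0.5) * w / tw - 0.5, 0), w - 1)
  r0 <- pmin(floor(sr), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(floor(sc), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- sr - r0; fc <- sc - c0
  a <- ch[r0 + 1, c0 + 1, drop = FALSE]
  b <- ch[r0 + 1, c1 + 1, drop = FALSE]
  cc <- ch[r1 + 1, c0 + 1, drop = FALSE]
  d <- ch[r1 + 1, c1 + 1, drop = FALSE]
  top <- a + sweep(b - a, 2, fc, "*")
  bot <- cc + sweep(d - cc, 2, fc, "*")
  top + sweep(bot - top, 1, fr, "*")
}

resize_channel_nearest <- function(ch, th, tw) {
  h <- nrow(ch); w <- ncol(ch)
  sr <- pmin(pmax(round((seq_len(th) - 0.5) * h / th - 0.5), 0), h - 1)
  sc <- pmin(pmax(round((seq_len(tw) - 0.5) * w / tw - 0.5), 0), w - 1)
  ch[sr + 1, sc + 1, drop = FALSE]
}

#' Resize a sample with bilinear interpolation
#'
#' The RGB channels are resampled bilinearly at target pixel centers; the
#' binary mask (when present) is resampled by nearest neighbour so it
#' stays strictly binary. The count is untouched.
#'
#' @param sample An `image_sample`, an H x W x C array, or a matrix.
#' @param target `c(H, W)` target size, both >= 1.
#' @return Same type as the input, resized.
#' @export
resize_bilinear <- function(sample, target) {
  if (!is.numeric(target) || length(target) != 2L || any(target < 1) ||
      any(target != round(target))) {
    stop_config("'target' must be two positive integers c(H, W)")
  }
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  if (is.matrix(sample)) return(resize_channel_bilinear(sample, th, tw))
  if (is.array(sample) && length(dim(sample)) == 3L) {
    out <- array(0, c(th, tw, dim(sample)[3]))
    for (ch in seq_len(dim(sample)[3])) {
      out[, , ch] <- resize_channel_bilinear(sample[, , ch], th, tw)
    }
    return(out)
  }
  stopifnot(inherits(sample, "image_sample"))
  if (all(dim(sample$rgb)[1:2] == c(th, tw))) return(sample)
  rgb <- resize_bilinear(sample$rgb, target)
  mask <- if (!is.null(sample$mask)) {
    resize_channel_nearest(sample$mask, th, tw)
  }
  new_image_sample(clip01(rgb), mask, sample$count, sample$source,
                   sample$split)
}

#' Geometric augmentation operations
#'
#' The closed op set is `VFLIP` (mirror about the horizontal axis: row
#' order reversed), `ROT90CW`, `ROT90CCW` and `ROT180`. The same transform
#' is applied to the RGB channels and the mask; the count is untouched.
#'
#' @param sample An `image_sample`, array, or matrix.
#' @param op One of `"VFLIP"`, `"ROT90CW"`, `"ROT90CCW"`, `"ROT180"`.
#' @return The transformed input, same type.
#' @export
apply_augmentation <- function(sample, op) {
  ops <- c("VFLIP", "ROT90CW", "ROT90CCW", "ROT180")
  if (!is.character(op) || length(op) != 1L || !op %in% ops) {
    stop_config("unknown augmentation op '%s' (must be one of %s)",
                paste(op, collapse = ","), paste(ops, collapse = ", "))
  }
  tf <- function(m) {
    switch(op,
      VFLIP   = m[rev(seq_len(nrow(m))), , drop = FALSE],
      ROT90CW = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
      ROT90CCW = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
      ROT180  = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
    )
  }
  if (is.matrix(sample)) return(tf(sample))
  if (is.array(sample) && length(dim(sample)) == 3L) {
    planes <- lapply(seq_len(dim(sample)[3]), function(ch) tf(sample[, , ch]))
    out <- array(0, c(dim(planes[[1]]), length(planes)))
    for (ch in seq_along(planes)) out[, , ch] <- planes[[ch]]
    return(out)
  }
  stopifnot(inherits(sample, "image_sample"))
  new_image_sample(apply_augmentation(sample$rgb, op),
                   if (!is.null(sample$mask)) tf(sample$mask),
                   sample$count, sample$source, sample$split)
}

#' Materialize augmented copies of a dataset
#'
#' Appends `k_per_image` augmented copies per source image to the
#' manifest, with ops drawn uniformly under the given seed; augmented
#' images and masks are written next to the originals and counts are
#' copied verbatim.
#'
#' @param manifest Manifest data frame.
#' @param root Directory the manifest paths are relative to.
#' @param k_per_image Number of augmented copies per image (>= 0).
#' @param seed Integer seed for the op draws.
#' @return The expanded manifest (original records first).
#' @export
expand_with_augmentation <- function(manifest, root, k_per_image, seed = 1L) {
  manifest <- validate_manifest(manifest)
  check_number(k_per_image, "k_per_image", min = 0, integer = TRUE)
  if (k_per_image == 0) return(manifest)
  ops <- c("VFLIP", "ROT90CW", "ROT90CCW", "ROT180")
  draws <- with_seed(seed,
    sample(ops, nrow(manifest) * k_per_image, replace = TRUE))
  extra <- vector("list", nrow(manifest) * k_per_image)
  idx <- 0L
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    img_file <- file.path(root, rec$image_path)
    if (!file.exists(img_file)) {
      stop_config("image file missing on disk: '%s'", img_file)
    }
    img <- read_image(img_file)
    has_mask <- !is.na(rec$mask_path) && nzchar(rec$mask_path)
    msk <- if (has_mask) read_mask(file.path(root, rec$mask_path))
    for (k in seq_len(k_per_image)) {
      idx <- idx + 1L
      op <- draws[idx]
      stem <- tools::file_path_sans_ext(rec$image_path)
      img_rel <- sprintf("%s_aug%d_%s.png", stem, k, tolower(op))
      png::writePNG(apply_augmentation(img, op), file.path(root, img_rel))
      msk_rel <- NA_character_
      if (has_mask) {
        mstem <- tools::file_path_sans_ext(rec$mask_path)
        msk_rel <- sprintf("%s_aug%d_%s.png", mstem, k, tolower(op))
        png::writePNG(apply_augmentation(msk, op), file.path(root, msk_rel))
      }
      extra[[idx]] <- data.frame(
        image_path = img_rel, mask_path = msk_rel, count = rec$count,
        source = rec$source, split = rec$split, stringsAsFactors = FALSE)
    }
  }
  rbind(manifest, do.call(rbind, extra))
}

#' Assign train/validation/test splits
#'
#' Shuffles the records under the given seed, then assigns
#' `round(n * fraction)` records to validation and test and the remainder
#' to train, so the sizes follow the rounding rule exactly (for n = 2010
#' at fractions 1410/2010, 300/2010, 300/2010 this yields 1410/300/300).
#'
#' @param manifest Manifest data frame (non-empty).
#' @param fractions `c(train, val, test)` fractions summing to 1.
#' @param seed Integer shuffle seed.
#' @return Manifest with every record assigned exactly one split.
#' @export
split_dataset <- function(manifest, fractions, seed = 1L) {
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) == 0) stop_config("cannot split an empty manifest")
  if (!is.numeric(fractions) || length(fractions) != 3L ||
      any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_config("'fractions' must be c(train, val, test) in [0,1] summing to 1")
  }
  n <- nrow(manifest)
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  if (n_val + n_test > n) n_test <- n - n_val
  ord <- with_seed(seed, sample.int(n))
  split <- rep("train", n)
  split[ord[seq_len(n_val)]] <- "val"
  split[ord[n_val + seq_len(n_test)]] <- "test"
  manifest$split <- split
  manifest
}

#' Concatenate two manifests
#'
#' Records are concatenated in order with source labels preserved;
#' duplicate image paths across the two manifests are an error.
#'
#' @param a,b Manifest data frames.
#' @return The merged manifest.
#' @export
merge_manifests <- function(a, b) {
  a <- validate_manifest(a); b <- validate_manifest(b)
  dup <- intersect(a$image_path, b$image_path)
  if (length(dup)) {
    stop_config("duplicate image paths across manifests: %s",
                paste(dup, collapse = ", "))
  }
  rbind(a, b)
}
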