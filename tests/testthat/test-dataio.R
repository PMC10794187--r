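test_that("bilinear resize matches the per-pixel formula and edge cases", {
  src <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(resize_bilinear(src, c(4, 4)), bf_bilinear(src, 4, 4),
               tolerance = 1e-12)
  set.seed(1)
  src2 <- matrix(runif(35), 5, 7)
  expect_equal(resize_bilinear(src2, c(9, 4)), bf_bilinear(src2, 9, 4),
               tolerance = 1e-12)
  # identity resize returns the sample unchanged
  p <- sim_params(n_images = 1, canvas = c(32, 32), seed = 4)
  s <- render_scene(generate_scene(p, 0), p, 0)
  expect_identical(resize_bilinear(s, c(32, 32)), s)
  # masks go through nearest-neighbour and stay binary
  up <- resize_bilinear(s, c(48, 48))
  expect_true(all(up$mask %in% c(0, 1)))
  expect_equal(up$count, s$count)
  expect_error(resize_bilinear(s, c(0, 10)), "target")
})

test_that("upscale then downscale keeps the mask within a boundary band", {
  p <- sim_params(n_images = 2, canvas = c(32, 32), count_range = c(2, 4),
                  leaf_length_range = c(10, 14), leaf_width_range = c(4, 6),
                  radial_offset_range = c(3, 6), seed = 12)
  for (i in 0:1) {
    m <- render_scene(generate_scene(p, i), p, i)$mask
    up <- resize_bilinear(mask_only_sample(m), c(64, 64))
    back <- resize_bilinear(up, c(32, 32))$mask
    expect_gt(mean(back == m), 0.95)
    diff_px <- which(back != m, arr.ind = TRUE)
    if (nrow(diff_px)) {
      # every disagreeing pixel touches the mask boundary
      for (r in seq_len(nrow(diff_px))) {
        i0 <- diff_px[r, 1]; j0 <- diff_px[r, 2]
        nb <- m[max(1, i0 - 1):min(32, i0 + 1),
                max(1, j0 - 1):min(32, j0 + 1)]
        expect_true(any(nb != m[i0, j0]))
      }
    }
  }
})

test_that("augmentation ops satisfy the dihedral group laws", {
  set.seed(7)
  img <- array(runif(6 * 8 * 3), c(6, 8, 3))
  mask <- matrix(rbinom(48, 1, 0.4), 6, 8)
  s <- lcnet:::new_image_sample(img, mask, count = 4L)

  vv <- apply_augmentation(apply_augmentation(s, "VFLIP"), "VFLIP")
  expect_equal(vv, s)
  cwccw <- apply_augmentation(apply_augmentation(s, "ROT90CW"), "ROT90CCW")
  expect_equal(cwccw, s)
  via_cw <- apply_augmentation(apply_augmentation(s, "ROT90CW"), "ROT90CW")
  via_ccw <- apply_augmentation(apply_augmentation(s, "ROT90CCW"), "ROT90CCW")
  r180 <- apply_augmentation(s, "ROT180")
  expect_equal(via_cw, r180)
  expect_equal(via_ccw, r180)

  for (op in c("VFLIP", "ROT90CW", "ROT90CCW", "ROT180")) {
    out <- apply_augmentation(s, op)
    expect_equal(out$count, s$count)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_equal(sort(as.numeric(out$rgb)), sort(as.numeric(s$rgb)))
  }
  expect_error(apply_augmentation(s, "SHEAR"), "unknown augmentation")
})

test_that("the op set generates at most the 8 square-dihedral elements", {
  probe <- matrix(1:9, 3, 3)
  ops <- c("VFLIP", "ROT90CW", "ROT90CCW", "ROT180")
  seen <- list(probe)
  repeat {
    new <- list()
    for (m in seen) {
      for (op in ops) {
        t <- apply_augmentation(m, op)
        if (!any(vapply(c(seen, new), identical, TRUE, t))) {
          new <- c(new, list(t))
        }
      }
    }
    if (!length(new)) break
    seen <- c(seen, new)
  }
  expect_lte(length(seen), 8)
})

test_that("expand_with_augmentation appends seeded copies with counts kept", {
  fx <- tiny_dataset()
  sub <- fx$manifest[1:5, ]
  expect_identical(expand_with_augmentation(sub, fx$dir, 0), sub)
  e1 <- expand_with_augmentation(sub, fx$dir, 2, seed = 5)
  expect_equal(nrow(e1), 15)
  expect_equal(e1$count[6:15], rep(sub$count, each = 2))
  for (i in 6:15) {
    expect_true(file.exists(file.path(fx$dir, e1$image_path[i])))
    expect_true(all(read_mask(file.path(fx$dir, e1$mask_path[i])) %in%
                      c(0, 1)))
  }
  e2 <- expand_with_augmentation(sub, fx$dir, 2, seed = 5)
  expect_identical(e1$image_path, e2$image_path)
  bad <- sub
  bad$image_path[1] <- "images/does_not_exist.png"
  expect_error(expand_with_augmentation(bad, fx$dir, 1),
               "does_not_exist")
})

test_that("split sizes follow the rounding rule and partition the records", {
  mk <- function(n) {
    data.frame(image_path = sprintf("img%04d.png", seq_len(n)),
               mask_path = NA_character_, count = 3L, source = "x",
               split = "unassigned", stringsAsFactors = FALSE)
  }
  s <- split_dataset(mk(2010), c(1410 / 2010, 300 / 2010, 300 / 2010),
                     seed = 1)
  expect_equal(as.integer(table(s$split)[c("train", "val", "test")]),
               c(1410L, 300L, 300L))
  s2 <- split_dataset(mk(100), c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(as.integer(table(s2$split)[c("train", "val", "test")]),
               c(70L, 15L, 15L))
  s3 <- split_dataset(mk(10), c(1, 0, 0), seed = 1)
  expect_true(all(s3$split == "train"))
  # partition: every record in exactly one split
  expect_true(all(s$split %in% c("train", "val", "test")))
  expect_equal(nrow(s), 2010)
  expect_error(split_dataset(mk(10)[0, ], c(1, 0, 0)), "empty")
  expect_error(split_dataset(mk(10), c(0.5, 0.2, 0.2)), "fractions")
})

test_that("manifest merge preserves order and rejects duplicates", {
  mk <- function(n, prefix) {
    data.frame(image_path = sprintf("%s%04d.png", prefix, seq_len(n)),
               mask_path = NA_character_, count = 3L, source = prefix,
               split = "unassigned", stringsAsFactors = FALSE)
  }
  a <- mk(810, "cvppp")
  b <- mk(1200, "komatsuna")
  m <- merge_manifests(a, b)
  expect_equal(nrow(m), 2010)
  expect_identical(m$source, c(a$source, b$source))
  empty <- a[0, ]
  expect_identical(merge_manifests(a, empty), a)
  expect_error(merge_manifests(a, a[1, ]), "duplicate")
})

test_that("manifests round-trip through CSV with schema validation", {
  fx <- tiny_dataset()
  path <- file.path(tempdir(), "roundtrip.csv")
  write_manifest(fx$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$image_path, fx$manifest$image_path)
  expect_equal(back$count, fx$manifest$count)
  bad <- fx$manifest
  bad$count[1] <- -2L
  expect_error(write_manifest(bad, path), "non-negative")
})
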