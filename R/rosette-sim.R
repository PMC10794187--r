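# Procedural rosette-plant simulator. Scenes are lists of elliptical leaf
# primitives arranged radially around a plant center; rendering rasterizes
# them in painter's order over a textured background, adds an illumination
# gradient and Gaussian pixel noise, and returns the exact union mask and
# leaf count. Coordinates are row-major with origin at the top-left pixel
# center; angles are measured counter-clockwise from the +column axis.

#' Simulation parameters for the rosette-image generator
#'
#' Describes one generation regime: how many images, the range of leaf
#' counts, canvas size, leaf geometry, how strongly leaves crowd and
#' overlap, the background style, and the photometric nuisances
#' (illumination gradient, additive noise). The same parameter object with
#' the same seed always reproduces the same images.
#'
#' @param n_images Number of images to generate (positive integer).
#' @param count_range Inclusive integer interval `c(c_min, c_max)` of leaf
#'   counts per plant, `c_min >= 0`.
#' @param canvas `c(height, width)` in pixels; each dimension >= 32.
#' @param leaf_length_range Full leaf length interval in pixels.
#' @param leaf_width_range Full leaf width interval in pixels; leaf length
#'   must be >= leaf width > 0.
#' @param angular_jitter Standard half-width (radians, >= 0) of the uniform
#'   jitter added to each leaf's regular base angle.
#' @param radial_offset_range Interval of distances (pixels) from the plant
#'   center to a leaf's center.
#' @param overlap_level Real in `[0, 1]`; scales angular jitter and leaf
#'   width upward so neighbouring leaves overlap more.
#' @param background One of `"soil"`, `"pot"`, `"green"`. `"green"` is the
#'   deliberately hard regime: leaf-coloured background texture.
#' @param illumination_amplitude Real in `[0, 1]`; amplitude of a linear
#'   illumination ramp across the canvas.
#' @param noise_sigma Standard deviation (>= 0) of additive Gaussian pixel
#'   noise on the RGB channels.
#' @param seed Integer master seed; each image i uses the deterministic
#'   sub-seed `hash(seed, i)`.
#' @return An object of class `sim_params`.
#' @seealso [sim_params_preset()] for the "easy"/"hard" regimes,
#'   [generate_scene()], [render_scene()], [generate_dataset()].
#' @export
sim_params <- function(n_images = 10,
                       count_range = c(3, 8),
                       canvas = c(64, 64),
                       leaf_length_range = c(18, 26),
                       leaf_width_range = c(7, 11),
                       angular_jitter = 0.15,
                       radial_offset_range = c(6, 11),
                       overlap_level = 0.25,
                       background = c("soil", "pot", "green"),
                       illumination_amplitude = 0.15,
                       noise_sigma = 0.02,
                       seed = 1L) {
  background <- match.arg(background)
  check_number(n_images, "n_images", min = 1, integer = TRUE)
  check_range(count_range, "count_range", min = 0, integer = TRUE)
  check_range(canvas, "canvas", min = 32, integer = TRUE)
  check_range(leaf_length_range, "leaf_length_range", min = 1e-9)
  check_range(leaf_width_range, "leaf_width_range", min = 1e-9)
  if (leaf_width_range[2] > leaf_length_range[1]) {
    stop_config(
      "'leaf_width_range' must lie below 'leaf_length_range' (length >= width)")
  }
  check_number(angular_jitter, "angular_jitter", min = 0)
  check_range(radial_offset_range, "radial_offset_range", min = 0)
  check_number(overlap_level, "overlap_level", min = 0, max = 1)
  check_number(illumination_amplitude, "illumination_amplitude",
               min = 0, max = 1)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_images = as.integer(n_images),
    count_range = as.integer(count_range),
    canvas = as.integer(canvas),
    leaf_length_range = as.numeric(leaf_length_range),
    leaf_width_range = as.numeric(leaf_width_range),
    angular_jitter = angular_jitter,
    radial_offset_range = as.numeric(radial_offset_range),
    overlap_level = overlap_level,
    background = background,
    illumination_amplitude = illumination_amplitude,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Difficulty presets for the simulator
#'
#' `"easy"` is a low-jitter, low-overlap regime on a soil background;
#' `"hard"` uses heavy overlap and a green-tinted background, the regime
#' segmentation models are known to struggle with.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_preset <- function(preset = c("easy", "hard"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    easy = list(count_range = c(3, 8), angular_jitter = 0.12,
                overlap_level = 0.15, background = "soil",
                illumination_amplitude = 0.12, noise_sigma = 0.02),
    hard = list(count_range = c(3, 12), angular_jitter = 0.35,
                overlap_level = 0.75, background = "green",
                illumination_amplitude = 0.30, noise_sigma = 0.05)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

#' Generate the geometric description of one synthetic rosette
#'
#' Draws the leaf count uniformly from `count_range`, then places leaf k
#' at base angle `2*pi*(k-1)/count` plus uniform jitter, displaced radially
#' from the plant center, with leaf size and colour drawn from the
#' configured ranges. Fully deterministic given `(params$seed, index)`.
#'
#' @param params A [sim_params()] object.
#' @param index Image index in `[0, n_images)`.
#' @return A `rosette_scene`: list with `leaves` (each a leaf primitive
#'   with `center`, `orientation`, `semi_major`, `semi_minor`, `color`),
#'   `plant_center`, `background`, and `count == length(leaves)`.
#' @export
generate_scene <- function(params, index) {
  stopifnot(inherits(params, "sim_params"))
  check_number(index, "index", min = 0, max = params$n_images - 1,
               integer = TRUE)
  with_seed(hash_seed(params$seed, index), {
    h <- params$canvas[1]; w <- params$canvas[2]
    count <- if (params$count_range[1] == params$count_range[2]) {
      params$count_range[1]
    } else {
      sample(params$count_range[1]:params$count_range[2], 1L)
    }
    center <- c(row = (h - 1) / 2 + runif(1, -1.5, 1.5),
                col = (w - 1) / 2 + runif(1, -1.5, 1.5))
    jit <- params$angular_jitter * (1 + params$overlap_level)
    wscale <- 1 + 0.5 * params$overlap_level
    leaves <- vector("list", count)
    for (k in seq_len(count)) {
      theta <- 2 * pi * (k - 1) / max(count, 1L) + runif(1, -jit, jit)
      r <- runif(1, params$radial_offset_range[1],
                 params$radial_offset_range[2])
      len <- runif(1, params$leaf_length_range[1],
                   params$leaf_length_range[2])
      wid <- min(runif(1, params$leaf_width_range[1],
                       params$leaf_width_range[2]) * wscale, len)
      # +col is x, +row is y pointing down; CCW angle theta means the leaf
      # center moves by (r*cos, -r*sin) in (col, row).
      leaves[[k]] <- list(
        center = c(row = center[["row"]] - r * sin(theta),
                   col = center[["col"]] + r * cos(theta)),
        orientation = theta,
        semi_major = len / 2,
        semi_minor = wid / 2,
        color = c(0.10 + runif(1, -0.04, 0.04),
                  0.45 + runif(1, -0.10, 0.10),
                  0.12 + runif(1, -0.05, 0.05))
      )
    }
    structure(list(leaves = leaves, plant_center = center,
                   background = params$background, count = count),
              class = "rosette_scene")
  })
}

# Logical inside-ellipse grid for one leaf, evaluated at pixel centers.
leaf_mask_grid <- function(leaf, h, w) {
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  dx <- cols - leaf$center[["col"]]
  dy <- rows - leaf$center[["row"]]
  ct <- cos(leaf$orientation); st <- sin(leaf$orientation)
  # CCW orientation in screen coordinates (row axis points down).
  u <- dx * ct - dy * st
  v <- dx * st + dy * ct
  (u / leaf$semi_major)^2 + (v / leaf$semi_minor)^2 <= 1
}

render_background <- function(background, h, w) {
  bg <- array(0, c(h, w, 3))
  tex <- matrix(runif(h * w, -0.03, 0.03), h, w)
  if (background == "soil") {
    bg[, , 1] <- 0.32 + tex
    bg[, , 2] <- 0.22 + tex
    bg[, , 3] <- 0.13 + tex
  } else if (background == "pot") {
    bg[, , 1] <- 0.55 + tex
    bg[, , 2] <- 0.55 + tex
    bg[, , 3] <- 0.55 + tex
    rows <- matrix(0:(h - 1), h, w)
    cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
    disc <- (rows - (h - 1) / 2)^2 + (cols - (w - 1) / 2)^2 <=
      (0.42 * min(h, w))^2
    for (ch in 1:3) {
      plane <- bg[, , ch]
      plane[disc] <- 0.16 + tex[disc]
      bg[, , ch] <- plane
    }
  } else { # green: leaf-tinted background, the deliberately hard regime
    bg[, , 1] <- 0.16 + tex
    bg[, , 2] <- 0.38 + tex
    bg[, , 3] <- 0.16 + tex
  }
  bg
}

#' Rasterize a rosette scene into an image sample
#'
#' Paints the background, then each leaf in order (later leaves occlude
#' earlier ones), applies a linear illumination ramp and additive Gaussian
#' noise (clipped back to `[0, 1]`), and computes the binary ground-truth
#' mask as the union of all rasterized leaf interiors: a pixel belongs to
#' leaf k iff the rotated-ellipse inequality holds at its center. Leaves
#' that fall entirely outside the canvas are clipped with a warning; the
#' stored count is unchanged.
#'
#' @param scene A `rosette_scene` from [generate_scene()].
#' @param params The [sim_params()] the scene was generated with.
#' @param index Image index; photometric noise is seeded from
#'   `(params$seed, index)` so rendering is deterministic too.
#' @return An `image_sample`: list with `rgb` (H x W x 3 in `[0,1]`),
#'   `mask` (H x W in `{0,1}`), `count`, `source`, `split`.
#' @export
render_scene <- function(scene, params, index = 0) {
  stopifnot(inherits(scene, "rosette_scene"), inherits(params, "sim_params"))
  h <- params$canvas[1]; w <- params$canvas[2]
  with_seed(hash_seed(params$seed, index) + 7L, {
    rgb <- render_background(scene$background, h, w)
    mask <- matrix(FALSE, h, w)
    for (leaf in scene$leaves) {
      inside <- leaf_mask_grid(leaf, h, w)
      if (!any(inside)) {
        warning("leaf entirely outside canvas; clipped (count unchanged)")
        next
      }
      mask <- mask | inside
      shade <- 1 - 0.25 * (leaf_edge_dist(leaf, h, w))
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[inside] <- (leaf$color[ch] * shade)[inside]
        rgb[, , ch] <- plane
      }
    }
    if (params$illumination_amplitude > 0) {
      ramp <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
      gain <- 1 + params$illumination_amplitude * 0.5 * ramp
      rgb <- rgb * array(gain, c(h, w, 3))
    }
    if (params$noise_sigma > 0) {
      rgb <- rgb + array(rnorm(h * w * 3, sd = params$noise_sigma),
                         c(h, w, 3))
    }
    new_image_sample(rgb = clip01(rgb), mask = mask * 1,
                     count = scene$count, source = "rosette_sim")
  })
}

# Normalized distance from the leaf midrib, used to shade leaf interiors.
leaf_edge_dist <- function(leaf, h, w) {
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  dx <- cols - leaf$center[["col"]]
  dy <- rows - leaf$center[["row"]]
  ct <- cos(leaf$orientation); st <- sin(leaf$orientation)
  v <- dx * st + dy * ct
  pmin(abs(v) / leaf$semi_minor, 1)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `params$n_images` image/mask pairs as 8-bit PNGs (mask values
#' exactly 0 or 255) and writes a CSV manifest with one row per sample.
#' Re-running with identical parameters reproduces byte-identical files.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame (invisibly also written to
#'   `manifest.csv` in `out_dir`), with columns
#'   `image_path`, `mask_path`, `count`, `source`, `split`.
#' @export
generate_dataset <- function(params, out_dir) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_config("cannot create output directory '%s'", out_dir)
  }
  n <- params$n_images
  rows <- vector("list", n)
  for (i in seq_len(n) - 1L) {
    scene <- generate_scene(params, i)
    sample <- render_scene(scene, params, i)
    img_rel <- file.path("images", sprintf("img_%05d.png", i))
    msk_rel <- file.path("masks", sprintf("mask_%05d.png", i))
    png::writePNG(sample$rgb, file.path(out_dir, img_rel))
    png::writePNG(sample$mask, file.path(out_dir, msk_rel))
    rows[[i + 1L]] <- data.frame(
      image_path = img_rel, mask_path = msk_rel, count = sample$count,
      source = "rosette_sim", split = "unassigned",
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
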