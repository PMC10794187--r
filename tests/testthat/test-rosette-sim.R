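test_that("sim_params validates its fields and names the offender", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(n_images = 0), "n_images")
  expect_error(sim_params(count_range = c(5, 3)), "count_range")
  expect_error(sim_params(canvas = c(16, 64)), "canvas")
  expect_error(sim_params(overlap_level = 1.5), "overlap_level")
  expect_error(sim_params(noise_sigma = -1), "noise_sigma")
  expect_error(sim_params(leaf_length_range = c(5, 8),
                          leaf_width_range = c(6, 9)), "leaf_width_range")
})

test_that("scene generation is deterministic and respects the count range", {
  p <- sim_params(n_images = 5, count_range = c(0, 0), seed = 3)
  s0 <- generate_scene(p, 0)
  expect_equal(s0$count, 0)
  expect_length(s0$leaves, 0)

  p <- sim_params(n_images = 10, count_range = c(2, 9), seed = 3)
  for (i in c(0, 4, 9)) {
    a <- generate_scene(p, i)
    b <- generate_scene(p, i)
    expect_identical(a, b)
    expect_equal(a$count, length(a$leaves))
    expect_gte(a$count, 2)
    expect_lte(a$count, 9)
  }
  expect_false(identical(generate_scene(p, 0), generate_scene(p, 1)))
  expect_error(generate_scene(p, 10), "index")
})

test_that("with zero jitter, leaf base angles follow the closed form", {
  p <- sim_params(n_images = 1, count_range = c(5, 5), angular_jitter = 0,
                  overlap_level = 0, seed = 17)
  s <- generate_scene(p, 0)
  angles <- vapply(s$leaves, `[[`, 1, "orientation")
  expect_equal(angles, 2 * pi * (0:4) / 5, tolerance = 1e-12)
})

test_that("rendered single-leaf mask equals exhaustive point-in-ellipse", {
  p <- sim_params(n_images = 1, count_range = c(1, 1), canvas = c(64, 64),
                  noise_sigma = 0, illumination_amplitude = 0, seed = 5)
  a <- 10; b <- 5
  scene <- structure(list(
    leaves = list(list(center = c(row = 31, col = 31), orientation = 0,
                       semi_major = a, semi_minor = b,
                       color = c(0.1, 0.5, 0.1))),
    plant_center = c(row = 31, col = 31), background = "soil", count = 1L),
    class = "rosette_scene")
  s <- render_scene(scene, p, 0)
  oracle <- matrix(0, 64, 64)
  for (r in 0:63) {
    for (cc in 0:63) {
      if (((cc - 31) / a)^2 + ((r - 31) / b)^2 <= 1) {
        oracle[r + 1, cc + 1] <- 1
      }
    }
  }
  expect_identical(s$mask, oracle)
  expect_equal(s$count, 1)
  expect_true(all(s$rgb >= 0 & s$rgb <= 1))
})

test_that("empty scenes give empty masks; overlap shrinks the union", {
  p <- sim_params(n_images = 1, count_range = c(0, 0), canvas = c(32, 32),
                  seed = 2)
  s <- render_scene(generate_scene(p, 0), p, 0)
  expect_true(all(s$mask == 0))

  mk_scene <- function(leaves) {
    structure(list(leaves = leaves, plant_center = c(row = 15, col = 15),
                   background = "soil", count = length(leaves)),
              class = "rosette_scene")
  }
  leaf <- function(col) {
    list(center = c(row = 15, col = col), orientation = 0, semi_major = 8,
         semi_minor = 4, color = c(0.1, 0.5, 0.1))
  }
  p32 <- sim_params(n_images = 1, canvas = c(32, 32), noise_sigma = 0,
                    seed = 2)
  a1 <- sum(render_scene(mk_scene(list(leaf(12))), p32, 0)$mask)
  a2 <- sum(render_scene(mk_scene(list(leaf(18))), p32, 0)$mask)
  both <- render_scene(mk_scene(list(leaf(12), leaf(18))), p32, 0)
  expect_lt(sum(both$mask), a1 + a2)
  expect_equal(both$count, 2)
})

test_that("a leaf entirely outside the canvas is clipped with a warning", {
  p <- sim_params(n_images = 1, canvas = c(32, 32), noise_sigma = 0,
                  seed = 2)
  scene <- structure(list(
    leaves = list(list(center = c(row = 200, col = 200), orientation = 0,
                       semi_major = 5, semi_minor = 3,
                       color = c(0.1, 0.5, 0.1))),
    plant_center = c(row = 15, col = 15), background = "soil", count = 1L),
    class = "rosette_scene")
  expect_warning(s <- render_scene(scene, p, 0), "clipped")
  expect_true(all(s$mask == 0))
  expect_equal(s$count, 1)
})

test_that("generate_dataset writes a reproducible, self-consistent dataset", {
  dir1 <- file.path(tempdir(), "sim-a")
  dir2 <- file.path(tempdir(), "sim-b")
  p <- sim_params(n_images = 3, canvas = c(32, 32), count_range = c(2, 6),
                  leaf_length_range = c(10, 14), leaf_width_range = c(4, 6),
                  radial_offset_range = c(3, 6), seed = 21)
  m1 <- generate_dataset(p, dir1)
  expect_equal(nrow(m1), 3)
  for (i in seq_len(3)) {
    expect_true(file.exists(file.path(dir1, m1$image_path[i])))
    expect_true(file.exists(file.path(dir1, m1$mask_path[i])))
    expect_equal(m1$count[i], generate_scene(p, i - 1)$count)
  }
  mask <- read_mask(file.path(dir1, m1$mask_path[1]))
  expect_true(all(mask %in% c(0, 1)))

  m2 <- generate_dataset(p, dir2)
  expect_identical(m1$count, m2$count)
  sum1 <- unname(tools::md5sum(file.path(dir1, m1$image_path)))
  sum2 <- unname(tools::md5sum(file.path(dir2, m2$image_path)))
  expect_identical(sum1, sum2)
})

test_that("mask presence tracks the count and grows with the count cap", {
  p0 <- sim_params(n_images = 4, count_range = c(0, 0), canvas = c(32, 32),
                   seed = 8)
  p1 <- sim_params(n_images = 4, count_range = c(1, 3), canvas = c(32, 32),
                   seed = 8)
  for (i in 0:3) {
    expect_equal(sum(render_scene(generate_scene(p0, i), p0, i)$mask), 0)
    expect_gt(sum(render_scene(generate_scene(p1, i), p1, i)$mask), 0)
  }
  frac <- vapply(c(3, 6, 9), function(cmax) {
    p <- sim_params(n_images = 12, count_range = c(1, cmax),
                    canvas = c(48, 48), leaf_length_range = c(10, 14),
                    leaf_width_range = c(4, 6),
                    radial_offset_range = c(3, 7), seed = 31)
    mean(vapply(0:11, function(i) {
      mean(render_scene(generate_scene(p, i), p, i)$mask)
    }, 1))
  }, 1)
  expect_true(all(diff(frac) >= 0))
})
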