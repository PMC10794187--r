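test_that("counter config enforces the bottleneck and shape constraints", {
  expect_error(count_config(stages = list(c(24, 24))), "less filter size")
  expect_error(count_config(stages = list(c(48, 24))), "less filter size")
  expect_error(count_config(input_size = c(50, 64),
                            stages = list(c(4, 8), c(8, 16))), "divisible")
  expect_error(count_config(channels = 2), "channels")
  expect_s3_class(count_config(channels = 3), "count_config")
})

test_that("conv-block parameter counts match the closed form", {
  # 1x1 block, 4 in-channels, 24 filters: 1*1*4*24 + 2*24
  m <- build_lcnet(count_config(input_size = c(32, 32),
                                stages = list(c(24, 48))))
  l1 <- m$layers[[1]]  # 1x1 conv
  expect_equal(length(l1$params$W), 4 * 24)
  expect_equal(length(l1$params$W) + 2 * 24, 144)
  # full model equals the hand count
  expect_equal(count_parameters(m), bf_lcnet_params(list(c(24, 48))))
  # 3x3 block 24 in, 48 out: 9*24*48 + 2*48 = 10464
  conv3 <- m$layers[[4]]
  expect_equal(conv3$k, 3L)
  expect_equal(length(conv3$params$W) + 2 * 48, 10464)
  # linear head on 416 features: 416 weights + 1 bias
  mp <- build_lcnet(count_config(preset = "paper"))
  head <- mp$layers[[length(mp$layers)]]
  expect_equal(length(head$params$W) + length(head$params$b), 417)
})

test_that("counter outputs one scalar per sample and is deterministic", {
  cfg <- count_config(input_size = c(32, 32),
                      stages = list(c(4, 8), c(8, 16)))
  m <- build_lcnet(cfg, init_seed = 6)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  out <- lcnet:::nn_forward(m, x)
  expect_equal(dim(out), c(3L, 1L))
  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  masks <- lapply(1:3, function(i) matrix(rbinom(1024, 1, 0.3), 32, 32))
  p1 <- predict_count(m, imgs, masks)
  expect_length(p1, 3)
  expect_identical(p1, predict_count(m, imgs, masks))
  expect_equal(p1[2], predict_count(m, imgs[[2]], masks[[2]]),
               tolerance = 1e-12)
  expect_error(predict_count(m, imgs), "masks")
  # image-only ablation model accepts 3-channel input without masks
  m3 <- build_lcnet(count_config(input_size = c(32, 32), channels = 3,
                                 stages = list(c(4, 8), c(8, 16))))
  expect_length(predict_count(m3, imgs), 3)
  # parameters do not change under forward passes
  n0 <- count_parameters(m)
  invisible(lcnet:::nn_forward(m, x))
  expect_identical(count_parameters(m), n0)
})

test_that("smooth L1 matches closed forms and is smooth at the knee", {
  expect_equal(smooth_l1(5, 5), 0)
  expect_equal(smooth_l1(5.5, 5), 0.125)   # 0.5 * 0.5^2
  expect_equal(smooth_l1(7, 5), 1.5)       # |2| - 0.5
  expect_equal(smooth_l1(c(5.5, 7), c(5, 5)), (0.125 + 1.5) / 2)
  expect_error(smooth_l1(1:3, 1:2), "lengths")
  expect_error(smooth_l1(1, 1, delta = 0), "delta")
  # continuity and matching one-sided slopes at |d| = delta
  delta <- 1
  eps <- 1e-6
  below <- smooth_l1(delta - eps, 0, delta)
  above <- smooth_l1(delta + eps, 0, delta)
  expect_equal(below, above, tolerance = 1e-5)
  slope_below <- (smooth_l1(delta - eps, 0, delta) -
                  smooth_l1(delta - 2 * eps, 0, delta)) / eps
  slope_above <- (smooth_l1(delta + 2 * eps, 0, delta) -
                  smooth_l1(delta + eps, 0, delta)) / eps
  expect_equal(slope_below, slope_above, tolerance = 1e-4)
})

test_that("round_count rounds half away from zero and clamps at zero", {
  expect_identical(round_count(3.49), 3L)
  expect_identical(round_count(2.5), 3L)
  expect_identical(round_count(3.5), 4L)
  expect_identical(round_count(-0.2), 0L)
  expect_identical(round_count(-5), 0L)
  expect_identical(round_count(c(0.4, 0.5, 6.49)), c(0L, 1L, 6L))
  expect_error(round_count(Inf), "finite")
  expect_error(round_count(NA_real_), "finite")
})

test_that("bottlenecked triple-3x3 stages undercut a same-width 5x5 conv", {
  # per stage (p, w): [1x1 w->p] + [3x3 p->w] + 2x[3x3 w->w] (each with BN)
  # vs a single 5x5 w->w conv block -- the parameter-economy rationale.
  for (s in count_config(preset = "paper")$stages) {
    p <- s[1]; w <- s[2]
    stack <- (w * p + 2 * p) + (9 * p * w + 2 * w) + 2 * (9 * w * w + 2 * w)
    single5 <- 25 * w * w + 2 * w
    expect_lt(stack, single5)
  }
})

test_that("counter training is seeded and validates its inputs", {
  fx <- tiny_dataset()
  cfg <- count_config(input_size = c(32, 32),
                      stages = list(c(3, 6), c(6, 12)))
  tc <- train_config(epochs = 3, batch_size = 8, lr = 2e-3, seed = 4,
                     mask_source = "ground_truth")
  m1 <- build_lcnet(cfg, init_seed = 8)
  f1 <- train_counter(m1, fx$manifest, fx$dir, tc)
  expect_equal(nrow(f1$history), 3)
  m2 <- build_lcnet(cfg, init_seed = 8)
  f2 <- train_counter(m2, fx$manifest, fx$dir, tc)
  expect_identical(f1$history, f2$history)

  nocount <- fx$manifest
  nocount$count <- NA_integer_
  expect_error(train_counter(build_lcnet(cfg), nocount, fx$dir, tc),
               "counts")
  tc_seg <- train_config(epochs = 1, mask_source = "segmenter")
  expect_error(train_counter(build_lcnet(cfg), fx$manifest, fx$dir, tc_seg),
               "seg_model")
})

test_that("counter trains against segmenter-predicted masks end to end", {
  fx <- tiny_dataset()
  seg <- build_segnet(seg_config(input_size = c(32, 32),
                                 stages = list(c(1, 4))), init_seed = 2)
  seg_fit <- train_segmenter(seg, fx$manifest, fx$dir,
                             train_config(epochs = 2, batch_size = 8,
                                          seed = 3))
  cm <- build_lcnet(count_config(input_size = c(32, 32),
                                 stages = list(c(3, 6), c(6, 12))),
                    init_seed = 1)
  fit <- train_counter(cm, fx$manifest, fx$dir,
                       train_config(epochs = 2, batch_size = 8, seed = 5,
                                    mask_source = "segmenter"),
                       seg_model = seg_fit$model)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
})
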