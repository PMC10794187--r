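# Run configuration, the command surface behind the `lcnet` CLI script,
# and the two canned experiments: the desk-scale pipeline replication and
# the combined-input ablation. Every artifact written embeds the config
# hash and seed so a run can be reconstructed from its outputs.

#' Preset run configurations
#'
#' `"desk"` is the CPU-scale study regime: 64 x 64 synthetic images, 200
#' train / 50 validation / 100 test samples, reduced network widths (the
#' counter runs on 32 x 32 resized input), 8 segmentation epochs and 15
#' counting epochs. `"paper"` mirrors the
#' full-scale regime (224 x 224, 2010 images split 1410/300/300, VGG-style
#' segmenter, the 5M-parameter counter width schedule); it is provided for
#' completeness and parameter accounting, not for CPU training.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed Global seed recorded in the config and used to derive all
#'   stage seeds.
#' @return A nested `run_config` list with sections `sim`, `data`, `seg`,
#'   `count`.
#' @export
preset_config <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  check_number(seed, "seed", integer = TRUE)
  seed <- as.integer(seed)
  cfg <- if (preset == "desk") {
    list(
      preset = "desk", seed = seed,
      sim = list(preset = "easy", n_images = 350, canvas = c(64, 64),
                 seed = seed),
      data = list(fractions = c(200 / 350, 50 / 350, 100 / 350),
                  augment_k = 0, target = c(64, 64)),
      seg = list(input_size = c(64, 64), stages = list(c(2, 8), c(2, 16)),
                 epochs = 8, batch_size = 16, lr = 1e-3, lr_decay = 0.97),
      count = list(input_size = c(32, 32), channels = 4,
                   stages = list(c(6, 12), c(12, 24), c(24, 48)),
                   epochs = 15, batch_size = 16, lr = 2e-3, lr_decay = 0.97,
                   huber_delta = 1.0, mask_source = "ground_truth")
    )
  } else {
    list(
      preset = "paper", seed = seed,
      sim = list(preset = "easy", n_images = 2010, canvas = c(224, 224),
                 seed = seed),
      data = list(fractions = c(1410 / 2010, 300 / 2010, 300 / 2010),
                  augment_k = 1, target = c(224, 224)),
      seg = list(preset = "paper", epochs = 20, batch_size = 32, lr = 1e-3,
                 lr_decay = 1.0),
      count = list(preset = "paper", channels = 4, epochs = 60,
                   batch_size = 32, lr = 1e-3, lr_decay = 1.0,
                   huber_delta = 1.0, mask_source = "segmenter")
    )
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration
#'
#' Expands the preset, then overlays the YAML/JSON config file (if any),
#' then the explicit overrides -- so precedence is
#' overrides > file > preset.
#'
#' @param path Optional YAML or JSON config file.
#' @param preset Base preset name.
#' @param overrides Named nested list of final overrides.
#' @param seed Optional seed override.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL, preset = "desk",
                            overrides = list(), seed = NULL) {
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: '%s'", path)
    from_file <- if (tolower(tools::file_ext(path)) == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    preset <- from_file$preset %||% preset
  }
  cfg <- preset_config(preset, seed %||% from_file$seed %||% 1L)
  cfg <- merge_config(cfg, from_file)
  cfg <- merge_config(cfg, overrides)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

# Recursive config overlay: fully-named lists merge key-wise; anything
# else (scalars, vectors, unnamed lists such as stage schedules) replaces
# the base value wholesale.
merge_config <- function(base, override) {
  if (is.list(override) && length(override) == 0) return(base)
  named_list <- function(x) {
    is.list(x) && length(x) > 0 && !is.null(names(x)) &&
      all(nzchar(names(x)))
  }
  if (!named_list(base) || !named_list(override)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (is.null(base[[nm]])) {
      override[[nm]]
    } else {
      merge_config(base[[nm]], override[[nm]])
    }
  }
  base
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

run_sim_params <- function(cfg) {
  args <- cfg$sim
  args$seed <- args$seed %||% cfg$seed
  if (!is.null(args$preset)) {
    pr <- args$preset
    args$preset <- NULL
    do.call(sim_params_preset, c(list(preset = pr), args))
  } else {
    do.call(sim_params, args)
  }
}

#' Generate and split a synthetic dataset (CLI: `simulate`)
#'
#' Wraps [generate_dataset()] and [split_dataset()], prints a summary
#' (sample count and leaf-count histogram), and stores the config hash
#' next to the manifest.
#'
#' @param config A `run_config` from [load_run_config()].
#' @param out_dir Output directory.
#' @return Path of the written manifest, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  params <- run_sim_params(config)
  manifest <- generate_dataset(params, out_dir)
  manifest <- split_dataset(manifest, config$data$fractions,
                            seed = config$seed)
  if ((config$data$augment_k %||% 0) > 0) {
    train <- manifest[manifest$split == "train", ]
    rest <- manifest[manifest$split != "train", ]
    train <- expand_with_augmentation(train, out_dir,
                                      config$data$augment_k,
                                      seed = config$seed)
    manifest <- rbind(train, rest)
  }
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, path)
  meta <- list(config_hash = config_hash(config), seed = config$seed,
               n = nrow(manifest))
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE)
  message(sprintf("wrote %d samples to %s", nrow(manifest), out_dir))
  tab <- table(manifest$count)
  message("leaf-count histogram: ",
          paste(sprintf("%s:%d", names(tab), tab), collapse = "  "))
  invisible(path)
}

train_cfg_from <- function(section, global_seed, seed_offset = 0L) {
  train_config(
    epochs = section$epochs %||% 10,
    batch_size = section$batch_size %||% 16,
    lr = section$lr %||% 1e-3,
    seed = hash_seed(global_seed, seed_offset),
    huber_delta = section$huber_delta %||% 1.0,
    mask_source = section$mask_source %||% "ground_truth",
    lr_decay = section$lr_decay %||% 1.0,
    verbose = isTRUE(section$verbose)
  )
}

model_cfg_args <- function(section) {
  section[setdiff(names(section),
                  c("epochs", "batch_size", "lr", "lr_decay", "huber_delta",
                    "mask_source", "verbose"))]
}

#' Train the segmentation model (CLI: `train-seg`)
#'
#' @param config A `run_config`.
#' @param data_dir Dataset directory containing `manifest.csv`.
#' @param out_dir Run directory for the checkpoint, sidecar config JSON
#'   and per-epoch history CSV.
#' @return List with `checkpoint`, `history_csv` and the final `history`
#'   data frame.
#' @export
cmd_train_seg <- function(config, data_dir, out_dir = data_dir) {
  manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(seg_config, model_cfg_args(config$seg))
  model <- build_segnet(scfg, init_seed = hash_seed(config$seed, 101))
  tcfg <- train_cfg_from(config$seg, config$seed, 1L)
  fit <- train_segmenter(model, manifest, data_dir, tcfg)
  ckpt <- file.path(out_dir, "segnet.rds")
  save_checkpoint(fit$model, ckpt)
  hist_csv <- file.path(out_dir, "seg_history.csv")
  hist <- fit$history
  hist$seed <- tcfg$seed
  hist$config_hash <- config_hash(config)
  utils::write.csv(hist, hist_csv, row.names = FALSE)
  list(checkpoint = ckpt, history_csv = hist_csv, history = fit$history)
}

#' Train the counting model (CLI: `train-count`)
#'
#' @inheritParams cmd_train_seg
#' @param seg_checkpoint Segmenter checkpoint, required when
#'   `config$count$mask_source == "segmenter"`.
#' @return List with `checkpoint`, `history_csv` and `history`.
#' @export
cmd_train_count <- function(config, data_dir, out_dir = data_dir,
                            seg_checkpoint = NULL) {
  manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ccfg <- do.call(count_config, model_cfg_args(config$count))
  model <- build_lcnet(ccfg, init_seed = hash_seed(config$seed, 202))
  tcfg <- train_cfg_from(config$count, config$seed, 2L)
  seg_model <- if (!is.null(seg_checkpoint)) load_checkpoint(seg_checkpoint)
  fit <- train_counter(model, manifest, data_dir, tcfg, seg_model)
  ckpt <- file.path(out_dir, "lcnet.rds")
  save_checkpoint(fit$model, ckpt)
  hist_csv <- file.path(out_dir, "count_history.csv")
  hist <- fit$history
  hist$seed <- tcfg$seed
  hist$config_hash <- config_hash(config)
  utils::write.csv(hist, hist_csv, row.names = FALSE)
  list(checkpoint = ckpt, history_csv = hist_csv, history = fit$history)
}

#' Predict counts for a split (CLI: `predict`)
#'
#' Writes a CSV `image_path,raw_prediction,rounded_count`.
#'
#' @param checkpoint Counter checkpoint path.
#' @param data_dir Dataset directory with `manifest.csv`.
#' @param out_csv Output CSV path.
#' @param split Manifest split to predict.
#' @param seg_checkpoint Segmenter checkpoint; when given, mask channels
#'   come from its predictions, otherwise from the ground-truth masks.
#' @return The predictions as a data frame, invisibly.
#' @export
cmd_predict <- function(checkpoint, data_dir, out_csv, split = "test",
                        seg_checkpoint = NULL) {
  model <- load_checkpoint(checkpoint)
  manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  recs <- manifest[manifest$split == split, ]
  if (!nrow(recs)) stop_config("no records in split '%s'", split)
  samples <- load_samples(manifest, data_dir, split,
                          target = model$config$input_size)
  rgbs <- lapply(samples, `[[`, "rgb")
  masks <- NULL
  if (model$config$channels == 4L) {
    masks <- if (!is.null(seg_checkpoint)) {
      predict_mask(load_checkpoint(seg_checkpoint), rgbs)
    } else {
      lapply(samples, `[[`, "mask")
    }
  }
  raw <- predict_count(model, rgbs, masks)
  out <- data.frame(image_path = recs$image_path, raw_prediction = raw,
                    rounded_count = round_count(raw),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Evaluate a trained counter on a split (CLI: `evaluate`)
#'
#' Predicts the split, computes the counting metrics and writes a JSON
#' report embedding the config hash and seed.
#'
#' @inheritParams cmd_predict
#' @param config A `run_config` (for the report metadata).
#' @param out_json Report path.
#' @return The `count_metrics_report`, invisibly.
#' @export
cmd_evaluate <- function(config, checkpoint, data_dir, out_json,
                         split = "test", seg_checkpoint = NULL) {
  pred_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(pred_csv))
  cmd_predict(checkpoint, data_dir, pred_csv, split, seg_checkpoint)
  manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  report <- evaluate_counts(pred_csv, manifest, split)
  write_metrics_report(report, out_json,
                       extra = list(split = split, n = report$n,
                                    config_hash = config_hash(config),
                                    seed = config$seed))
  invisible(report)
}

# One counter training + test evaluation; shared by the ablation arms.
train_and_test_counter <- function(config, data_dir, channels, seed) {
  manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
  section <- config$count
  section$channels <- channels
  ccfg <- do.call(count_config, model_cfg_args(section))
  model <- build_lcnet(ccfg, init_seed = hash_seed(seed, 202))
  tcfg <- train_cfg_from(section, seed, 2L)
  fit <- train_counter(model, manifest, data_dir, tcfg)
  test <- load_samples(manifest, data_dir, "test",
                       target = ccfg$input_size)
  rgbs <- lapply(test, `[[`, "rgb")
  masks <- if (channels == 4L) lapply(test, `[[`, "mask")
  raw <- predict_count(fit$model, rgbs, masks)
  gt <- vapply(test, `[[`, 1, "count")
  list(report = count_metrics(round_count(raw), gt, raw = raw),
       history = fit$history, model = fit$model)
}

#' Combined-input ablation (CLI: `ablation`)
#'
#' Trains matched 4-channel (RGB + ground-truth mask) and 3-channel
#' (RGB only) counters on identical data, seeds and budgets, evaluates
#' both on the test split, and reports the per-seed pair of counting
#' reports plus the absolute-DiC difference. With several seeds, medians
#' across seeds are also reported.
#'
#' @param config A `run_config`.
#' @param data_dir Dataset directory with `manifest.csv`.
#' @param out_json Optional path for the paired JSON report.
#' @param seeds Integer vector of run seeds.
#' @return List with `per_seed` (each: `combined`, `image_only`,
#'   `abs_dic_diff`), `median_abs_dic_combined`,
#'   `median_abs_dic_image_only`.
#' @export
cmd_ablation <- function(config, data_dir, out_json = NULL,
                         seeds = config$seed) {
  per_seed <- lapply(seeds, function(s) {
    comb <- train_and_test_counter(config, data_dir, 4L, s)
    imgo <- train_and_test_counter(config, data_dir, 3L, s)
    list(seed = s, combined = comb$report, image_only = imgo$report,
         abs_dic_diff = comb$report$abs_dic - imgo$report$abs_dic)
  })
  result <- list(
    per_seed = per_seed,
    median_abs_dic_combined =
      stats::median(vapply(per_seed, function(r) r$combined$abs_dic, 1)),
    median_abs_dic_image_only =
      stats::median(vapply(per_seed, function(r) r$image_only$abs_dic, 1))
  )
  if (!is.null(out_json)) {
    payload <- list(
      task = "combined-input ablation",
      config_hash = config_hash(config), seeds = seeds,
      per_seed = lapply(per_seed, function(r) {
        list(seed = r$seed, combined = unclass(r$combined),
             image_only = unclass(r$image_only),
             abs_dic_diff = r$abs_dic_diff)
      }),
      median_abs_dic_combined = result$median_abs_dic_combined,
      median_abs_dic_image_only = result$median_abs_dic_image_only)
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  result
}
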