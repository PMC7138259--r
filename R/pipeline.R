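#' Shipped run configurations
#'
#' Two presets are provided:
#' \describe{
#'   \item{`"paper"`}{the full-scale conditions: 1392 x 1040 frames, 512-px
#'     tiles, positive cap 20, learning rate 1e-5 with staircase decay 0.9
#'     every 10,000 steps, lambda 0.001, 1000 epochs, batch size 3 (1 for
#'     class P), a 30 x 30 inference grid, and threshold 0.5. Faithful to
#'     the full-scale protocol but far too expensive for a CPU session.}
#'   \item{`"desk"`}{CPU-scale conditions used by the package's own test
#'     suite: 256 x 256 phantoms (6 training + 2 test frames), 64-px tiles
#'     at stride 32 with positive cap 6, a depth-2/base-8 network, learning
#'     rate 1e-3 with staircase decay 0.9 every 1000 steps, 200 epochs,
#'     batch 3, an 8 x 8 grid, threshold 0.5, and the two high-contrast
#'     classes O and P. The higher learning rate compensates for running
#'     ~3000 optimizer steps instead of hundreds of thousands.}
#' }
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed global pipeline seed.
#' @return a run-configuration list (class `run_config`).
#' @export
preset_config <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(
      seed = as.integer(seed),
      classes = c("O", "P"),
      phantom = list(preset = "desk", train_frames = 6L, test_frames = 2L),
      sampler = list(tile_size = 64L, max_positive = 6L, stride = 32L,
                     min_positive_pixels = 1L),
      augment = list(rot90 = TRUE, flips = TRUE, brightness = 0.1,
                     gamma = NULL),
      network = list(depth = 2L, base_filters = 8L, input_size = 64L),
      training = list(lr0 = 1e-3, decay_rate = 0.9, decay_every = 1000L,
                      lambda_l2 = 0.001, epochs = 200L, batch_size = 3L,
                      batch_size_overrides = list()),
      grid = list(n_per_axis = 8L, tile_size = 64L),
      evaluation = list(threshold = 0.5))
  } else {
    list(
      seed = as.integer(seed),
      classes = c("P", "S", "I", "IP", "O", "R"),
      phantom = list(preset = "full", train_frames = 34L, test_frames = 2L),
      sampler = list(tile_size = 512L, max_positive = 20L, stride = 64L,
                     min_positive_pixels = 1L),
      augment = list(rot90 = TRUE, flips = TRUE, brightness = 0.1,
                     gamma = NULL),
      network = list(depth = 4L, base_filters = 64L, input_size = 512L),
      training = list(lr0 = 1e-5, decay_rate = 0.9, decay_every = 10000L,
                      lambda_l2 = 0.001, epochs = 1000L, batch_size = 3L,
                      batch_size_overrides = list(P = 1L)),
      grid = list(n_per_axis = 30L, tile_size = 512L),
      evaluation = list(threshold = 0.5))
  }
  structure(cfg, class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a run-configuration list.
#' @return `load_run_config` returns the configuration (class `run_config`).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Structural and invariant checks across every block — with no side
#' effects. Returns a character vector of violations; an empty vector means
#' the configuration is valid.
#'
#' @param cfg a run-configuration list, or a path to a YAML file.
#' @return character vector of violations (possibly empty).
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  need <- c("seed", "classes", "phantom", "sampler", "augment", "network",
            "training", "grid", "evaluation")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    return(paste("missing config block(s):", paste(missing, collapse = ", ")))
  }
  sch <- schema_labels(default_schema())
  if (!length(cfg$classes)) add("classes: at least one class is required")
  bad <- setdiff(cfg$classes, sch)
  if (length(bad)) add(paste("classes: unknown label(s)",
                             paste(bad, collapse = ", ")))
  s <- cfg$sampler
  if (s$tile_size < 1) add("sampler: tile_size must be >= 1")
  if (s$max_positive < 0) add("sampler: max_positive must be >= 0")
  if (s$stride < 1) add("sampler: stride must be >= 1")
  n <- cfg$network
  if (n$depth < 1) add("network: depth must be >= 1")
  if (n$input_size %% (2^n$depth) != 0)
    add(sprintf("network: input_size %d not divisible by 2^depth = %d",
                n$input_size, 2^n$depth))
  if (n$input_size != s$tile_size)
    add("network: input_size must equal sampler tile_size")
  t <- cfg$training
  if (t$lr0 <= 0) add("training: lr0 must be positive")
  if (t$decay_rate <= 0) add("training: decay_rate must be positive")
  if (t$decay_every < 1) add("training: decay_every must be >= 1")
  if (t$lambda_l2 < 0) add("training: lambda_l2 must be >= 0")
  if (t$epochs < 1) add("training: epochs must be >= 1")
  if (t$batch_size < 1) add("training: batch_size must be >= 1")
  a <- cfg$augment
  if (a$brightness < 0 || a$brightness > 1)
    add("augment: brightness must be in [0, 1]")
  g <- cfg$grid
  if (g$n_per_axis < 1) add("grid: n_per_axis must be >= 1")
  if (g$tile_size != n$input_size)
    add("grid: tile_size must equal network input_size")
  e <- cfg$evaluation
  if (e$threshold < 0 || e$threshold > 1)
    add("evaluation: threshold must be in [0, 1]")
  ph <- cfg$phantom
  if ((ph$train_frames %||% 1) < 1) add("phantom: train_frames must be >= 1")
  if ((ph$test_frames %||% 1) < 1) add("phantom: test_frames must be >= 1")
  v
}

phantom_config_from_block <- function(block, seed = NULL) {
  phantom_config(preset = block$preset %||% "desk",
                 frame_size = block$frame_size,
                 n_vessels = block$n_vessels, n_cells = block$n_cells,
                 n_invasive = block$n_invasive,
                 n_spheroids = block$n_spheroids,
                 spike_density = block$spike_density,
                 halo_width = block$halo_width,
                 noise_level = block$noise_level %||% 0.03,
                 seed = seed)
}

#' Run the full pipeline: synth, sample, train, predict, evaluate
#'
#' For each configured class: builds its balanced tile dataset from the
#' training frames, trains its own network, predicts every held-out test
#' frame with overlapping-grid stitching, and evaluates against the test
#' ground truth. Test frames are generated from seeds disjoint from the
#' training frames'. Evaluation rows are reported per test frame and pooled
#' over all test-frame pixels.
#'
#' When `out_dir` is given, every artifact needed to reproduce or resume
#' the run is persisted: the resolved configuration, per-class training
#' history CSVs and checkpoints, probability and coverage maps (16-bit
#' TIFF), thresholded masks, error overlays, and the report as JSON + CSV.
#'
#' @param cfg a run-configuration list (see [preset_config()]) or a YAML
#'   path.
#' @param out_dir artifact directory, or `NULL` for no files.
#' @param verbose print stage progress.
#' @return list with `report` (data.frame; pooled rows have
#'   `frame == "pooled"`), `histories`, `params` (per-class), and
#'   `manifests`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = FALSE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  violations <- validate_config(cfg)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_run_config(cfg, file.path(out_dir, "config.yaml"))
  }

  ph_cfg <- phantom_config_from_block(cfg$phantom)
  say("stage synth: %d train + %d test frames (%dx%d)",
      cfg$phantom$train_frames, cfg$phantom$test_frames,
      ph_cfg$frame_size[1], ph_cfg$frame_size[2])
  train_set <- generate_phantom_dataset(ph_cfg, cfg$phantom$train_frames,
                                        seed = derive_seed(cfg$seed, "train"),
                                        prefix = "train")
  test_set <- generate_phantom_dataset(ph_cfg, cfg$phantom$test_frames,
                                       seed = derive_seed(cfg$seed, "test"),
                                       prefix = "test")

  spec <- grid_spec(cfg$grid$n_per_axis, cfg$grid$tile_size)
  aug <- augment_config(cfg$augment$rot90, cfg$augment$flips,
                        cfg$augment$brightness, cfg$augment$gamma)
  threshold <- cfg$evaluation$threshold

  report_rows <- list()
  histories <- list()
  all_params <- list()
  for (lab in cfg$classes) {
    stage <- function(name) paste0("class ", lab, " / ", name)
    samp_cfg <- sampler_config(cfg$sampler$tile_size, cfg$sampler$max_positive,
                               cfg$sampler$stride,
                               cfg$sampler$min_positive_pixels,
                               seed = derive_seed(cfg$seed, "sampler", lab))
    dataset <- tryCatch(
      build_class_dataset(train_set$frames, lab, samp_cfg),
      error = function(e) stop("stage [", stage("make-dataset"), "] failed: ",
                               conditionMessage(e)))
    say("class %s: %d tiles (%d positive)", lab, length(dataset),
        sum(vapply(dataset, function(s) s$is_positive, TRUE)))
    if (!length(dataset)) {
      warning("class ", lab, " has no training tiles; skipped")
      next
    }
    bs <- cfg$training$batch_size_overrides[[lab]] %||% cfg$training$batch_size
    tr_cfg <- train_config(cfg$training$lr0, cfg$training$decay_rate,
                           cfg$training$decay_every, cfg$training$lambda_l2,
                           cfg$training$epochs, bs,
                           seed = derive_seed(cfg$seed, "train", lab))
    net_cfg <- network_config(cfg$network$depth, cfg$network$base_filters,
                              cfg$network$input_size)
    say("class %s: training %d epochs (batch %d)", lab,
        tr_cfg$epochs, tr_cfg$batch_size)
    fit <- tryCatch(
      train_class_network(dataset, tr_cfg, net_cfg, aug, verbose = verbose),
      error = function(e) stop("stage [", stage("train"), "] failed: ",
                               conditionMessage(e)))
    histories[[lab]] <- fit$history
    all_params[[lab]] <- fit$params

    if (!is.null(out_dir)) {
      cls_dir <- file.path(out_dir, lab)
      save_checkpoint(fit$params, file.path(cls_dir, "checkpoint"))
      write.csv(fit$history$epochs, file.path(cls_dir, "history.csv"),
                row.names = FALSE)
    }

    pooled_prob <- c(); pooled_gt <- c()
    for (fr in test_set$frames) {
      pmap <- predict_frame(fit$params, fr, spec)
      gt <- fr$masks[[lab]]
      ev <- evaluate_frame(stats::setNames(list(pmap), lab), fr,
                           threshold = threshold)
      ev$frame <- fr$id
      report_rows[[length(report_rows) + 1L]] <- ev
      pooled_prob <- c(pooled_prob, as.vector(pmap$prob))
      pooled_gt <- c(pooled_gt, as.vector(gt))
      if (!is.null(out_dir)) {
        cls_dir <- file.path(out_dir, lab)
        dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
        write_image(pmap$prob, file.path(cls_dir, paste0(fr$id, ".prob.tiff")),
                    bits = 16L)
        write_image(pmap$coverage / max(pmap$coverage),
                    file.path(cls_dir, paste0(fr$id, ".coverage.tiff")),
                    bits = 16L)
        pred <- binarize(pmap, threshold)
        write_mask(pred, file.path(cls_dir, paste0(fr$id, ".mask.png")))
        write_image(error_overlay(pred, gt),
                    file.path(cls_dir, paste0(fr$id, ".errors.png")))
        write_image(error_heatmap(pmap, gt, fr$image),
                    file.path(cls_dir, paste0(fr$id, ".heat.png")))
      }
    }
    # pooled over all test pixels
    pooled <- eval_pooled(pooled_prob, pooled_gt, lab, threshold)
    report_rows[[length(report_rows) + 1L]] <- pooled
  }
  report <- do.call(rbind, report_rows)
  if (!is.null(out_dir) && !is.null(report)) {
    write_report(report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "report.csv"))
  }
  list(report = report, histories = histories, params = all_params,
       manifests = list(train = train_set$manifest, test = test_set$manifest))
}

# Pooled-pixel evaluation row (vectors rather than frames).
eval_pooled <- function(scores, gt, lab, threshold) {
  pred <- as.integer(scores > threshold)
  g <- as.integer(gt != 0)
  cc <- list(tp = sum(pred & g), fp = sum(pred & !g),
             tn = sum(!pred & !g), fn = sum(!pred & g))
  absent <- sum(g) == 0
  ci <- auc_ci(matrix(scores, ncol = 1), matrix(g, ncol = 1))
  data.frame(class = lab,
             sensitivity = if (absent) 0 else as.numeric(sensitivity(cc)),
             specificity = as.numeric(specificity(cc)),
             dsc = if (absent) 0 else as.numeric(dsc(cc)),
             auc = ci$auc, auc_lo = ci$lo, auc_hi = ci$hi,
             threshold = threshold, class_absent = absent,
             frame = "pooled", stringsAsFactors = FALSE)
}
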