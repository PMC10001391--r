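# Pipeline orchestration: the synth/preprocess/train/evaluate/predict
# stages behind one entry point, with YAML configuration, schema checking
# and a reproducibility manifest per run.

default_config <- function() {
  list(
    seed = 0L,
    deterministic = TRUE,
    synth = list(n_cases = 4L, shape = c(64L, 64L, 32L)),
    preprocess = list(slice_index = NULL, sigma = 0.5, target = 64L),
    encoder = list(pretrained = FALSE, trainable = TRUE, channels = NULL),
    bifpn = list(channels = NULL, repeats = 1L, upsample_mode = "bilinear"),
    model = list(variant = "full", profile = "tiny", encoder = "vgg19",
                 decoder_channels = NULL, attention_channels = NULL,
                 fusion = "concat"),
    train = list(alpha0 = 1e-4, Ne = 350L, batch_size = 5L,
                 split_ratios = c(0.8, 0.1, 0.1), epochs = NULL),
    evaluate = list(spacing = c(1, 1))
  )
}

check_config_keys <- function(cfg, schema = default_config(), path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema))
      stop("unknown config key: '", full, "'")
    if (is.list(schema[[key]]) && !is.null(names(schema[[key]])) &&
        is.list(cfg[[key]]))
      check_config_keys(cfg[[key]], schema[[key]], full)
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]])))
      base[[key]] <- merge_config(base[[key]], override[[key]])
    else base[[key]] <- override[[key]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config NULL (defaults), a YAML file path, or a named list;
#'   partial configs are merged over the defaults.  Unknown keys raise an
#'   error naming the key.
#' @return complete configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  check_config_keys(config)
  merge_config(default_config(), config)
}

write_manifest <- function(out_dir, command, cfg, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("triunet")),
    seed = cfg$seed,
    config = cfg), extra)
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

build_model_from_config <- function(cfg) {
  profile <- model_profile(cfg$model$profile)
  if (!is.null(cfg$encoder$channels))
    profile$pyramid_channels <- as.integer(cfg$encoder$channels)
  if (!is.null(cfg$bifpn$channels))
    profile$pyramid_channels <- as.integer(cfg$bifpn$channels)
  if (!is.null(cfg$model$decoder_channels))
    profile$decoder_channels <- as.integer(cfg$model$decoder_channels)
  if (!is.null(cfg$model$attention_channels))
    profile$attention_channels <- as.integer(cfg$model$attention_channels)
  build_model(variant = cfg$model$variant, profile = profile,
              encoder = cfg$model$encoder, fusion = cfg$model$fusion,
              bifpn_repeats = cfg$bifpn$repeats,
              trainable_encoders = cfg$encoder$trainable,
              pretrained = cfg$encoder$pretrained,
              seed = cfg$seed)
}

load_case_dirs <- function(input_dir) {
  dirs <- list.dirs(input_dir, recursive = FALSE)
  dirs <- dirs[vapply(dirs, function(d)
    length(list.files(d, pattern = "\\.nii")) > 0, logical(1))]
  if (!length(dirs)) stop("no case directories found under ", input_dir)
  dirs
}

preprocess_dir <- function(input_dir, cfg) {
  dirs <- load_case_dirs(input_dir)
  pairs <- lapply(dirs, function(d)
    preprocess_case(read_case(d), slice_index = cfg$preprocess$slice_index,
                    sigma = cfg$preprocess$sigma,
                    target = cfg$preprocess$target))
  names(pairs) <- basename(dirs)
  pairs
}

#' Run one pipeline stage
#'
#' Commands: `"synth"` writes phantom cases to `out_dir`; `"preprocess"`
#' converts case directories under `input_dir` into slice/mask NIfTI pairs
#' in `out_dir`; `"train"` preprocesses, splits, trains and writes the
#' history CSV plus the best weights; `"evaluate"` compares predicted and
#' ground-truth label maps; `"predict"` writes a predicted label map (file
#' codes \{0,1,2,4\}) per case.  Every run writes a JSON manifest recording
#' the configuration and seeds.
#'
#' @param command one of `"synth"`, `"preprocess"`, `"train"`,
#'   `"evaluate"`, `"predict"`.
#' @param config configuration (path, list or NULL; see [load_config()]).
#' @param input_dir input directory (cases, or predictions for `evaluate`).
#' @param out_dir output directory.
#' @param gt_dir ground-truth directory for `evaluate`.
#' @param model optional prebuilt/pretrained model for `train`/`predict`.
#' @return command-specific result, invisibly (paths, history or metrics).
#' @export
run_pipeline <- function(command = c("synth", "preprocess", "train",
                                     "evaluate", "predict"),
                         config = NULL, input_dir = NULL, out_dir = NULL,
                         gt_dir = NULL, model = NULL) {
  command <- match.arg(command)
  cfg <- load_config(config)
  if (is.null(out_dir)) stop("out_dir is required")

  if (command == "synth") {
    dirs <- synthesize_cases(out_dir, n_cases = cfg$synth$n_cases,
                             shape = cfg$synth$shape, seed = cfg$seed)
    write_manifest(out_dir, command, cfg, list(cases = basename(dirs)))
    return(invisible(dirs))
  }

  if (is.null(input_dir)) stop("input_dir is required for ", command)

  if (command == "preprocess") {
    pairs <- preprocess_dir(input_dir, cfg)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(pairs)) {
      px <- file.path(out_dir, paste0(nm, "_input.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(unclass(pairs[[nm]]$x)), px)
      paths <- c(paths, px)
      if (!is.null(pairs[[nm]]$y)) {
        py <- file.path(out_dir, paste0(nm, "_labels.nii.gz"))
        RNifti::writeNifti(RNifti::asNifti(
          remap_labels_to_file(pairs[[nm]]$y), datatype = "int16"), py)
        paths <- c(paths, py)
      }
    }
    write_manifest(out_dir, command, cfg, list(n_pairs = length(pairs)))
    return(invisible(paths))
  }

  if (command == "train") {
    pairs <- preprocess_dir(input_dir, cfg)
    split <- split_dataset(names(pairs), cfg$train$split_ratios, cfg$seed)
    if (is.null(model)) model <- build_model_from_config(cfg)
    tc <- train_config(alpha0 = cfg$train$alpha0, Ne = cfg$train$Ne,
                       batch_size = cfg$train$batch_size,
                       split_ratios = cfg$train$split_ratios,
                       seed = cfg$seed, epochs = cfg$train$epochs)
    history <- train_model(model, list(train = pairs[split$train],
                                       val = pairs[split$val]), tc)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(history),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
    saveRDS(net_state(model$net), file.path(out_dir, "weights.rds"))
    write_manifest(out_dir, command, cfg,
                   list(split = split, best_epoch = attr(history,
                                                         "best_epoch")))
    return(invisible(list(model = model, history = history, split = split)))
  }

  if (command == "evaluate") {
    if (is.null(gt_dir)) stop("gt_dir is required for evaluate")
    read_labels <- function(dir) {
      files <- sort(list.files(dir, pattern = "labels\\.nii", full.names = TRUE))
      if (!length(files)) stop("no *_labels.nii files under ", dir)
      lapply(files, function(f) {
        lab <- RNifti::readNifti(f)
        remap_labels_from_file(array(as.integer(round(lab)), dim(lab)))
      })
    }
    pred <- read_labels(input_dir)
    gt <- read_labels(gt_dir)
    report <- evaluate_predictions(pred, gt, cfg$evaluate$spacing)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, command, cfg, list(n_cases = length(pred)))
    return(invisible(report))
  }

  # predict
  if (is.null(model)) stop("predict requires a trained model object")
  pairs <- preprocess_dir(input_dir, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(pairs)) {
    lab <- predict_labels(model, pairs[[nm]]$x)
    p <- file.path(out_dir, paste0(nm, "_labels.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(remap_labels_to_file(lab),
                                       datatype = "int16"), p)
    paths <- c(paths, p)
  }
  write_manifest(out_dir, command, cfg, list(n_cases = length(paths)))
  invisible(paths)
}
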