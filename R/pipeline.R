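#' Read a pipeline run configuration
#'
#' Configurations are YAML with one section per stage (`synth`,
#' `preprocess`, `segment`, `augment`, `train`, `evaluate`) plus global
#' keys `seed` and `out_dir`. Unknown keys are rejected; defaults are
#' merged in and the effective configuration is echoed into the run
#' manifest.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides Named list merged over the file's values.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L, out_dir = "toothstage-run",
    synth = list(n_per_stage_per_cohort = 2L, clutter_level = 0.08,
                 impulse_noise_fraction = 0.02),
    preprocess = list(side = 250L, low_pct = 1, high_pct = 99, kernel = 7L,
                      clahe = FALSE),
    segment = list(enabled = TRUE, n_lines = 1200L, radius_length = 100,
                   delta = 3),
    augment = list(factor = 10L),
    train = list(optimizer = "adam", learning_rate = 1e-3, epochs = 10L,
                 batch_size = 8L, train_fraction = 0.8, input_side = 90L),
    evaluate = list()
  )
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_section <- function(def, usr, name) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown config key(s) in ", name, ": ",
           paste(unknown, collapse = ", "))
    utils::modifyList(def, usr)
  }
  top_unknown <- setdiff(names(user), names(defaults))
  if (length(top_unknown))
    stop("unknown config section(s): ", paste(top_unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]]))
      merge_section(defaults[[nm]], user[[nm]], nm)
    else user[[nm]]
  }
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

# per-stage seeds fan out from the global seed by fixed offsets, so one
# number reproduces a whole run
.stage_seed <- function(seed, stage) {
  offs <- c(synth = 101L, augment = 202L, split = 303L, train = 404L)
  as.integer((as.numeric(seed) + offs[[stage]]) %% 2147483647)
}

#' Run the full pipeline
#'
#' Executes, in order: phantom synthesis, preprocessing, segmentation
#' (optional — disabling it gives the unsegmented-crops ablation),
#' train/test split, augmentation of the training partition, classifier
#' training and evaluation. Artifacts and a JSON manifest (effective
#' config, seeds, per-stage wall time and metrics) are written under
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      .write_manifest(manifest, config$out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "completed",
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  data <- t_stage("synth", generate_phantom_set(
    config$synth$n_per_stage_per_cohort,
    seed = .stage_seed(config$seed, "synth"),
    clutter_level = config$synth$clutter_level,
    impulse_noise_fraction = config$synth$impulse_noise_fraction))

  data <- t_stage("preprocess", {
    pc <- config$preprocess
    dplyr::mutate(data, image = purrr::map(
      .data$image,
      ~ preprocess_roi(.x, side = pc$side, low_pct = pc$low_pct,
                       high_pct = pc$high_pct, kernel = pc$kernel,
                       clahe = pc$clahe)))
  })

  data <- t_stage("segment", {
    sc <- config$segment
    if (!sc$enabled) data
    else dplyr::mutate(data, image = purrr::map(
      .data$image,
      ~ segment_tooth(.x, n_lines = sc$n_lines,
                      radius_length = sc$radius_length,
                      config = dp_config(delta = sc$delta))$roi))
  })

  parts <- t_stage("split", split_dataset(
    data, config$train$train_fraction,
    seed = .stage_seed(config$seed, "split")))

  train_data <- t_stage("augment", expand_dataset(
    parts$train, augment_plan(factor = config$augment$factor),
    seed = .stage_seed(config$seed, "augment")))

  model <- t_stage("train", {
    tc <- config$train
    spec <- architecture_spec(input_side = tc$input_side)
    cfg <- train_config(optimizer = tc$optimizer,
                        learning_rate = tc$learning_rate,
                        epochs = tc$epochs, batch_size = tc$batch_size,
                        seed = .stage_seed(config$seed, "train"))
    train_stage_cnn(build_model(spec, seed = cfg$seed), train_data, cfg)
  })

  report <- t_stage("evaluate", evaluate_model(model, parts$test))

  write.csv(model$history, file.path(config$out_dir, "history.csv"),
            row.names = FALSE)
  manifest$metrics <- list(
    test_overall_accuracy = report$overall_accuracy,
    test_kappa = report$kappa,
    confusion_counts = unclass(report$counts))
  manifest$seed <- config$seed
  .write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
}
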