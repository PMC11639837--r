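# End-to-end orchestration: generate (or load) scenes, select bands
# with the firefly search, train the spectral classifier and a fusion
# detector, detect on held-out scenes and evaluate. Every stage writes
# its artifacts into the run directory and is skipped on rerun when its
# outputs already exist, so runs are resumable per stage.

#' Pipeline configuration
#'
#' All stage parameters in one place; the global seed propagates to
#' every stage. Defaults are desk-scale (60-band grid, small scenes)
#' so a full run completes on one CPU in minutes.
#'
#' @param output_dir run directory for artifacts.
#' @param n_bands grid size (desk default 60; 360 is the faithful
#'   grid).
#' @param n_scenes_train,n_scenes_test scene counts.
#' @param n_per_class spectra per class for band selection /
#'   classifier training.
#' @param firefly a [firefly_params()].
#' @param detector a [detector_config()] (its `bands` field is filled
#'   from the selection stage).
#' @param scene_height,scene_width scene size in pixels.
#' @param n_defects_range,defect_size_range passed to [scene_spec()].
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            n_bands = 60,
                            n_scenes_train = 24, n_scenes_test = 8,
                            n_per_class = 150,
                            firefly = firefly_params(max_iterations = 5,
                                                     eval_epochs = 4),
                            detector = detector_config(epochs = 20),
                            scene_height = 64, scene_width = 64,
                            n_defects_range = c(1, 3),
                            defect_size_range = c(10, 18),
                            seed = 1) {
  structure(list(output_dir = output_dir, n_bands = n_bands,
                 n_scenes_train = n_scenes_train, n_scenes_test = n_scenes_test,
                 n_per_class = n_per_class, firefly = firefly,
                 detector = detector, scene_height = scene_height,
                 scene_width = scene_width,
                 n_defects_range = n_defects_range,
                 defect_size_range = defect_size_range, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields keep their defaults; `firefly` and `detector`
#' sub-maps are passed to [firefly_params()] and [detector_config()].
#'
#' @param path YAML file path.
#' @param output_dir overrides the file's `output_dir` when not `NULL`.
#' @export
read_pipeline_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("firefly", "detector"))]
  if (!is.null(y$firefly)) {
    ff <- y$firefly
    # YAML 1.1 parses the bare key "n" as boolean FALSE; undo that
    names(ff)[names(ff) == "FALSE"] <- "n"
    args$firefly <- do.call(firefly_params, ff)
  }
  if (!is.null(y$detector)) args$detector <- do.call(detector_config, y$detector)
  if (!is.null(output_dir)) args$output_dir <- output_dir
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Stages, in order: `simulate` (spectra + annotated scenes),
#' `select-bands` (firefly search), `train-spectral`, `train-detector`,
#' `detect`, `evaluate`. Each stage's outputs land in
#' `cfg$output_dir`; a manifest (config, seed, package version) is
#' written first. Completed stages are detected by their output files
#' and skipped on rerun.
#'
#' @param cfg a [pipeline_config()].
#' @param profiles class profiles used by the generator.
#' @param verbose print stage progress to stderr.
#' @return list with the stage artifacts (`selection`, `spectral`,
#'   `detector_model`, `detections`, `report`) and the run directory.
#' @export
run_pipeline <- function(cfg, profiles = NULL, verbose = TRUE) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_hsd(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                "hsd_pipeline_error"))
  }
  grid <- if (cfg$n_bands == 360) default_grid() else desk_grid(cfg$n_bands)
  if (is.null(profiles)) profiles <- default_profiles(grid)
  manifest <- list(package = "hsdefect",
                   version = as.character(utils::packageVersion("hsdefect")),
                   seed = cfg$seed,
                   config = rapply(unclass(cfg), identity, how = "list"))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  log_msg("[simulate] generating spectra and scenes")
  sim <- stage("simulate", {
    spectra <- generate_spectrum_dataset(profiles, cfg$n_per_class, grid,
                                         seed = cfg$seed)
    mk_scene <- function(i) generate_scene(
      scene_spec(cfg$scene_height, cfg$scene_width, grid,
                 n_defects_range = cfg$n_defects_range,
                 defect_size_range = cfg$defect_size_range,
                 seed = cfg$seed + i),
      profiles)
    train_scenes <- lapply(seq_len(cfg$n_scenes_train), mk_scene)
    test_scenes <- lapply(cfg$n_scenes_train + seq_len(cfg$n_scenes_test), mk_scene)
    write_spectrum_csv(spectra, file.path(cfg$output_dir, "spectra.csv"))
    list(spectra = spectra, train = train_scenes, test = test_scenes)
  })

  sel_path <- file.path(cfg$output_dir, "selection.json")
  log_msg("[select-bands] firefly search")
  selection <- stage("select-bands", {
    fp <- cfg$firefly
    fp$seed <- cfg$seed
    res <- run_selection(sim$spectra, fp)
    write_selection_json(res, grid, sel_path,
                         history_csv = file.path(cfg$output_dir, "selection_history.csv"))
    res
  })
  bands <- selection$best$position

  log_msg("[train-spectral] 1-D CNN on selected-band spectra")
  spectral <- stage("train-spectral", {
    sp_cfg <- spectral_net_preset_scaled(input_length = cfg$n_bands,
                                         n_classes = length(unique(sim$spectra$labels)),
                                         seed = cfg$seed)
    masked <- list(spectra = mask_spectra(sim$spectra$spectra, bands),
                   labels = sim$spectra$labels)
    m <- train_classifier(masked, sp_cfg)
    save_spectral_net(m, file.path(cfg$output_dir, "spectral_net.json"))
    utils::write.csv(m$history, file.path(cfg$output_dir, "spectral_history.csv"),
                     row.names = FALSE)
    m
  })

  log_msg("[train-detector] %s detector, fusion %s",
          cfg$detector$architecture, if (cfg$detector$fusion) "on" else "off")
  det_model <- stage("train-detector", {
    dc <- cfg$detector
    dc$bands <- bands
    dc$seed <- cfg$seed
    train_detector(sim$train, dc, spectral_model = spectral)
  })

  log_msg("[detect] %d test scenes", length(sim$test))
  detections <- stage("detect", {
    dets <- lapply(sim$test, function(s) detect(det_model, s))
    for (i in seq_along(dets))
      write_detections(dets[[i]],
                       file.path(cfg$output_dir, sprintf("detections_%03d.json", i)))
    dets
  })

  log_msg("[evaluate] metrics report")
  report <- stage("evaluate", {
    truths <- lapply(sim$test, `[[`, "truths")
    rep <- evaluation_report(detections, truths, det_model$classes,
                             iou_threshold = 0.5,
                             confidence_threshold = cfg$detector$confidence_threshold)
    writeLines(format_report_table(rep), file.path(cfg$output_dir, "report.txt"))
    jsonlite::write_json(
      list(per_class = rep$per_class, map = rep$map, miou = rep$miou,
           confusion = as.data.frame.matrix(rep$confusion)),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    rep
  })
  list(selection = selection, spectral = spectral, detector_model = det_model,
       detections = detections, report = report, run_dir = cfg$output_dir)
}
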