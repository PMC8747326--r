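# End-to-end pipeline driver: simulate -> preprocess -> extract ->
# select -> train -> evaluate, with reproducible artifacts.

PIPELINE_KEYS <- c("n_subjects", "exercises", "effect_scale", "seed",
                   "sensor_mode", "cv_folds", "max_subset_size",
                   "scaling", "bird_dog_sides", "write_sessions",
                   "write_plots", "out_dir", "noise_sd")

#' Pipeline configuration
#'
#' Validated, fully serializable run configuration: any run is
#' reproducible from the configuration plus its seed. Unknown keys are
#' rejected.
#'
#' @param n_subjects Cohort size.
#' @param exercises Character vector of exercise names.
#' @param effect_scale Multiplier on all TCM effect amplitudes.
#' @param seed Master seed for the whole run.
#' @param sensor_mode `"all"` for the 50-feature matrix or `"s1"`, `"s2"`,
#'   `"s3"` for a 16-feature single-sensor matrix.
#' @param cv_folds Cross-validation folds inside feature selection.
#' @param max_subset_size Cap on accepted features.
#' @param scaling `"as_is"` (z-score fit once on the full matrix) or
#'   `"train_only"` for leakage-free LOSO rescaling.
#' @param bird_dog_sides Simulate both Bird-Dog sides.
#' @param write_sessions Write every raw session CSV (slow; off by
#'   default).
#' @param write_plots Write per-exercise scatter plots (PNG).
#' @param out_dir Output directory.
#' @param noise_sd Sensor noise SD, m/s^2.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 30L,
                            exercises = c("prone_rocking", "bird_dog",
                                          "rowing"),
                            effect_scale = 1,
                            seed = 1L,
                            sensor_mode = "all",
                            cv_folds = 5L,
                            max_subset_size = 5L,
                            scaling = "as_is",
                            bird_dog_sides = FALSE,
                            write_sessions = FALSE,
                            write_plots = FALSE,
                            out_dir = tempfile("tcmdetect_run_"),
                            noise_sd = 0.25) {
  cfg <- list(n_subjects = as.integer(n_subjects), exercises = exercises,
              effect_scale = effect_scale, seed = as.integer(seed),
              sensor_mode = sensor_mode, cv_folds = as.integer(cv_folds),
              max_subset_size = as.integer(max_subset_size),
              scaling = scaling, bird_dog_sides = isTRUE(bird_dog_sides),
              write_sessions = isTRUE(write_sessions),
              write_plots = isTRUE(write_plots), out_dir = out_dir,
              noise_sd = noise_sd)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stopifnot(cfg$n_subjects >= 1, cfg$effect_scale >= 0,
            cfg$cv_folds >= 2, cfg$max_subset_size >= 1)
  if (!all(cfg$exercises %in% names(default_exercises())))
    stop("unknown exercise(s): ",
         paste(setdiff(cfg$exercises, names(default_exercises())),
               collapse = ", "))
  if (!cfg$sensor_mode %in% c("all", "s1", "s2", "s3"))
    stop("sensor_mode must be one of all, s1, s2, s3")
  if (!cfg$scaling %in% c("as_is", "train_only"))
    stop("scaling must be as_is or train_only")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys take the [pipeline_config()] defaults; unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Run the full detection pipeline
#'
#' Executes simulate -> preprocess -> extract -> select -> train ->
#' evaluate for every configured exercise and writes all artifacts
#' (manifest, per-exercise feature matrix, selection result, model JSON,
#' evaluation JSON, optional scatter plot) plus a log and an MD5 content
#' hash listing into `config$out_dir`.
#'
#' @param config A `pipeline_config` or the path of a YAML file.
#' @return Invisibly, a named list of per-exercise results
#'   (`feature_matrix`, `selection`, `model`, `cv_report`,
#'   `loso_report`) with the output directory as attribute `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  logf("tcmdetect %s | seed %d | %d subjects | effect_scale %g",
       as.character(utils::packageVersion("tcmdetect")), config$seed,
       config$n_subjects, config$effect_scale)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  model <- sensor_model(noise_sd = config$noise_sd)
  cohort <- stage("simulate", generate_cohort(
    n_subjects = config$n_subjects, exercises = config$exercises,
    model = model, effect_scale = config$effect_scale,
    master_seed = config$seed, bird_dog_sides = config$bird_dog_sides))
  utils::write.csv(cohort$manifest,
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  logf("simulate: %d recordings", nrow(cohort$manifest))
  if (config$write_sessions) {
    sess_dir <- file.path(config$out_dir, "sessions")
    dir.create(sess_dir, showWarnings = FALSE)
    for (i in seq_along(cohort$recordings)) {
      r <- cohort$recordings[[i]]
      fn <- sprintf("%s_%s%s_%s_set%d.csv", r$subject_id, r$exercise,
                    if (is.na(r$side)) "" else paste0("_", r$side),
                    r$category, r$set_index)
      write_session_csv(r, file.path(sess_dir, fn))
    }
  }

  sets <- stage("preprocess", preprocess_cohort(cohort))
  logf("preprocess: %d averaged sets", length(sets))

  mode <- if (config$sensor_mode == "all") "all_sensors" else "single_sensor"
  sensor <- if (mode == "single_sensor")
    as.integer(substring(config$sensor_mode, 2)) else NULL

  results <- list()
  for (ex in config$exercises) {
    ex_sets <- Filter(function(s) identical(s$exercise, ex), sets)
    fm <- stage("extract", build_feature_matrix(ex_sets, mode, sensor))
    write_feature_matrix_csv(fm, file.path(config$out_dir,
                                           sprintf("features_%s.csv", ex)))
    sel_cfg <- selection_config(max_subset_size = config$max_subset_size,
                                cv_folds = config$cv_folds,
                                rng_seed = derive_seed(config$seed, 7))
    sel <- stage("select", forward_select(fm, sel_cfg))
    jsonlite::write_json(
      list(exercise = ex, accepted_features = sel$accepted_features,
           step_losses = sel$step_losses,
           baseline_loss = sel$baseline_loss,
           candidate_evaluations = sel$candidate_evaluations,
           stopped_reason = sel$stopped_reason),
      file.path(config$out_dir, sprintf("selection_%s.json", ex)),
      auto_unbox = TRUE, digits = NA, null = "null")
    feats <- sel$accepted_features
    tree <- stage("train", if (length(feats))
      fit_cart(fm[feats], fm$category, features = feats)
      else fit_cart(fm["set_index"], fm$category, features = character(0)))
    write_model_json(tree, file.path(config$out_dir,
                                     sprintf("model_%s.json", ex)))
    cv_rep <- if (length(feats))
      evaluation_report(fm$category, predict(tree, fm)) else NULL
    loso <- stage("evaluate", loso_evaluate(fm, feats,
                                            scaling = config$scaling))
    jsonlite::write_json(
      list(exercise = ex, selected = feats,
           loso = list(accuracy = loso$accuracy,
                       sensitivity = loso$sensitivity,
                       specificity = loso$specificity,
                       confusion = as.list(loso$confusion)),
           resubstitution = if (is.null(cv_rep)) NULL else
             list(accuracy = cv_rep$accuracy)),
      file.path(config$out_dir, sprintf("evaluation_%s.json", ex)),
      auto_unbox = TRUE, digits = NA, null = "null")
    if (config$write_plots && length(feats)) {
      grDevices::png(file.path(config$out_dir,
                               sprintf("scatter_%s.png", ex)),
                     width = 700, height = 550)
      plot_decision_scatter(fm, feats[seq_len(min(2, length(feats)))],
                            tree = tree)
      grDevices::dev.off()
    }
    logf("%s: selected [%s], LOSO accuracy %.3f", ex,
         paste(feats, collapse = ", "), loso$accuracy)
    results[[ex]] <- list(feature_matrix = fm, selection = sel,
                          model = tree, cv_report = cv_rep,
                          loso_report = loso)
  }

  files <- setdiff(list.files(config$out_dir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(config$out_dir, "hashes.csv"))
  hashes <- data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  utils::write.csv(hashes[order(hashes$file), ],
                   file.path(config$out_dir, "hashes.csv"),
                   row.names = FALSE)
  attr(results, "out_dir") <- config$out_dir
  invisible(results)
}
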