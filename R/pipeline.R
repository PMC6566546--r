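#' Pipeline configuration
#'
#' Bundles the simulation settings with the segmentation, scoring and
#' classification options of an end-to-end run.
#'
#' @param simulation a [simulation_config()].
#' @param min_area segmentation minimum component area (pixels).
#' @param calibration_fraction fraction of each class's seeds used to train
#'   the scoring model and class ranges (the remainder is the validation
#'   set). With too few seeds, at least 2 per class are taken; if no seeds
#'   remain for validation the calibration set is evaluated on itself.
#' @param combine ventral/dorsal combination rule, `"max"` (severity-max,
#'   default) or `"mean"`.
#' @param max_pixels_per_tissue training-pixel cap per tissue role for the
#'   discriminant transform.
#' @param work_dir directory for intermediate artifacts (`NULL`: in-memory
#'   run, nothing written).
#' @param rng_seed integer master seed; overrides `simulation$rng_seed` so a
#'   single seed reproduces the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            min_area = 50,
                            calibration_fraction = 0.6,
                            combine = c("max", "mean"),
                            max_pixels_per_tissue = 1500,
                            work_dir = NULL,
                            rng_seed = simulation$rng_seed) {
  combine <- match.arg(combine)
  stopifnot(inherits(simulation, "simulation_config"),
            calibration_fraction > 0, calibration_fraction <= 1)
  simulation$rng_seed <- as.integer(rng_seed)
  structure(list(simulation = simulation, min_area = min_area,
                 calibration_fraction = calibration_fraction,
                 combine = combine,
                 max_pixels_per_tissue = max_pixels_per_tissue,
                 work_dir = work_dir, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are the [pipeline_config()] arguments; the `simulation` key
#' holds [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation
  if (!is.null(sim_args$image_size)) {
    sim_args$image_size <- as.integer(unlist(sim_args$image_size))
  }
  sim <- do.call(simulation_config, sim_args %||% list())
  y$simulation <- NULL
  do.call(pipeline_config, c(list(simulation = sim), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Feature-table text round trip with full double precision (%.17g), so
# stages re-run from disk reproduce in-memory results bit-for-bit.

#' Write a feature table as delimited text
#' @param features data.frame from [extract_features_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (nm in intersect(msi_feature_names(), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulate-to-evaluate pipeline
#'
#' Executes, in order: synthetic image simulation, seed segmentation,
#' discriminant-transform training on calibration tissue pixels, feature
#' extraction, scoring-model fit and class-range derivation on the
#' calibration split, ventral/dorsal classification of the validation split,
#' and confusion-matrix evaluation. Deterministic given `config$rng_seed`.
#' When `config$work_dir` is set, every stage boundary is written there
#' (dataset, feature table, model files, results table, report).
#'
#' @param config a [pipeline_config()].
#' @return list of class `msi_pipeline_result`: `report`
#'   (an `evaluation_report`), `results`, `ncda_model`, `scoring_model`,
#'   `ranges`, `features`, `scores`, `calibration_ids`, `separation`
#'   (minimum adjacent class-mean score gap in pooled within-class SD units),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  writing <- !is.null(config$work_dir)
  if (writing) dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- run_stage("simulate", generate_dataset(config$simulation))
  if (writing) run_stage("simulate", write_dataset(ds, config$work_dir))

  regions <- run_stage("segment", lapply(names(ds$stacks), function(id) {
    regs <- segment_seeds(ds$stacks[[id]], config$min_area)
    if (!length(regs)) stop("no seed found in ", id)
    regs[[which.max(vapply(regs, `[[`, 0, "area"))]]
  }))
  names(regions) <- names(ds$stacks)

  # per-class calibration/validation split at seed level
  tt <- ds$truth_table
  seeds <- unique(tt[, c("seed_id", "true_class")])
  calibration_ids <- unlist(lapply(sort(unique(seeds$true_class)), function(k) {
    ids <- seeds$seed_id[seeds$true_class == k]
    n_cal <- min(length(ids),
                 max(2, floor(config$calibration_fraction * length(ids))))
    ids[seq_len(n_cal)]
  }))
  validation_ids <- setdiff(seeds$seed_id, calibration_ids)
  if (!length(validation_ids)) validation_ids <- calibration_ids

  cal_rows <- tt$seed_id %in% calibration_ids
  ncda_model <- run_stage("transform", with_seed(config$rng_seed, {
    tp <- sample_tissue_pixels(ds$stacks[cal_rows], ds$truth[cal_rows],
                               config$max_pixels_per_tissue)
    fit_ncda(tp$x, tp$labels)
  }))
  ncda_model <- run_stage("transform", calibrate_damage_threshold(
    ncda_model, ds$stacks[cal_rows],
    lapply(ds$truth[cal_rows], `[[`, "mask"), tt$true_class[cal_rows]))
  if (writing) {
    write_ncda_model(ncda_model, file.path(config$work_dir, "ncda_model.txt"))
  }

  features <- run_stage("features",
    extract_features_table(ds$stacks, regions, tt, ncda_model))
  if (writing) {
    write_feature_table(features, file.path(config$work_dir, "features.tsv"))
  }

  cal_features <- features[features$seed_id %in% calibration_ids, ]
  scoring_model <- run_stage("train", fit_scoring_model(cal_features))
  scores <- run_stage("train", score_seeds(scoring_model, features))
  cal_scores <- scores[scores$seed_id %in% calibration_ids, ]
  ranges <- run_stage("train",
    derive_class_ranges(cal_scores$score, cal_scores$true_class,
                        expected_classes = 1:5))
  if (writing) {
    write_scoring_model(scoring_model,
                        file.path(config$work_dir, "scoring_model.txt"),
                        ranges = ranges)
  }

  # separation diagnostic: adjacent class-mean gaps in pooled-SD units
  cm <- vapply(1:5, function(k) {
    mean(cal_scores$score[cal_scores$true_class == k])
  }, 0)
  pooled_sd <- sqrt(mean(vapply(1:5, function(k) {
    stats::var(cal_scores$score[cal_scores$true_class == k])
  }, 0)))
  separation <- min(diff(sort(cm))) / pooled_sd

  val_scores <- scores[scores$seed_id %in% validation_ids, ]
  results <- run_stage("classify",
    classify_seeds(ranges, val_scores, config$combine))
  if (writing) {
    write_feature_table(results, file.path(config$work_dir, "results.tsv"))
  }

  report <- run_stage("evaluate", evaluation_report(results))
  if (writing) {
    write_evaluation_report(report, file.path(config$work_dir, "report.txt"))
  }

  structure(list(report = report, results = results,
                 ncda_model = ncda_model, scoring_model = scoring_model,
                 ranges = ranges, features = features, scores = scores,
                 calibration_ids = calibration_ids, separation = separation,
                 config = config),
            class = "msi_pipeline_result")
}

#' @export
print.msi_pipeline_result <- function(x, ...) {
  cat("End-to-end seed damage classification run\n")
  cat(sprintf("  separation: %.2f pooled SDs (min adjacent class-mean gap)\n",
              x$separation))
  print(x$report)
  invisible(x)
}

#' Re-fit the scoring stage from an on-disk feature table
#'
#' @param features_path feature table written by [write_feature_table()]
#'   (must carry `true_class` for the calibration rows used).
#' @param model_path output path for the scoring model + ranges.
#' @param calibration_ids seed ids to fit on (default: all rows).
#' @return list with `model` and `ranges`, invisibly.
#' @export
train_from_features <- function(features_path, model_path,
                                calibration_ids = NULL) {
  features <- read_feature_table(features_path)
  if (!is.null(calibration_ids)) {
    features <- features[features$seed_id %in% calibration_ids, ]
  }
  model <- fit_scoring_model(features)
  sc <- score_seeds(model, features)
  ranges <- derive_class_ranges(sc$score, sc$true_class)
  write_scoring_model(model, model_path, ranges = ranges)
  invisible(list(model = model, ranges = ranges))
}

#' Classify an on-disk feature table with an on-disk scoring model
#'
#' @param model_path scoring model file from [write_scoring_model()].
#' @param features_path feature table path.
#' @param results_path output results table path.
#' @param combine side-combination rule, see [classify_pair()].
#' @return the results data.frame, invisibly.
#' @export
classify_from_files <- function(model_path, features_path, results_path,
                                combine = c("max", "mean")) {
  ms <- read_scoring_model(model_path)
  if (is.null(ms$ranges)) stop("model file carries no class ranges")
  features <- read_feature_table(features_path)
  scores <- score_seeds(ms$model, features)
  results <- classify_seeds(ms$ranges, scores, match.arg(combine))
  write_feature_table(results, results_path)
  invisible(results)
}

#' Evaluate an on-disk results table
#'
#' @param results_path results table from [classify_from_files()] /
#'   [run_pipeline()].
#' @param report_path output report path.
#' @return the `evaluation_report`, invisibly.
#' @export
evaluate_from_files <- function(results_path, report_path) {
  results <- read_feature_table(results_path)
  report <- evaluation_report(results)
  write_evaluation_report(report, report_path)
  invisible(report)
}
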