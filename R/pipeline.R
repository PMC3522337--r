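#' Resolved pipeline configuration
#'
#' Gathers every tunable of the pipeline with its default, validating each
#' against the owning module's constraints.
#'
#' @param snake a [snake_params()].
#' @param air_threshold seeding threshold, HU.
#' @param subsample_step slice subsampling step for the volume feature.
#' @param prior prior mode for [airtrap_model()].
#' @param feature decision feature for [airtrap_model()].
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(snake = snake_params(), air_threshold = -320,
                       subsample_step = 17L,
                       prior = c("empirical", "equal"),
                       feature = c("volume", "area"), seed = 1L) {
  prior <- match.arg(prior)
  feature <- match.arg(feature)
  k <- as.integer(subsample_step)
  if (is.na(k) || k < 1L)
    abort("subsample_step must be a positive integer", "airtrapcad_parameter_error")
  if (!inherits(snake, "snake_params"))
    abort("snake must be snake_params", "airtrapcad_parameter_error")
  structure(list(snake = snake, air_threshold = air_threshold,
                 subsample_step = k, prior = prior, feature = feature,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Stable hash of a config for report provenance.
#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(lapply(unclass(config), unclass), file = f)
  unname(tools::md5sum(f))
}

#' Run the full diagnosis pipeline over a subject manifest
#'
#' For each subject: read both phase volumes, extract the air-trapping
#' features ([extract_features()]); then fit the Bayes model on the labelled
#' subjects ([airtrap_model()]), classify everyone, and - when true labels
#' exist - evaluate ([evaluate_predictions()]).  Per-subject stage failures
#' are collected and reported; the pipeline continues for the remaining
#' subjects.
#'
#' @param manifest data frame with columns `subject_id`, `insp_path`,
#'   `exp_path` and optionally `label`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   `model.json`, `labels.csv` and `report.json` there.
#' @return list with `features` (data frame), `model`, `predictions`,
#'   `evaluation` (or `NULL`), `failures` (named character vector), and
#'   `config_hash`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL) {
  need <- c("subject_id", "insp_path", "exp_path")
  if (!is.data.frame(manifest) || nrow(manifest) == 0L ||
      !all(need %in% names(manifest)))
    abort("manifest must be a non-empty data frame with subject_id, insp_path, exp_path",
          "airtrapcad_input_error")
  has_label <- "label" %in% names(manifest)
  feats <- list()
  failures <- character()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    row <- tryCatch({
      vi <- read_volume(manifest$insp_path[i], "inspiration", sid)
      ve <- read_volume(manifest$exp_path[i], "expiration", sid)
      extract_features(vi, ve, config$snake, config$air_threshold,
                       config$subsample_step, subject_id = sid,
                       label = if (has_label) as.character(manifest$label[i])
                               else NA_character_)
    }, airtrapcad_error = function(e) {
      failures[[sid]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) feats[[length(feats) + 1L]] <- row
  }
  if (!length(feats))
    abort("feature extraction failed for every subject",
          "airtrapcad_pipeline_error")
  features <- do.call(rbind, feats)
  labelled <- features[!is.na(features$label), , drop = FALSE]
  model <- NULL; predictions <- NULL; evaluation <- NULL
  if (nrow(labelled) >= 4L &&
      length(unique(labelled$label)) == 2L) {
    model <- airtrap_model(labelled, feature = config$feature,
                           prior = config$prior)
    predictions <- predict(model, features)
    if (nrow(labelled) == nrow(features))
      evaluation <- evaluate_predictions(predictions$label, features$label)
  }
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    if (!is.null(model)) write_model(model, file.path(out_dir, "model.json"))
    if (!is.null(predictions))
      write.csv(predictions, file.path(out_dir, "labels.csv"),
                row.names = FALSE)
    report <- list(config_hash = hash,
                   n_subjects = nrow(features),
                   failures = as.list(failures))
    if (!is.null(evaluation)) {
      report$confusion <- unclass(evaluation$confusion)
      report$metrics <- evaluation$metrics
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, model = model, predictions = predictions,
       evaluation = evaluation, failures = failures, config_hash = hash)
}
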