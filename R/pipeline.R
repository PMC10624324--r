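# Stage orchestration: simulate / extract / features / agreement /
# train+evaluate, chained by run_all() with a reproducible run manifest.
# Stages communicate through plain-text artifacts (OpenPose JSON-lines pose
# files, CSV tables, JSON models) under the configured output directory.

#' Build a run configuration
#'
#' Merges user settings over the package defaults. Accepts a YAML file path
#' or a nested list with any of the blocks `paths` (`pose_dir`,
#' `ratings_csv`, `output_dir`), `pose` (`missing_threshold`,
#' `max_gap_frames`, `fps`), `catalogue` (YAML override path), `features`
#' (`mode`), `agreement` (`kappa_min`, `min_minority`), `boost`
#' ([boost_params()] fields plus `cv_folds`), `simulate`
#' ([simulation_config()] fields), and a top-level `seed` that propagates to
#' every stochastic stage.
#'
#' @param config YAML path, nested list, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    paths = list(pose_dir = NULL, ratings_csv = NULL,
                 output_dir = "motionscreen_out"),
    pose = list(missing_threshold = 0.1, max_gap_frames = 5, fps = 30),
    catalogue = NULL,
    features = list(mode = "rom"),
    agreement = list(kappa_min = 0.41, min_minority = 8),
    boost = list(n_learners = 50, learning_rate = 0.1, max_depth = 3,
                 feature_subset = "sqrt", cv_folds = 5),
    simulate = list(),
    seed = 42,
    quiet = FALSE
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  merged <- utils::modifyList(defaults, config %||% list())
  class(merged) <- "run_config"
  merged
}

stage_log <- function(config, fmt, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(paste0("[motionscreen] ", fmt), ...))
}

cfg_catalogue <- function(config) {
  if (is.null(config$catalogue)) default_catalogue()
  else read_catalogue_yaml(config$catalogue)
}

out_path <- function(config, ...) {
  dir.create(config$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$paths$output_dir, ...)
}

#' Simulation stage
#'
#' Generates the synthetic cohort of [generate_dataset()] and writes its
#' pose sequences as OpenPose JSON-lines files under
#' `<output_dir>/pose/`, the true labels to `true_labels.csv` and the
#' simulated ratings (long format) to `ratings.csv`.
#'
#' @param config A [run_config()].
#' @return The dataset list, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  config <- run_config(config)
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(list(seed = config$seed), config$simulate))
  ds <- generate_dataset(sim_cfg)
  pose_dir <- out_path(config, "pose")
  dir.create(pose_dir, showWarnings = FALSE)
  for (nm in names(ds$sequences))
    write_openpose_jsonl(ds$sequences[[nm]], file.path(pose_dir, paste0(nm, ".jsonl")))
  truth <- data.frame(subject_id = sprintf("S%03d", seq_len(nrow(ds$true_labels))),
                      ds$true_labels, check.names = FALSE)
  utils::write.csv(truth, out_path(config, "true_labels.csv"), row.names = FALSE)
  long <- expand.grid(subject = seq_len(dim(ds$ratings)[1]),
                      rater = seq_len(dim(ds$ratings)[2]),
                      parameter = dimnames(ds$ratings)[[3]],
                      stringsAsFactors = FALSE)
  long <- data.frame(subject_id = sprintf("S%03d", long$subject),
                     rater_id = sprintf("R%d", long$rater),
                     parameter = long$parameter,
                     rating = as.integer(ds$ratings[cbind(long$subject, long$rater,
                                                          match(long$parameter,
                                                                dimnames(ds$ratings)[[3]]))]))
  utils::write.csv(long, out_path(config, "ratings.csv"), row.names = FALSE)
  stage_log(config, "simulate: %d subjects, %d sequences, %d raters",
            sim_cfg$n_subjects, length(ds$sequences), dim(ds$ratings)[2])
  invisible(ds)
}

#' Extraction stage
#'
#' Reads every `*.jsonl` pose file from `paths$pose_dir` (falling back to
#' the simulation stage's output), gap-fills short dropouts, computes the
#' catalogue signals and writes them to `signals.csv`.
#'
#' @param config A [run_config()].
#' @return List with `sequences` and `signals` (per recording), invisibly.
#' @export
run_extract <- function(config = run_config()) {
  config <- run_config(config)
  pose_dir <- config$paths$pose_dir %||% out_path(config, "pose")
  files <- sort(list.files(pose_dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (length(files) == 0)
    ms_stop("stage_error", "extract: no .jsonl pose files in %s", pose_dir)
  catalogue <- cfg_catalogue(config)
  sequences <- list(); signals <- list()
  for (f in files) {
    rid <- sub("\\.jsonl$", "", basename(f))
    parts <- strsplit(rid, "_")[[1]]
    seq <- read_pose_sequence(f, fps = config$pose$fps,
                              subject_id = parts[1],
                              test_id = if (length(parts) > 1) parts[2] else "SLST",
                              missing_threshold = config$pose$missing_threshold)
    seq <- fill_missing(seq, config$pose$max_gap_frames)
    sequences[[rid]] <- seq
    signals[[rid]] <- compute_signals(seq, catalogue)
  }
  df <- do.call(rbind, lapply(names(signals), function(rid)
    cbind(recording_id = rid, signals_to_df(signals[[rid]]))))
  utils::write.csv(df, out_path(config, "signals.csv"), row.names = FALSE)
  stage_log(config, "extract: %d recordings, %d signals each",
            length(sequences), length(catalogue))
  invisible(list(sequences = sequences, signals = signals))
}

#' Feature stage
#'
#' Builds the recordings-by-features table (one row per recording, ROM per
#' catalogue signal by default) and writes `features.csv`.
#'
#' @param config A [run_config()].
#' @param extracted Optional result of [run_extract()] to avoid re-reading.
#' @return The `feature_table`, invisibly.
#' @export
run_features <- function(config = run_config(), extracted = NULL) {
  config <- run_config(config)
  if (is.null(extracted)) extracted <- run_extract(config)
  ft <- build_feature_table(extracted$sequences, cfg_catalogue(config),
                            mode = config$features$mode)
  utils::write.csv(as.data.frame(ft), out_path(config, "features.csv"),
                   row.names = FALSE)
  stage_log(config, "features: %d x %d table (%d recordings excluded)",
            nrow(ft), ncol(ft) - 2, length(attr(ft, "excluded")))
  invisible(ft)
}

#' Agreement stage
#'
#' Reads the long-format ratings CSV (`subject_id`, `rater_id`, `parameter`,
#' `rating`), computes per-parameter Fleiss kappa, consensus group sizes and
#' the eligibility gate, and writes `agreement.csv`.
#'
#' @param config A [run_config()].
#' @return The agreement report data frame, invisibly.
#' @export
run_agreement <- function(config = run_config()) {
  config <- run_config(config)
  ratings_csv <- config$paths$ratings_csv %||% out_path(config, "ratings.csv")
  if (!file.exists(ratings_csv))
    ms_stop("stage_error", "agreement: ratings file %s not found", ratings_csv)
  ratings <- utils::read.csv(ratings_csv, stringsAsFactors = FALSE)
  report <- agreement_report(ratings, config$agreement$kappa_min,
                             config$agreement$min_minority)
  utils::write.csv(report, out_path(config, "agreement.csv"), row.names = FALSE)
  stage_log(config, "agreement: %d/%d parameters eligible",
            sum(report$eligible), nrow(report))
  invisible(report)
}

#' Training and evaluation stage
#'
#' For each parameter that passed the agreement gate (or the single
#' `parameter` requested), derives majority-vote consensus labels from the
#' ratings, trains the boosted ensemble per test with stratified k-fold
#' cross-validation, and writes `evaluation.csv` plus one model JSON per
#' (test, parameter). Parameters rejected by the gate are refused.
#'
#' @param config A [run_config()].
#' @param features Optional precomputed `feature_table`.
#' @param report Optional precomputed agreement report.
#' @param parameter Optional single parameter name to train.
#' @return Evaluation data frame (one row per test x parameter), invisibly.
#' @export
run_train_eval <- function(config = run_config(), features = NULL,
                           report = NULL, parameter = NULL) {
  config <- run_config(config)
  if (is.null(report)) report <- run_agreement(config)
  if (is.null(features)) {
    fpath <- out_path(config, "features.csv")
    if (!file.exists(fpath))
      ms_stop("stage_error", "train: features file %s not found", fpath)
    features <- utils::read.csv(fpath, check.names = FALSE)
  }
  ratings_csv <- config$paths$ratings_csv %||% out_path(config, "ratings.csv")
  ratings <- utils::read.csv(ratings_csv, stringsAsFactors = FALSE)
  eligible <- report$parameter[report$eligible]
  todo <- parameter %||% eligible
  rows <- list()
  for (par in todo) {
    if (!par %in% eligible)
      ms_stop("gate_refusal",
              "parameter '%s' was rejected by the agreement gate (kappa >= %g, minority >= %d) and cannot be classified",
              par, config$agreement$kappa_min, config$agreement$min_minority)
    sub <- ratings[ratings$parameter == par, ]
    wide <- stats::reshape(sub[, c("subject_id", "rater_id", "rating")],
                           idvar = "subject_id", timevar = "rater_id",
                           direction = "wide")
    wide <- wide[order(wide$subject_id), ]
    labels <- consensus_labels(as.matrix(wide[, -1]))$labels
    names(labels) <- wide$subject_id
    for (tt in unique(features$test_id)) {
      ft <- features[features$test_id == tt, ]
      y <- labels[match(ft$recording_id, names(labels))]
      keep <- !is.na(y)
      X <- as.matrix(ft[keep, setdiff(names(ft), c("recording_id", "test_id"))])
      y <- as.integer(y[keep])
      if (length(unique(y)) < 2) next
      bp <- boost_params(n_learners = config$boost$n_learners,
                         learning_rate = config$boost$learning_rate,
                         max_depth = config$boost$max_depth,
                         feature_subset = config$boost$feature_subset,
                         seed = config$seed)
      cv <- cross_validate_adaboost(X, y, bp, k = config$boost$cv_folds)
      model <- train_adaboost(X, y, bp)
      write_model_json(model, out_path(config, sprintf("model_%s_%s.json", tt,
                       gsub("[^A-Za-z0-9]+", "_", par))))
      rows[[length(rows) + 1L]] <- data.frame(
        test_id = tt, parameter = par, n = length(y),
        specificity = cv$metrics$specificity,
        sensitivity = cv$metrics$sensitivity,
        accuracy = cv$metrics$accuracy)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test_id = character(0), parameter = character(0), n = integer(0),
               specificity = numeric(0), sensitivity = numeric(0),
               accuracy = numeric(0))
  utils::write.csv(ev, out_path(config, "evaluation.csv"), row.names = FALSE)
  stage_log(config, "train: %d (test, parameter) models evaluated", nrow(ev))
  invisible(ev)
}

#' Run the full pipeline
#'
#' Chains the stages in study order — simulate (when no pose input is
#' configured), extract, features, agreement, train/evaluate — and writes a
#' run manifest (`manifest.json`) holding the configuration hash, package
#' version, per-stage row counts and the output inventory. Re-running with
#' an identical configuration and inputs reproduces all outputs.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  config <- run_config(config)
  simulated <- is.null(config$paths$pose_dir)
  if (simulated) run_simulate(config)
  extracted <- run_extract(config)
  features <- run_features(config, extracted)
  report <- run_agreement(config)
  ev <- run_train_eval(config, features = features, report = report)
  cfg_file <- out_path(config, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  # hash the semantic configuration only: where outputs live (and logging)
  # must not change what is computed
  sem <- unclass(config)
  sem$paths <- NULL; sem$quiet <- NULL
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(sem, hash_file)
  on.exit(unlink(hash_file))
  manifest <- list(
    config_hash = unname(tools::md5sum(hash_file)),
    package_version = as.character(utils::packageVersion("motionscreen")),
    counts = list(
      recordings = length(extracted$sequences),
      frames = sum(vapply(extracted$sequences, n_frames, 0L)),
      recordings_excluded = length(attr(features, "excluded")),
      parameters_eligible = sum(report$eligible),
      parameters_total = nrow(report),
      models = nrow(ev)),
    outputs = sort(list.files(config$paths$output_dir, recursive = TRUE))
  )
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(config, "run_all: manifest written (%d outputs)",
            length(manifest$outputs))
  invisible(manifest)
}
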