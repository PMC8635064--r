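#' Build (or read) a pipeline configuration
#'
#' Either a YAML file path or a named list. Recognized fields:
#' `transcripts_dir`, `scores_csv`, `output_dir`, optional lexicon/
#' template overrides (`sentiment_lexicon`, `filler_lexicon`,
#' `relationship_lexicon`, `comm_frequency`, `comm_modes`,
#' `none_understood`, `question_templates`), `target` (name of a scores
#' column), `cutoff_rule` (`fixed`/`median`/`pct75`), `cutoff`,
#' `model_family`, `hyperparameters`, `k_max`, `seed`.
#' @param config YAML path or named list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(target = "ucla", cutoff_rule = "fixed", cutoff = 40,
                   model_family = "ann_logistic", hyperparameters = list(),
                   k_max = 10, seed = 1L, output_dir = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("transcripts_dir", "scores_csv")) {
    if (is.null(config[[f]])) stop("pipeline config is missing '", f, "'")
    if (!file.exists(config[[f]])) {
      stop("pipeline config: path for '", f, "' does not exist: ", config[[f]])
    }
  }
  for (f in c("sentiment_lexicon", "filler_lexicon", "relationship_lexicon",
              "comm_frequency", "comm_modes", "none_understood",
              "question_templates")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("pipeline config: lexicon path does not exist: ", config[[f]])
    }
  }
  structure(config, class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config)[order(names(unclass(config)))], tf)
  unname(tools::md5sum(tf))
}

#' Run the full detection pipeline
#'
#' Transcripts -> question localization -> feature extraction -> table
#' assembly -> target binarization -> Gini feature ranking ->
#' incremental top-k LOOCV evaluation. Writes the feature CSV, the
#' localization report, the ranked-features CSV and a metrics JSON
#' (confusion matrix, sensitivity, specificity, weighted F1, AUC,
#' selected k, config hash, seed) into `output_dir` when one is
#' configured. Idempotent and deterministic given identical inputs and
#' seed.
#' @param config A `pipeline_config`, a named list, or a YAML path.
#' @return The run report: list with `features`, `localization`,
#'   `ranked`, `target`, `selection`, `metrics`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  lex <- stage("lexicons", default_lexicons(
    sentiment = config$sentiment_lexicon, fillers = config$filler_lexicon,
    relationships = config$relationship_lexicon,
    comm_frequency = config$comm_frequency, comm_modes = config$comm_modes,
    none_understood = config$none_understood))
  templates <- stage("templates", question_templates(
    config$question_templates %||%
      system.file("extdata", "question_templates.tsv", package = "sociolex")))

  paths <- sort(list.files(config$transcripts_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  if (length(paths) == 0) stop("no transcript files in ", config$transcripts_dir)
  feats <- stage("extract", extract_features_dir(paths, templates = templates,
                                                 lexicons = lex))
  loc <- stage("localize", do.call(rbind, lapply(paths, function(p) {
    tr <- read_transcript(p)
    cbind(participant_id = tr$participant_id,
          localize_responses(tr, templates)[, c("label", "matched_turn_index",
                                                "similarity", "low_confidence")])
  })))

  scores <- stage("scores", utils::read.csv(config$scores_csv,
                                            stringsAsFactors = FALSE))
  target_col <- config$target
  if (!target_col %in% names(scores)) {
    stop("pipeline stage 'target' failed: no column '", target_col,
         "' in scores table")
  }
  demo_cols <- intersect(c("gender", "age", "education", "caucasian",
                           "not_single"), names(scores))
  target_cols <- setdiff(names(scores), c("participant_id", demo_cols))
  table <- stage("assemble", assemble_feature_table(
    feats, scores[, c("participant_id", target_cols), drop = FALSE],
    demographics = if (length(demo_cols) > 0)
      scores[, c("participant_id", demo_cols), drop = FALSE]))

  rule <- switch(config$cutoff_rule, fixed = "fixed", median = "median",
                 pct75 = "pct75",
                 stop("unknown cutoff_rule: ", config$cutoff_rule))
  target <- stage("binarize", binarize_target(table$scores[[target_col]],
                                              rule, config$cutoff,
                                              name = target_col))
  spec <- model_spec(config$model_family, config$hyperparameters,
                     seed = config$seed)
  feature_cols <- setdiff(names(table$x), target_cols)
  ranked <- stage("rank", gini_rank(table, target, features = feature_cols))
  sel <- stage("evaluate", incremental_selection(
    table, target, spec, ranked, k_max = min(config$k_max, nrow(ranked))))

  metrics <- list(
    target = target_col, cutoff_rule = rule, cutoff_value = target$cutoff_value,
    model_family = config$model_family, seed = config$seed,
    config_hash = hash, n = sum(sel$best$confusion),
    selected_k = sel$best_k, selected_features = sel$best_features,
    confusion = as.list(sel$best$confusion),
    sensitivity = sel$best$sensitivity, specificity = sel$best$specificity,
    f1_weighted = sel$best$f1_weighted, auc = sel$best$auc)

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    tag <- substr(hash, 1, 8)
    utils::write.csv(feats, file.path(out, paste0("features_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(loc, file.path(out, paste0("localization_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(ranked, file.path(out, paste0("ranked_features_", tag, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out, paste0("metrics_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("config_hash:", hash),
                 paste("seed:", config$seed),
                 paste("transcripts:", length(paths)),
                 paste("run_at:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(out, paste0("run_", tag, ".log")))
  }
  list(features = feats, localization = loc, ranked = ranked,
       target = target, selection = sel, metrics = metrics,
       config_hash = hash)
}
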