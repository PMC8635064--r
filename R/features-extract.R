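#' Names of the participant feature registry
#'
#' The stable set of column names produced by [extract_features()]:
#' POS frequencies and ratios, pronoun:noun ratio, vocabulary richness,
#' filler frequency, Yngve complexity, sentence similarity, sentiment
#' aggregates, response lengths, pronoun densities at both scopes, and
#' the social-profile summary features.
#' @return Character vector of feature names.
#' @export
feature_registry <- function() {
  c(paste0("pos_freq_", COARSE_TAGS), paste0("pos_ratio_", COARSE_TAGS),
    "pronoun_noun_ratio",
    "type_token_ratio", "brunet_index", "honore_statistic",
    "filler_frequency",
    "yngve_mean", "yngve_total", "yngve_median",
    "sentence_similarity_mean", "sentence_similarity_median",
    "sentence_similarity_sd", "sentence_similarity_max",
    as.vector(outer(c("pos", "neg", "neu", "compound"),
                    c("mean", "median", "sd", "max"),
                    function(c, s) paste0("sentiment_", c, "_", s))),
    "response_length_total_words", "response_length_total_chars",
    "response_length_mean_words", "response_length_median_chars",
    "response_length_min_words",
    paste0("pron_density_", c("first_singular", "first_plural", "third"),
           "_whole"),
    paste0("pron_density_", c("first_singular", "first_plural", "third"),
           "_section"),
    "social_important_total", "social_understood_total",
    "social_none_understood", "social_comm_frequency_per_month",
    "social_n_modes")
}

#' Extract the full feature vector for one participant
#'
#' Localizes the template questions, then computes every registry
#' feature. Linguistic features come from the relationship-section
#' responses only; pronoun densities are computed both over the whole
#' interview (all participant turns — the default modeling scope) and
#' over the relationship section.
#' @param transcript A `transcript`.
#' @param templates Question templates, see [question_templates()].
#' @param lexicons Lexicon list, see [default_lexicons()].
#' @param tagger POS tagger function (default [rule_tagger()]).
#' @param parser Constituency parser function (default
#'   [fallback_parse()]).
#' @return Named numeric vector over [feature_registry()], with the
#'   localization report as attribute `"located"`.
#' @export
extract_features <- function(transcript, templates = question_templates(),
                             lexicons = default_lexicons(),
                             tagger = rule_tagger, parser = fallback_parse) {
  validate_transcript(transcript)
  located <- localize_responses(transcript, templates)
  responses <- located$response_text
  combined <- paste(responses[nzchar(responses)], collapse = " ")
  tt <- tokenize_and_tag(combined, tagger)
  flat <- unlist(tt$sentences)

  sent_scores <- lapply(tt$sentences, sentiment_score, lexicon = lexicons$sentiment)
  prof <- social_profile(transcript, located, lexicons)
  dens_w <- prof$pronoun_density$whole_transcript
  dens_s <- prof$pronoun_density$relationship_section

  out <- c(
    pos_profile(tt),
    vocabulary_richness(flat),
    filler_frequency = filler_frequency(tt, lexicons$fillers),
    yngve_stats(tt, parser),
    sentence_similarity_stats(tt$sentences),
    aggregate_sentiment(sent_scores),
    response_length_stats(responses),
    stats::setNames(dens_w, paste0("pron_density_", names(dens_w), "_whole")),
    stats::setNames(dens_s, paste0("pron_density_", names(dens_s), "_section")),
    social_important_total = prof$important_total,
    social_understood_total = prof$understood_total,
    social_none_understood = as.numeric(prof$none_understood),
    social_comm_frequency_per_month = as.numeric(prof$comm_frequency_per_month),
    social_n_modes = length(prof$modes)
  )
  out <- out[feature_registry()]
  names(out) <- feature_registry()
  attr(out, "located") <- located
  out
}

#' Extract features for a directory of transcripts
#'
#' @param paths Character vector of transcript file paths.
#' @param ... Passed to [extract_features()].
#' @return data.frame: `participant_id` plus one column per registry
#'   feature, one row per transcript.
#' @export
extract_features_dir <- function(paths, ...) {
  rows <- lapply(paths, function(p) {
    tr <- read_transcript(p)
    fv <- extract_features(tr, ...)
    cbind(data.frame(participant_id = tr$participant_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
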