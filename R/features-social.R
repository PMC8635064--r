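#' Pronoun densities for first-singular, first-plural and third person
#'
#' Density of a class = count of its members / total token count.
#' Second-person pronouns are excluded (they mostly address the
#' interviewer). Callers compute the whole-transcript and
#' relationship-section scopes separately; the whole interview is the
#' default modeling scope because the relationship section inflates
#' pronoun use.
#' @param tokens Character vector of tokens (case-folded internally).
#' @param inventory Pronoun inventory, see [pronoun_inventory()].
#' @return Named numeric: `first_singular`, `first_plural`, `third`.
#' @examples
#' pronoun_densities(c("we", "love", "our", "garden"))
#' @export
pronoun_densities <- function(tokens, inventory = pronoun_inventory()) {
  n <- length(tokens)
  if (n == 0) {
    return(flagged(c(first_singular = 0, first_plural = 0, third = 0),
                   "degenerate"))
  }
  lt <- tolower(tokens)
  c(first_singular = sum(lt %in% inventory$first_singular) / n,
    first_plural = sum(lt %in% inventory$first_plural) / n,
    third = sum(lt %in% inventory$third) / n)
}

# fold a token onto the lexicon: direct hit, else simple plural s-stripping
fold_to_lexicon <- function(tokens, words) {
  hit <- tokens %in% words
  stripped <- sub("s$", "", tokens)
  ifelse(hit, tokens, ifelse(stripped %in% words, stripped, NA_character_))
}

#' Count relationship-word mentions by category
#'
#' Pure dictionary word counting: every token found in the relationship
#' lexicon (case-folded, with simple plural s-stripping, e.g. sons ->
#' son) increments its category. Repeated or co-referent mentions each
#' count — no anaphora resolution is attempted, so counts can
#' overestimate the number of distinct relationships ("I have children.
#' A son and a daughter." counts 3 in the children category).
#' @param response_text Character scalar.
#' @param lexicon Named character vector: word -> category.
#' @return Named integer vector of counts per category present (empty
#'   when nothing matches), with attribute `total`.
#' @export
count_relationships <- function(response_text, lexicon) {
  stopifnot(length(lexicon) > 0)
  tokens <- tokenize(response_text)[[1]]
  matched <- fold_to_lexicon(tokens, names(lexicon))
  matched <- matched[!is.na(matched)]
  if (length(matched) == 0) {
    out <- integer(0)
    attr(out, "total") <- 0L
    return(out)
  }
  cats <- lexicon[matched]
  tb <- table(cats)
  out <- stats::setNames(as.integer(tb), names(tb))
  attr(out, "total") <- sum(out)
  out
}

# longest-match phrase search: which lexicon phrases occur in the text?
match_phrases <- function(text, phrases) {
  norm <- paste0(" ", paste(tokenize(text)[[1]], collapse = " "), " ")
  found <- vapply(phrases, function(p) {
    grepl(paste0(" ", p, " "), norm, fixed = TRUE)
  }, logical(1))
  phrases[found]
}

#' Communication frequency and modes from a response
#'
#' Searches the response for predefined American-English phrases mapping
#' to approximate contact frequency (times per month) and to
#' communication modes. With several frequency phrases matched, the
#' maximum is kept (the most frequent stated contact). No frequency
#' phrase at all yields `NA` with a `"frequency_missing"` flag — missing,
#' not zero.
#' @param response_text Character scalar.
#' @param lexicons List with `comm_frequency` (named numeric) and
#'   `comm_modes` (named character), see [default_lexicons()].
#' @return List with `frequency_per_month` (numeric or `NA`) and `modes`
#'   (character vector).
#' @export
communication_profile <- function(response_text, lexicons) {
  stopifnot(length(lexicons$comm_frequency) > 0)
  freq_hits <- match_phrases(response_text, names(lexicons$comm_frequency))
  mode_hits <- match_phrases(response_text, names(lexicons$comm_modes))
  freq <- if (length(freq_hits) == 0) {
    flagged(NA_real_, "frequency_missing")
  } else {
    max(lexicons$comm_frequency[freq_hits])
  }
  list(frequency_per_month = freq,
       modes = sort(unique(unname(lexicons$comm_modes[mode_hits]))))
}

#' Detect "understood by no one" responses
#'
#' True when a negation pattern ("no one", "nobody", "not really", ...)
#' matches the response and no relationship word co-occurs in it
#' ("Nobody but my daughter" is not a none-understood response).
#' @param response_text Character scalar.
#' @param patterns Character vector of negation patterns.
#' @param relationship_lexicon Named character vector (word -> category).
#' @return Logical scalar.
#' @export
detect_none_understood <- function(response_text,
                                   patterns = default_lexicons()$none_understood,
                                   relationship_lexicon = default_lexicons()$relationships) {
  neg <- length(match_phrases(response_text, patterns)) > 0
  if (!neg) return(FALSE)
  rel <- count_relationships(response_text, relationship_lexicon)
  attr(rel, "total") == 0
}

#' Social profile of one participant
#'
#' Combines the relationship-word counts from the important-relationships
#' response (Q1) and the feeling-understood response (Q3), the
#' communication frequency/modes from Q4, the none-understood detector,
#' and pronoun densities at both scopes (whole transcript = all
#' participant turns; relationship section = the located responses).
#' @param transcript A `transcript`.
#' @param located data.frame from [localize_responses()].
#' @param lexicons List from [default_lexicons()].
#' @return List of class `social_profile`.
#' @export
social_profile <- function(transcript, located, lexicons = default_lexicons()) {
  resp <- stats::setNames(located$response_text, located$label)
  imp <- count_relationships(resp[["Q1"]] %||% "", lexicons$relationships)
  und <- count_relationships(resp[["Q3"]] %||% "", lexicons$relationships)
  comm <- communication_profile(resp[["Q4"]] %||% "", lexicons)
  whole_tokens <- tokenize(participant_text(transcript))[[1]]
  section_tokens <- tokenize(paste(resp, collapse = " "))[[1]]
  structure(list(
    important_counts = imp,
    important_total = attr(imp, "total"),
    understood_counts = und,
    understood_total = attr(und, "total"),
    none_understood = detect_none_understood(resp[["Q3"]] %||% "",
                                             lexicons$none_understood,
                                             lexicons$relationships),
    comm_frequency_per_month = comm$frequency_per_month,
    modes = comm$modes,
    pronoun_density = list(
      whole_transcript = pronoun_densities(whole_tokens),
      relationship_section = pronoun_densities(section_tokens)
    )
  ), class = "social_profile")
}
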