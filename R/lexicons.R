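#' Load the packaged (or user-supplied) analysis lexicons
#'
#' All lexicons are editable plain-text configuration, not ground truth:
#' the relationship and communication dictionaries are curated defaults
#' with the category scheme spouse / children / grandchildren / sibling /
#' parent / friend / other-family / professional, and the valence lexicon
#' is the package's own curated list.
#'
#' @param sentiment,fillers,relationships,comm_frequency,comm_modes,none_understood
#'   Optional paths overriding the shipped files.
#' @return A list with elements `sentiment` (named numeric: token ->
#'   valence), `fillers` (character vector, multiword entries allowed),
#'   `relationships` (named character: word -> category), `comm_frequency`
#'   (named numeric: phrase -> times per month), `comm_modes` (named
#'   character: phrase -> mode), `none_understood` (character patterns).
#' @export
default_lexicons <- function(sentiment = NULL, fillers = NULL,
                             relationships = NULL, comm_frequency = NULL,
                             comm_modes = NULL, none_understood = NULL) {
  pkg_file <- function(f) system.file("extdata", f, package = "sociolex")
  read2 <- function(path, numeric_value = FALSE) {
    d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
    v <- if (numeric_value) as.numeric(d[[2]]) else as.character(d[[2]])
    stats::setNames(v, tolower(trimws(d[[1]])))
  }
  read_lines <- function(path) {
    x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
    tolower(x[nzchar(x) & !startsWith(x, "#")])
  }
  list(
    sentiment = read2(sentiment %||% pkg_file("sentiment_lexicon.tsv"), TRUE),
    fillers = read_lines(fillers %||% pkg_file("filler_lexicon.txt")),
    relationships = read2(relationships %||% pkg_file("relationship_lexicon.tsv")),
    comm_frequency = read2(comm_frequency %||% pkg_file("communication_frequency.tsv"), TRUE),
    comm_modes = read2(comm_modes %||% pkg_file("communication_modes.tsv")),
    none_understood = read_lines(none_understood %||% pkg_file("none_understood_patterns.txt"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pronoun inventory used for density features
#'
#' First-person singular, first-person plural and third-person classes;
#' second-person pronouns are excluded because they mostly address the
#' interviewer.
#' @return List of character vectors `first_singular`, `first_plural`,
#'   `third`, `excluded_second`.
#' @export
pronoun_inventory <- function() {
  list(
    first_singular = c("i", "me", "my", "mine"),
    first_plural = c("we", "our", "us", "ours"),
    third = c("he", "she", "they", "them", "their"),
    excluded_second = c("you", "your", "yours")
  )
}
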