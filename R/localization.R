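#' Build smoothed TF-IDF vectors over a document collection
#'
#' Each interviewer turn of a transcript is treated as a document of the
#' retrieval corpus. Term frequency is the raw within-document count; the
#' inverse document frequency is smoothed,
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, so terms present in every
#' document still get weight 1. Vectors are not length-normalized here —
#' the cosine similarity normalizes.
#'
#' @param documents List of token vectors (use [tokenize()]).
#' @return A `document_vectors` object: list with `vocabulary`, `idf`
#'   (named numeric) and `doc_vectors` (matrix, one row per document,
#'   columns indexed by vocabulary).
#' @examples
#' dv <- build_tfidf(tokenize(c("the cat sat", "the dog ran")))
#' dv$idf
#' @export
build_tfidf <- function(documents) {
  stopifnot(is.list(documents), length(documents) >= 1)
  if (all(lengths(documents) == 0)) stop("all documents are empty")
  vocab <- sort(unique(unlist(documents)))
  n_docs <- length(documents)
  df <- vapply(vocab, function(term) {
    sum(vapply(documents, function(d) term %in% d, logical(1)))
  }, numeric(1))
  idf <- log((1 + n_docs) / (1 + df)) + 1
  mat <- matrix(0, nrow = n_docs, ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_len(n_docs)) {
    if (length(documents[[i]]) == 0) next
    tf <- table(documents[[i]])
    mat[i, names(tf)] <- as.numeric(tf) * idf[names(tf)]
  }
  structure(list(vocabulary = vocab, idf = idf, doc_vectors = mat),
            class = "document_vectors")
}

# cosine with the zero-vector convention: similarity 0
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

vectorize_query <- function(tokens, vectors) {
  v <- numeric(length(vectors$vocabulary))
  names(v) <- vectors$vocabulary
  tf <- table(tokens[tokens %in% vectors$vocabulary])
  if (length(tf) > 0) v[names(tf)] <- as.numeric(tf) * vectors$idf[names(tf)]
  v
}

#' The six relationship-section question templates
#'
#' Reads the template set shipped as a tab-separated config file
#' (label, question text); users may point to an edited copy.
#' @param path Template file; defaults to the shipped set.
#' @return data.frame with columns `label`, `template_text`.
#' @export
question_templates <- function(path = system.file("extdata", "question_templates.tsv",
                                                  package = "sociolex")) {
  q <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         quote = "")
  stopifnot(all(c("label", "template_text") %in% names(q)),
            !anyDuplicated(q$label))
  q
}

#' Locate one template question in a transcript
#'
#' Matches the vectorized query against the TF-IDF vectors of the
#' transcript's interviewer turns by cosine similarity; query matching is
#' restricted to interviewer turns since responses are recovered
#' positionally. Ties break to the earliest turn. Matches with similarity
#' below `low_conf` are flagged low-confidence.
#'
#' @param transcript A `transcript`.
#' @param query One-row data.frame (or list) with `label` and
#'   `template_text`.
#' @param vectors `document_vectors` built over the transcript's
#'   interviewer turns; built on the fly when `NULL`.
#' @param low_conf Low-confidence similarity threshold (default 0.2).
#' @return A `located_response`: list with `label`, `matched_turn_index`
#'   (index into `transcript$turns`), `similarity`, `low_confidence`,
#'   `response_text`.
#' @export
locate_question <- function(transcript, query, vectors = NULL, low_conf = 0.2) {
  stopifnot(inherits(transcript, "transcript"))
  qi <- which(transcript$turns$speaker == "interviewer")
  if (length(qi) == 0) stop("transcript has no interviewer turns")
  if (is.null(vectors)) {
    vectors <- build_tfidf(tokenize(transcript$turns$text[qi]))
  }
  qtok <- tokenize(query$template_text)[[1]]
  qvec <- vectorize_query(qtok, vectors)
  sims <- apply(vectors$doc_vectors, 1, cosine_sim, b = qvec)
  best <- which.max(sims)  # which.max takes the earliest on ties
  idx <- qi[best]
  structure(list(
    label = query$label,
    matched_turn_index = idx,
    similarity = unname(sims[best]),
    low_confidence = unname(sims[best]) < low_conf,
    response_text = extract_response(transcript, idx)
  ), class = "located_response")
}

#' Extract the participant response following a matched question turn
#'
#' Concatenates all participant turns strictly after the matched
#' interviewer turn and before the next interviewer turn; empty string if
#' the interview ends immediately or the next turn is another question.
#' @param transcript A `transcript`.
#' @param matched_turn_index Index of an interviewer turn in
#'   `transcript$turns`.
#' @return Character scalar (possibly `""`).
#' @export
extract_response <- function(transcript, matched_turn_index) {
  stopifnot(inherits(transcript, "transcript"))
  n <- nrow(transcript$turns)
  if (matched_turn_index < 1 || matched_turn_index > n) {
    stop("matched_turn_index out of range: ", matched_turn_index)
  }
  if (transcript$turns$speaker[matched_turn_index] != "interviewer") {
    stop("matched turn is not an interviewer turn")
  }
  if (matched_turn_index == n) return("")
  after <- seq(matched_turn_index + 1L, n)
  spk <- transcript$turns$speaker[after]
  nxt_q <- which(spk == "interviewer")
  if (length(nxt_q) > 0) after <- after[seq_len(nxt_q[1] - 1L)]
  if (length(after) == 0) return("")
  paste(transcript$turns$text[after], collapse = " ")
}

#' Localize all template questions in a transcript
#'
#' Builds one TF-IDF model over the transcript's interviewer turns and
#' matches every template against it.
#' @param transcript A `transcript`.
#' @param templates data.frame as from [question_templates()].
#' @param low_conf Low-confidence threshold passed to [locate_question()].
#' @return data.frame (one row per template): `label`,
#'   `matched_turn_index`, `similarity`, `low_confidence`,
#'   `response_text`.
#' @export
localize_responses <- function(transcript, templates = question_templates(),
                               low_conf = 0.2) {
  qi <- which(transcript$turns$speaker == "interviewer")
  if (length(qi) == 0) stop("transcript has no interviewer turns")
  vectors <- build_tfidf(tokenize(transcript$turns$text[qi]))
  rows <- lapply(seq_len(nrow(templates)), function(i) {
    lr <- locate_question(transcript, templates[i, ], vectors, low_conf)
    data.frame(label = lr$label, matched_turn_index = lr$matched_turn_index,
               similarity = lr$similarity, low_confidence = lr$low_confidence,
               response_text = lr$response_text, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
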