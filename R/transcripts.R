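#' Parse an interview transcript in the Q/A plain-text dialect
#'
#' Transcripts mark each interviewer utterance with a line starting with
#' `Q` and each participant answer with a line starting with `A`; lines
#' without a marker continue the current turn. The marker may be followed
#' by whitespace, `:` or `.` (transcriptionist variants). Internal
#' whitespace is collapsed to single spaces; case is preserved because
#' tagging and sentiment scoring downstream are case-sensitive.
#'
#' @param raw_text Character scalar (or vector of lines) with the raw
#'   transcript text, UTF-8.
#' @param participant_id Opaque identifier attached to the transcript.
#' @return An object of class `transcript`: a list with `participant_id`
#'   and `turns`, a data.frame with columns `speaker`
#'   (`"interviewer"`/`"participant"`), `text`, `line_start`, `line_end`.
#' @examples
#' tr <- parse_transcript("Q How are you?\nA Fine, thanks.", "p1")
#' tr$turns$speaker
#' @export
parse_transcript <- function(raw_text, participant_id = "unknown") {
  stopifnot(is.character(raw_text), length(raw_text) >= 1)
  if (length(raw_text) == 1L) {
    lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- raw_text
  }
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("malformed transcript [", participant_id, "]: empty input")
  }
  marker <- marker_of(lines)
  nonblank <- nzchar(trimws(lines))
  if (!any(!is.na(marker))) {
    first_bad <- which(nonblank)[1]
    stop("malformed transcript [", participant_id, "]: no 'Q'/'A' marker lines; first line: ",
         dQuote(trimws(lines[first_bad])))
  }
  first_marked <- which(!is.na(marker))[1]
  early <- which(nonblank[seq_len(first_marked - 1L)])
  if (length(early) > 0L) {
    stop("malformed transcript [", participant_id, "]: text before first marker at line ",
         early[1], ": ", dQuote(trimws(lines[early[1]])))
  }

  speaker <- character(0)
  text <- character(0)
  line_start <- integer(0)
  line_end <- integer(0)
  cur <- 0L
  for (i in seq_along(lines)) {
    if (!nonblank[i]) next
    if (!is.na(marker[i])) {
      cur <- cur + 1L
      speaker[cur] <- if (marker[i] == "Q") "interviewer" else "participant"
      text[cur] <- strip_marker(lines[i])
      line_start[cur] <- i
      line_end[cur] <- i
    } else {
      # continuation line of the current turn
      text[cur] <- paste(text[cur], trimws(lines[i]))
      line_end[cur] <- i
    }
  }
  text <- squeeze_ws(text)
  keep <- nzchar(text)
  turns <- data.frame(
    speaker = speaker[keep], text = text[keep],
    line_start = line_start[keep], line_end = line_end[keep],
    stringsAsFactors = FALSE
  )
  structure(list(participant_id = participant_id, turns = turns),
            class = "transcript")
}

# marker grammar: first non-whitespace char is Q or A, followed by
# whitespace, ":" or "." (or end of line)
marker_of <- function(lines) {
  t <- trimws(lines)
  m <- rep(NA_character_, length(lines))
  hit <- grepl("^[QA]([[:space:]:.]|$)", t)
  m[hit] <- substr(t[hit], 1, 1)
  m
}

strip_marker <- function(line) {
  sub("^[[:space:]]*[QA][[:space:]:.]+", "", paste0(line, " "))
}

squeeze_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript> participant", x$participant_id, "-", nrow(x$turns), "turns\n")
  n_show <- min(4L, nrow(x$turns))
  for (i in seq_len(n_show)) {
    cat(sprintf("  [%s] %s\n", substr(x$turns$speaker[i], 1, 1),
                substr(x$turns$text[i], 1, 60)))
  }
  if (nrow(x$turns) > n_show) cat("  ...\n")
  invisible(x)
}

#' Validate a transcript for analysis
#'
#' A valid interview has at least one interviewer and one participant turn.
#' @param x A `transcript`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_transcript <- function(x) {
  stopifnot(inherits(x, "transcript"))
  if (!any(x$turns$speaker == "interviewer") ||
      !any(x$turns$speaker == "participant")) {
    stop("invalid interview [", x$participant_id,
         "]: needs at least one interviewer and one participant turn")
  }
  invisible(TRUE)
}

#' Read a transcript file
#'
#' One file per participant; the file stem is the participant id.
#' @param path Path to a Q/A-dialect text file (UTF-8).
#' @return A `transcript`.
#' @export
read_transcript <- function(path) {
  id <- tools::file_path_sans_ext(basename(path))
  parse_transcript(readLines(path, encoding = "UTF-8", warn = FALSE), id)
}

#' Write a transcript in the Q/A dialect
#'
#' @param x A `transcript`.
#' @param path Output file; defaults to `<participant_id>.txt` in `dir`.
#' @param dir Directory used when `path` is missing.
#' @return The path written, invisibly.
#' @export
write_transcript <- function(x, path = NULL, dir = ".") {
  stopifnot(inherits(x, "transcript"))
  if (is.null(path)) path <- file.path(dir, paste0(x$participant_id, ".txt"))
  mk <- ifelse(x$turns$speaker == "interviewer", "Q:", "A:")
  writeLines(paste(mk, x$turns$text), path, useBytes = TRUE)
  invisible(path)
}

#' Participant text of a transcript
#'
#' Concatenated text of all participant turns (the scope used for
#' whole-transcript pronoun densities).
#' @param x A `transcript`.
#' @return Character scalar.
#' @export
participant_text <- function(x) {
  stopifnot(inherits(x, "transcript"))
  paste(x$turns$text[x$turns$speaker == "participant"], collapse = " ")
}
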