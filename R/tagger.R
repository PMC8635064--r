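#' Tokenize text for bag-of-words retrieval
#'
#' Lowercases, strips punctuation, splits on whitespace. No stemming and
#' no stop-word removal: the question templates are short and their
#' function words carry matching signal.
#' @param text Character vector.
#' @return List of character vectors (one per element of `text`).
#' @export
tokenize <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9' ]+", " ", gsub("[[:space:]]+", " ", text))
  text <- gsub("(^|\\s)'+|'+(\\s|$)", " ", text)  # strip quote-only apostrophes
  lapply(strsplit(trimws(text), "[[:space:]]+"), function(x) x[nzchar(x)])
}

#' Split text into sentences
#'
#' Sentence boundaries at runs of `.`, `!`, `?` followed by whitespace or
#' end of text.
#' @param text Character scalar.
#' @return Character vector of sentences (possibly empty).
#' @export
split_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(character(0))
  s <- strsplit(text, "(?<=[.!?])[[:space:]]+|[.!?]+$", perl = TRUE)[[1]]
  s <- trimws(gsub("[.!?]+$", "", s))
  s[nzchar(s)]
}

# closed-class word lists for the default rule tagger; the coarse tagset is
# {noun, verb, adjective, adverb, pronoun, interjection, filler, other}
.tag_lists <- local({
  pronouns <- c("i", "me", "my", "mine", "myself", "we", "our", "us", "ours",
                "ourselves", "you", "your", "yours", "yourself", "he", "him",
                "his", "she", "her", "hers", "it", "its", "they", "them",
                "their", "theirs", "themselves", "who", "whom", "everyone",
                "someone", "anyone", "nobody", "somebody", "anybody",
                "everybody", "something", "anything", "nothing", "everything",
                "this", "that", "these", "those", "one")
  interjections <- c("oh", "wow", "yeah", "yes", "no", "hey", "ah", "ooh",
                     "huh", "hmm", "gosh", "gee", "okay", "ok", "alright")
  fillers <- c("um", "uh", "er", "erm", "uhm", "mhm")
  verbs <- c("am", "is", "are", "was", "were", "be", "been", "being", "do",
             "does", "did", "have", "has", "had", "will", "would", "can",
             "could", "shall", "should", "may", "might", "must", "go", "goes",
             "went", "gone", "get", "gets", "got", "see", "saw", "seen",
             "know", "knew", "known", "think", "thought", "feel", "felt",
             "call", "calls", "called", "talk", "talks", "talked", "say",
             "says", "said", "tell", "told", "live", "lives", "lived",
             "visit", "visits", "visited", "love", "loves", "loved", "like",
             "likes", "liked", "make", "makes", "made", "come", "comes",
             "came", "keep", "keeps", "kept", "spend", "spends", "spent",
             "help", "helps", "helped", "meet", "meets", "met", "stay",
             "understand", "understands", "understood", "enjoy", "enjoys",
             "enjoyed", "miss", "misses", "missed", "email", "emails",
             "emailed", "text", "texts", "texted", "reach", "chat", "chats",
             "share", "shares", "shared", "care", "cares", "cared", "try",
             "tries", "tried", "want", "wants", "wanted", "need", "needs",
             "needed", "read", "reads", "write", "writes", "wrote", "play",
             "plays", "played", "belong", "belongs", "belonged", "connect",
             "connects", "connected", "listen", "listens", "listened")
  adjectives <- c("good", "great", "nice", "happy", "sad", "lonely", "close",
                  "dear", "old", "young", "big", "small", "long", "hard",
                  "difficult", "easy", "important", "meaningful", "special",
                  "wonderful", "lovely", "kind", "warm", "quiet", "busy",
                  "alone", "isolated", "empty", "grateful", "thankful",
                  "supportive", "new", "few", "many", "much", "several",
                  "best", "better", "worse", "worst", "other", "own", "same",
                  "whole", "larger", "active", "strong", "true", "deep")
  adverbs <- c("very", "really", "quite", "so", "too", "also", "just",
               "often", "sometimes", "always", "never", "rarely", "usually",
               "together", "again", "still", "now", "then", "here", "there",
               "not", "n't", "maybe", "perhaps", "well", "much", "more",
               "most", "less", "least", "away", "back", "out", "up", "down",
               "daily", "weekly", "monthly", "nearby", "anymore", "lately")
  other <- c("the", "a", "an", "and", "or", "but", "if", "because", "as",
             "of", "at", "by", "for", "with", "about", "against", "between",
             "into", "through", "during", "before", "after", "above",
             "below", "to", "from", "in", "on", "off", "over", "under",
             "when", "where", "why", "how", "all", "any", "both", "each",
             "some", "such", "only", "than", "while", "since", "until",
             "though", "although", "whether", "per", "via", "every", "once",
             "twice", "couple", "times", "time", "what", "which")
  list(pronoun = pronouns, interjection = interjections, filler = fillers,
       verb = verbs, adjective = adjectives, adverb = adverbs, other = other)
})

#' Default rule-and-lexicon part-of-speech tagger
#'
#' Tags tokens with the coarse 8-class tagset used throughout the feature
#' suite: closed-class lookup first (pronoun, interjection, filler, verb,
#' adjective, adverb, function words as `other`), then suffix heuristics
#' (`-ly` adverb; `-ing`/`-ed` verb; `-ous`/`-ful`/`-ive`/`-able`/`-al`
#' adjective), numerals as `other`, and noun as the open-class default.
#' Any other tagger honoring the contract (character vector of tokens in,
#' parallel vector of coarse tags out) can be supplied to
#' [tokenize_and_tag()]; a Penn-to-coarse mapping file ships in
#' `inst/extdata/pos_penn_to_coarse.tsv` for adapters.
#' @param tokens Character vector of tokens.
#' @return Character vector of coarse tags, parallel to `tokens`.
#' @export
rule_tagger <- function(tokens) {
  lt <- tolower(tokens)
  tags <- rep(NA_character_, length(tokens))
  for (tag in names(.tag_lists)) {
    tags[is.na(tags) & lt %in% .tag_lists[[tag]]] <- tag
  }
  idx <- is.na(tags)
  tags[idx & grepl("ly$", lt)] <- "adverb"
  idx <- is.na(tags)
  tags[idx & grepl("(ing|ed)$", lt) & nchar(lt) > 4] <- "verb"
  idx <- is.na(tags)
  tags[idx & grepl("(ous|ful|ive|able|ible|less)$", lt)] <- "adjective"
  idx <- is.na(tags)
  tags[idx & grepl("^[0-9]+$", lt)] <- "other"
  tags[is.na(tags)] <- "noun"
  tags
}

#' Tokenize and part-of-speech tag a text span
#'
#' Adapter around any POS tagger honoring the coarse tag set.
#' @param text Character scalar.
#' @param tagger Function mapping a token character vector to a parallel
#'   coarse-tag vector; defaults to [rule_tagger()].
#' @return A `tokenized_text`: list with `sentences` (list of token
#'   vectors) and `pos_tags` (parallel list of tag vectors).
#' @examples
#' tt <- tokenize_and_tag("I run. We talk.")
#' tt$pos_tags
#' @export
tokenize_and_tag <- function(text, tagger = rule_tagger) {
  stopifnot(is.character(text), length(text) == 1)
  sents <- split_sentences(text)
  toks <- tokenize(sents)
  toks <- toks[lengths(toks) > 0]
  tags <- lapply(toks, function(tk) {
    tg <- tryCatch(tagger(tk), error = function(e) {
      stop("tagger failed on ", dQuote(paste(tk, collapse = " ")), ": ",
           conditionMessage(e))
    })
    if (length(tg) != length(tk)) {
      stop("tagger returned ", length(tg), " tags for ", length(tk), " tokens")
    }
    tg
  })
  structure(list(sentences = toks, pos_tags = tags), class = "tokenized_text")
}

#' Load a tagger-tag to coarse-tag mapping file
#'
#' Two-column whitespace-separated text: source tag, coarse tag. Wrap an
#' external tagger emitting its own tagset into the coarse contract.
#' @param path Mapping file; defaults to the shipped Penn mapping.
#' @return Named character vector (source tag -> coarse tag).
#' @export
read_pos_mapping <- function(path = system.file("extdata", "pos_penn_to_coarse.tsv",
                                                package = "sociolex")) {
  m <- utils::read.table(path, header = FALSE, col.names = c("from", "to"),
                         stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(m$to, m$from)
}
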