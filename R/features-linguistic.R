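COARSE_TAGS <- c("noun", "verb", "adjective", "adverb", "pronoun",
                 "interjection", "filler", "other")

# population SD (the feature suite uses population, not sample, SD)
sd_pop <- function(x) {
  if (length(x) == 0) return(0)
  sqrt(mean((x - mean(x))^2))
}

flagged <- function(x, flag = NULL) {
  if (!is.null(flag)) attr(x, "flags") <- flag
  x
}

#' Part-of-speech profile of a tagged text
#'
#' For each coarse tag: `pos_freq_<tag>` = tag count / token count and
#' `pos_ratio_<tag>` = tag count / open-class (noun+verb+adjective+adverb)
#' token count, plus the pronoun-to-noun ratio. Zero tokens (or zero
#' nouns for the pronoun:noun ratio) yield 0 with a `"degenerate"` flag
#' attribute.
#' @param tt A `tokenized_text` from [tokenize_and_tag()].
#' @return Named numeric vector.
#' @export
pos_profile <- function(tt) {
  tags <- unlist(tt$pos_tags)
  n <- length(tags)
  out <- numeric(0)
  if (n == 0) {
    out <- c(stats::setNames(rep(0, length(COARSE_TAGS)),
                             paste0("pos_freq_", COARSE_TAGS)),
             stats::setNames(rep(0, length(COARSE_TAGS)),
                             paste0("pos_ratio_", COARSE_TAGS)),
             pronoun_noun_ratio = 0)
    return(flagged(out, "degenerate"))
  }
  counts <- vapply(COARSE_TAGS, function(t) sum(tags == t), numeric(1))
  open_n <- sum(counts[c("noun", "verb", "adjective", "adverb")])
  freq <- counts / n
  ratio <- if (open_n > 0) counts / open_n else counts * 0
  pn <- if (counts["noun"] > 0) counts["pronoun"] / counts["noun"] else 0
  out <- c(stats::setNames(freq, paste0("pos_freq_", COARSE_TAGS)),
           stats::setNames(ratio, paste0("pos_ratio_", COARSE_TAGS)),
           pronoun_noun_ratio = unname(pn))
  fl <- c(if (counts["noun"] == 0) "zero_nouns",
          if (open_n == 0) "zero_open_class")
  flagged(out, if (length(fl)) fl else NULL)
}

#' Vocabulary richness: type-token ratio, Brunet's index, Honore's statistic
#'
#' With `N` tokens, `V` case-folded types and `V1` types occurring
#' exactly once: `TTR = V/N`; Brunet's `W = N^(V^-0.165)` (lower = richer
#' vocabulary); Honore's `R = 100*ln(N) / (1 - V1/V)` (emphasizes hapax
#' legomena). When every type is a hapax (`V1 == V`) the denominator is
#' capped at 1e-3 and the result carries a `"honore_capped"` flag — short
#' responses make this singularity common.
#' @param tokens Flat character vector of tokens (may be empty).
#' @return Named numeric: `type_token_ratio`, `brunet_index`,
#'   `honore_statistic`.
#' @examples
#' vocabulary_richness(c("the", "the", "the", "the"))
#' @export
vocabulary_richness <- function(tokens) {
  n <- length(tokens)
  if (n == 0) {
    return(flagged(c(type_token_ratio = 0, brunet_index = 0,
                     honore_statistic = 0), "degenerate"))
  }
  tab <- table(tolower(tokens))
  v <- length(tab)
  v1 <- sum(tab == 1)
  ttr <- v / n
  w <- n^(v^(-0.165))
  denom <- 1 - v1 / v
  fl <- NULL
  if (denom < 1e-3) {
    denom <- 1e-3
    fl <- "honore_capped"
  }
  r <- 100 * log(n) / denom
  flagged(c(type_token_ratio = ttr, brunet_index = w, honore_statistic = r), fl)
}

#' Filled-pause frequency
#'
#' Counts lexicon hits (multiword entries matched as token n-grams,
#' counted once per occurrence) divided by the total token count.
#' @param tt A `tokenized_text`.
#' @param filler_lexicon Character vector of filler entries (lowercase;
#'   multiword entries space-separated).
#' @return Numeric scalar.
#' @export
filler_frequency <- function(tt, filler_lexicon) {
  stopifnot(length(filler_lexicon) > 0)
  tokens <- tolower(unlist(tt$sentences))
  n <- length(tokens)
  if (n == 0) return(flagged(0, "degenerate"))
  hits <- 0
  for (entry in filler_lexicon) {
    parts <- strsplit(entry, " ", fixed = TRUE)[[1]]
    k <- length(parts)
    if (k == 1) {
      hits <- hits + sum(tokens == entry)
    } else if (n >= k) {
      for (start in seq_len(n - k + 1)) {
        if (all(tokens[start:(start + k - 1)] == parts)) hits <- hits + 1
      }
    }
  }
  hits / n
}

#' Yngve depth of each word in a constituency tree
#'
#' Children of every node are indexed right-to-left starting at 0 (the
#' rightmost child has index 0); a word's Yngve depth is the sum of the
#' child indices along its root-to-leaf path — a classic measure of the
#' working-memory load of left-branching structure. Depths are returned
#' in word order.
#' @param tree A parse tree: a leaf is `list(token = "w")`; an internal
#'   node is `list(children = list(...))` with optional `label`.
#' @return Numeric vector, one depth per leaf in leaf order.
#' @examples
#' # (S (NP the cat) (VP sat)) -> depths 2 1 0
#' tree <- list(children = list(
#'   list(children = list(list(token = "the"), list(token = "cat"))),
#'   list(children = list(list(token = "sat")))))
#' yngve_depths(tree)
#' @export
yngve_depths <- function(tree) {
  walk <- function(node, acc) {
    if (!is.null(node$token)) return(acc)
    kids <- node$children
    stopifnot(length(kids) >= 1)
    idx <- rev(seq_along(kids)) - 1L  # right-to-left indices
    unlist(lapply(seq_along(kids), function(i) walk(kids[[i]], acc + idx[i])))
  }
  depths <- walk(tree, 0)
  if (is.null(depths)) stop("tree has no leaves")
  depths
}

#' Deterministic fallback constituency parse
#'
#' A strictly right-branching binary tree over the tokens, used when no
#' constituency-parser adapter is configured; under the Yngve measure it
#' assigns depth 1 to every non-final word and 0 to the last.
#' @param tokens Non-empty character vector.
#' @return A parse tree (see [yngve_depths()]).
#' @export
fallback_parse <- function(tokens) {
  if (length(tokens) == 0) stop("cannot parse an empty token list")
  if (length(tokens) == 1) return(list(token = tokens[1]))
  list(children = list(list(token = tokens[1]),
                       fallback_parse(tokens[-1])))
}

#' Yngve complexity statistics over the sentences of a text
#'
#' Per-sentence depths are computed with `parser` (default
#' [fallback_parse()]), then aggregated: `yngve_mean` is the mean over
#' sentences of the per-sentence mean depth, `yngve_total` the sum of all
#' word depths, `yngve_median` the median of per-sentence means.
#' @param tt A `tokenized_text`.
#' @param parser Function tokens -> parse tree.
#' @return Named numeric: `yngve_mean`, `yngve_total`, `yngve_median`.
#' @export
yngve_stats <- function(tt, parser = fallback_parse) {
  sents <- tt$sentences[lengths(tt$sentences) > 0]
  if (length(sents) == 0) {
    return(flagged(c(yngve_mean = 0, yngve_total = 0, yngve_median = 0),
                   "degenerate"))
  }
  per <- lapply(sents, function(tk) yngve_depths(parser(tk)))
  means <- vapply(per, mean, numeric(1))
  c(yngve_mean = mean(means),
    yngve_total = sum(unlist(per)),
    yngve_median = stats::median(means))
}

#' Pairwise sentence-similarity statistics
#'
#' Cosine similarity of raw term-count vectors over all unordered pairs
#' of sentences; aggregates over the pair list. Fewer than two sentences
#' yields all-zero statistics with a flag.
#' @param sentences List of token vectors.
#' @return Named numeric: `sentence_similarity_mean`, `_median`, `_sd`
#'   (population), `_max`.
#' @export
sentence_similarity_stats <- function(sentences) {
  sentences <- sentences[lengths(sentences) >= 0]
  k <- length(sentences)
  zero <- c(sentence_similarity_mean = 0, sentence_similarity_median = 0,
            sentence_similarity_sd = 0, sentence_similarity_max = 0)
  if (k < 2) return(flagged(zero, "degenerate"))
  vocab <- unique(unlist(sentences))
  if (length(vocab) == 0) return(flagged(zero, "degenerate"))
  counts <- t(vapply(sentences, function(s) {
    v <- numeric(length(vocab)); names(v) <- vocab
    tb <- table(s)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(vocab))))
  sims <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      sims <- c(sims, cosine_sim(counts[i, ], counts[j, ]))
    }
  }
  c(sentence_similarity_mean = mean(sims),
    sentence_similarity_median = stats::median(sims),
    sentence_similarity_sd = sd_pop(sims),
    sentence_similarity_max = max(sims))
}

#' Lexicon sentiment score of one sentence
#'
#' Additive valence model: the raw score `s` is the sum of the token
#' valences; `compound = s / sqrt(s^2 + 15)` maps it into (-1, 1).
#' `pos`/`neg`/`neu` are the normalized proportions of positive-valence
#' mass, absolute negative-valence mass and zero-valence token mass (one
#' unit per neutral token). Capitalization/punctuation boosting of the
#' full reference tool is deliberately not modeled.
#' @param sentence Character vector of tokens (matching is case-folded).
#' @param lexicon Named numeric vector: token -> valence.
#' @return A `sentiment_score`: list with `pos`, `neg`, `neu`,
#'   `compound`.
#' @examples
#' sentiment_score(c("i", "love", "it"), c(love = 2))
#' @export
sentiment_score <- function(sentence, lexicon) {
  stopifnot(length(lexicon) > 0)
  if (length(sentence) == 0) {
    return(structure(list(pos = 0, neg = 0, neu = 1, compound = 0),
                     class = "sentiment_score"))
  }
  val <- lexicon[tolower(sentence)]
  val[is.na(val)] <- 0
  s <- sum(val)
  compound <- s / sqrt(s^2 + 15)
  pos_m <- sum(val[val > 0])
  neg_m <- sum(-val[val < 0])
  neu_m <- sum(val == 0)
  total <- pos_m + neg_m + neu_m
  structure(list(pos = pos_m / total, neg = neg_m / total,
                 neu = neu_m / total, compound = compound),
            class = "sentiment_score")
}

#' Aggregate per-sentence sentiment scores
#'
#' For each channel (pos, neg, neu, compound): mean, median, population
#' SD and maximum over the sentence scores.
#' @param scores List of `sentiment_score` objects.
#' @return Named numeric vector `sentiment_<channel>_<stat>`.
#' @export
aggregate_sentiment <- function(scores) {
  channels <- c("pos", "neg", "neu", "compound")
  stats_names <- c("mean", "median", "sd", "max")
  out <- numeric(length(channels) * length(stats_names))
  names(out) <- as.vector(outer(channels, stats_names,
                                function(c, s) paste0("sentiment_", c, "_", s)))
  if (length(scores) == 0) return(flagged(out, "degenerate"))
  for (ch in channels) {
    x <- vapply(scores, function(s) s[[ch]], numeric(1))
    out[paste0("sentiment_", ch, "_mean")] <- mean(x)
    out[paste0("sentiment_", ch, "_median")] <- stats::median(x)
    out[paste0("sentiment_", ch, "_sd")] <- sd_pop(x)
    out[paste0("sentiment_", ch, "_max")] <- max(x)
  }
  out
}

#' Response-length statistics over a set of responses
#'
#' Word counts use whitespace tokenization; character counts exclude
#' nothing (whitespace included).
#' @param responses Character vector of response texts.
#' @return Named numeric: `response_length_total_words`, `_total_chars`,
#'   `_mean_words`, `_median_chars`, `_min_words`.
#' @export
response_length_stats <- function(responses) {
  zero <- c(response_length_total_words = 0, response_length_total_chars = 0,
            response_length_mean_words = 0, response_length_median_chars = 0,
            response_length_min_words = 0)
  if (length(responses) == 0) return(flagged(zero, "degenerate"))
  words <- vapply(responses, function(r) {
    length(tokenize(r)[[1]])
  }, numeric(1))
  chars <- nchar(responses)
  c(response_length_total_words = sum(words),
    response_length_total_chars = sum(chars),
    response_length_mean_words = mean(words),
    response_length_median_chars = stats::median(chars),
    response_length_min_words = min(words))
}
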