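dict_tagger <- function(map) {
  function(tokens) {
    out <- unname(map[tolower(tokens)])
    out[is.na(out)] <- "other"
    out
  }
}

test_that("tokenize_and_tag splits sentences and applies the tagger contract", {
  expect_length(tokenize_and_tag("")$sentences, 0)
  tt <- tokenize_and_tag("I run.", dict_tagger(c(i = "pronoun", run = "verb")))
  expect_equal(tt$pos_tags[[1]], c("pronoun", "verb"))
  tt2 <- tokenize_and_tag("One here. Two there now.")
  expect_length(tt2$sentences, 2)
  expect_equal(lengths(tt2$sentences), c(2L, 3L))
  expect_error(
    tokenize_and_tag("a b", function(t) stop("boom")), "tagger failed")
  expect_error(
    tokenize_and_tag("a b", function(t) "noun"), "2 tokens")
})

test_that("pos_profile counts frequencies, ratios and pronoun:noun", {
  mk <- function(tags) list(sentences = list(rep("w", length(tags))),
                            pos_tags = list(tags))
  p <- pos_profile(mk(c("noun", "noun", "verb", "pronoun")))
  expect_equal(unname(p["pos_freq_noun"]), 0.5)
  expect_equal(unname(p["pronoun_noun_ratio"]), 0.5)
  p2 <- pos_profile(mk(rep("verb", 5)))
  expect_equal(unname(p2["pos_freq_verb"]), 1)
  expect_equal(sum(p2[paste0("pos_freq_",
                             setdiff(COARSE_TAGS <- c("noun", "verb",
                               "adjective", "adverb", "pronoun",
                               "interjection", "filler", "other"), "verb"))]), 0)
  # 10-token mixed fixture against hand enumeration
  tags <- c("noun", "verb", "noun", "pronoun", "adverb",
            "filler", "noun", "adjective", "pronoun", "other")
  p3 <- pos_profile(mk(tags))
  expect_equal(unname(p3["pos_freq_noun"]), 3 / 10)
  expect_equal(unname(p3["pos_freq_pronoun"]), 2 / 10)
  expect_equal(unname(p3["pos_ratio_noun"]), 3 / 6)   # 6 open-class tokens
  expect_equal(unname(p3["pronoun_noun_ratio"]), 2 / 3)
  # degenerate input flagged
  p0 <- pos_profile(list(sentences = list(), pos_tags = list()))
  expect_true(all(p0 == 0))
  expect_equal(attr(p0, "flags"), "degenerate")
})

test_that("vocabulary richness matches direct evaluation of the formulas", {
  r <- vocabulary_richness(rep("the", 4))
  expect_equal(unname(r["type_token_ratio"]), 0.25)
  expect_equal(unname(r["honore_statistic"]), 100 * log(4), tolerance = 1e-10)
  expect_equal(unname(r["honore_statistic"]), 138.63, tolerance = 1e-3)

  # N=100, V=50, V1=25: 25 hapax types + 25 types repeated 3x
  toks <- c(paste0("h", 1:25), rep(paste0("r", 1:25), each = 3))
  expect_length(toks, 100)
  r2 <- vocabulary_richness(toks)
  expect_equal(unname(r2["brunet_index"]), 100^(50^(-0.165)), tolerance = 1e-12)
  expect_equal(unname(r2["brunet_index"]), 11.19, tolerance = 1e-3)
  expect_equal(unname(r2["honore_statistic"]), 100 * log(100) / 0.5,
               tolerance = 1e-12)
  expect_equal(unname(r2["honore_statistic"]), 921.03, tolerance = 1e-2)

  r1 <- vocabulary_richness("word")
  expect_equal(unname(r1["type_token_ratio"]), 1)
  expect_equal(unname(r1["brunet_index"]), 1)
  expect_equal(attr(r1, "flags"), "honore_capped")
  r0 <- vocabulary_richness(character(0))
  expect_true(all(r0 == 0))
  expect_equal(attr(r0, "flags"), "degenerate")
})

test_that("richness invariants: self-concatenation and order invariance", {
  set.seed(11)
  toks <- sample(letters[1:8], 30, replace = TRUE)
  ttr1 <- vocabulary_richness(toks)["type_token_ratio"]
  ttr2 <- vocabulary_richness(c(toks, toks))["type_token_ratio"]
  expect_lte(ttr2, ttr1)
  w1 <- vocabulary_richness(toks)["brunet_index"]
  w2 <- vocabulary_richness(sample(toks))["brunet_index"]
  expect_equal(unname(w1), unname(w2))
})

test_that("filler frequency counts single and multiword lexicon entries", {
  tt <- tokenize_and_tag("um I um left")
  expect_equal(filler_frequency(tt, c("um", "uh")), 0.5)
  expect_equal(filler_frequency(tokenize_and_tag("all clear here"),
                                c("um", "uh")), 0)
  # bigram entries counted once per occurrence (sliding-window oracle)
  tt2 <- tokenize_and_tag("you know I left you know")
  toks <- tolower(unlist(tt2$sentences))
  oracle <- sum(vapply(seq_len(length(toks) - 1), function(i) {
    all(toks[i:(i + 1)] == c("you", "know"))
  }, logical(1)))
  expect_equal(filler_frequency(tt2, "you know"), oracle / length(toks))
  expect_equal(oracle, 2)
})

test_that("yngve depths equal right-to-left child-index path sums", {
  leaf <- function(w) list(token = w)
  node <- function(...) list(children = list(...))
  expect_equal(yngve_depths(leaf("hi")), 0)
  # (S (NP the cat) (VP sat))
  tree <- node(node(leaf("the"), leaf("cat")), node(leaf("sat")))
  expect_equal(yngve_depths(tree), c(2, 1, 0))
  expect_equal(mean(yngve_depths(tree)), 1)
  # fully left-branching chains: first word depth n - 1
  left_chain <- function(n) {
    t <- leaf("w1")
    for (i in seq_len(n - 1)) t <- node(t, leaf(paste0("w", i + 1)))
    t
  }
  for (n in 2:5) {
    d <- yngve_depths(left_chain(n))
    expect_equal(d[1], n - 1)
    expect_equal(d, oracle_yngve(left_chain(n)))
  }
})

test_that("yngve_depths agrees with the path-enumeration oracle on random trees", {
  set.seed(42)
  random_tree <- function(tokens) {
    if (length(tokens) == 1) return(list(token = tokens))
    k <- sample(seq_len(length(tokens) - 1), 1)
    list(children = list(random_tree(tokens[1:k]),
                         random_tree(tokens[(k + 1):length(tokens)])))
  }
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    tree <- random_tree(paste0("t", 1:n))
    expect_equal(yngve_depths(tree), oracle_yngve(tree))
  }
})

test_that("fallback parse is right-branching with total depth n - 1", {
  expect_equal(yngve_depths(fallback_parse("a")), 0)
  expect_equal(yngve_depths(fallback_parse(c("a", "b", "c"))), c(1, 1, 0))
  for (n in 2:6) {
    expect_equal(sum(yngve_depths(fallback_parse(paste0("w", 1:n)))), n - 1)
  }
  expect_error(fallback_parse(character(0)), "empty")
})

test_that("sentence similarity stats match exhaustive pair enumeration", {
  two_same <- sentence_similarity_stats(list(c("a", "b"), c("a", "b")))
  expect_equal(unname(two_same["sentence_similarity_mean"]), 1)
  expect_equal(unname(two_same["sentence_similarity_sd"]), 0)
  disjoint <- sentence_similarity_stats(list(c("a"), c("b")))
  expect_equal(unname(disjoint["sentence_similarity_max"]), 0)

  sents <- list(c("the", "cat", "sat"), c("the", "dog"), c("cat", "dog", "dog"))
  vocab <- unique(unlist(sents))
  vecs <- lapply(sents, function(s) {
    v <- numeric(length(vocab)); names(v) <- vocab
    tb <- table(s); v[names(tb)] <- tb; v
  })
  pairwise <- c(oracle_cosine(vecs[[1]], vecs[[2]]),
                oracle_cosine(vecs[[1]], vecs[[3]]),
                oracle_cosine(vecs[[2]], vecs[[3]]))
  got <- sentence_similarity_stats(sents)
  expect_equal(unname(got["sentence_similarity_mean"]), mean(pairwise))
  expect_equal(unname(got["sentence_similarity_median"]), median(pairwise))
  expect_equal(unname(got["sentence_similarity_max"]), max(pairwise))
  # symmetry under sentence reordering
  got_rev <- sentence_similarity_stats(rev(sents))
  expect_equal(unname(got), unname(got_rev))
  # fewer than two sentences is flagged degenerate
  one <- sentence_similarity_stats(list(c("a")))
  expect_true(all(one == 0))
  expect_equal(attr(one, "flags"), "degenerate")
})

test_that("sentiment score follows the additive compound model", {
  lex <- c(love = 2, hate = -2)
  none <- sentiment_score(c("just", "words"), lex)
  expect_equal(none$compound, 0)
  expect_equal(none$neu, 1)
  one <- sentiment_score(c("i", "love"), lex)
  expect_equal(one$compound, 2 / sqrt(4 + 15), tolerance = 1e-12)
  expect_equal(one$compound, 0.4588, tolerance = 1e-4)
  both <- sentiment_score(c("love", "hate"), lex)
  expect_equal(both$compound, 0)
  empty <- sentiment_score(character(0), lex)
  expect_equal(empty$neu, 1)
  expect_equal(empty$compound, 0)
})

test_that("sentiment proportions sum to one and compound stays bounded", {
  lex <- test_lexicons$sentiment
  set.seed(7)
  for (i in 1:20) {
    toks <- sample(c(names(lex), "plain", "words"), sample(1:30, 1),
                   replace = TRUE)
    s <- sentiment_score(toks, lex)
    expect_equal(s$pos + s$neg + s$neu, 1, tolerance = 1e-6)
    expect_gt(s$compound, -1)
    expect_lt(s$compound, 1)
  }
})

test_that("sentiment aggregation equals direct recomputation", {
  lex <- c(good = 1, bad = -1)
  one <- aggregate_sentiment(list(sentiment_score(c("good", "day"), lex)))
  expect_equal(unname(one["sentiment_compound_mean"]),
               unname(one["sentiment_compound_max"]))
  expect_equal(unname(one["sentiment_compound_sd"]), 0)

  scores <- lapply(list(c("good"), c("bad"), c("good", "good"), c("so")),
                   sentiment_score, lexicon = lex)
  agg <- aggregate_sentiment(scores)
  comp <- vapply(scores, `[[`, numeric(1), "compound")
  expect_equal(unname(agg["sentiment_compound_mean"]), mean(comp))
  expect_equal(unname(agg["sentiment_compound_median"]), median(comp))
  expect_equal(unname(agg["sentiment_compound_sd"]),
               sqrt(mean((comp - mean(comp))^2)))
  expect_equal(unname(agg["sentiment_pos_max"]),
               max(vapply(scores, `[[`, numeric(1), "pos")))
  # mean 0 / sd / max example
  pair <- list(list(pos = 0.5, neg = 0, neu = 0.5, compound = 0.5),
               list(pos = 0, neg = 0.5, neu = 0.5, compound = -0.5))
  agg2 <- aggregate_sentiment(pair)
  expect_equal(unname(agg2["sentiment_compound_mean"]), 0)
  expect_equal(unname(agg2["sentiment_compound_sd"]), 0.5)
  expect_equal(unname(agg2["sentiment_compound_max"]), 0.5)
})

test_that("response length statistics match hand counts", {
  r <- response_length_stats(c("a b", "c"))
  expect_equal(unname(r["response_length_total_words"]), 3)
  expect_equal(unname(r["response_length_min_words"]), 1)
  r2 <- response_length_stats(c("a b", "", "c d e"))
  expect_equal(unname(r2["response_length_min_words"]), 0)
  resp <- c("one two three", "four", "", "five six", "seven eight nine ten")
  r3 <- response_length_stats(resp)
  expect_equal(unname(r3["response_length_total_words"]), 10)
  expect_equal(unname(r3["response_length_total_chars"]), sum(nchar(resp)))
  expect_equal(unname(r3["response_length_mean_words"]), 2)
  expect_equal(unname(r3["response_length_median_chars"]), median(nchar(resp)))
  expect_equal(unname(r3["response_length_min_words"]), 0)
})
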