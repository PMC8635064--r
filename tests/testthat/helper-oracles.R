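# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# cosine similarity by direct formula
oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
}

# AUC by enumerating every positive/negative pair
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# best-split Gini gain by exhaustive threshold enumeration
oracle_gini_gain <- function(x, y) {
  imp <- function(yy) {
    if (length(yy) == 0) return(0)
    p1 <- mean(yy == 1)
    1 - p1^2 - (1 - p1)^2
  }
  parent <- imp(y)
  vals <- sort(unique(x))
  if (length(vals) < 2) return(0)
  thr <- (vals[-1] + vals[-length(vals)]) / 2
  best <- Inf
  for (t in thr) {
    l <- y[x <= t]; r <- y[x > t]
    w <- (length(l) * imp(l) + length(r) * imp(r)) / length(y)
    if (w < best) best <- w
  }
  parent - best
}

# Yngve depths by materializing every root-to-leaf path and summing
# right-to-left child indices along it
oracle_yngve <- function(tree) {
  paths <- list()
  descend <- function(node, acc) {
    if (!is.null(node$token)) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    k <- length(node$children)
    for (i in seq_len(k)) descend(node$children[[i]], c(acc, k - i))
  }
  descend(tree, numeric(0))
  vapply(paths, sum, numeric(1))
}

# a small fixed well-formed transcript used across test files
fixture_transcript <- function() {
  parse_transcript(paste(
    "Q So, this first section is about family, friendships and relationships. Do you have important relationships in your life? Please describe them.",
    "A My husband and my daughter are the most important.",
    "A We talk every single day.",
    "Q What makes those relationships meaningful to you?",
    "A They give my life purpose. We share everything.",
    "Q Do you feel that there are people in your life who fully understand you?",
    "A Yes, my husband fully understands me.",
    "Q How often do you spend time with or connect (via phone, email, or social media) with others?",
    "A I call my son every day and we email once a week.",
    "Q Do you feel you are part of a larger community? Please explain.",
    "A Yes, I volunteer at the library.",
    "Q When you are feeling disconnected or isolated what do you do?",
    "A I call someone or take a walk.",
    sep = "\n"), "fixture01")
}

# shared lexicons/templates loaded once per test run
test_lexicons <- default_lexicons()
test_templates <- question_templates()

# generate a cohort, write it, extract features, assemble against a
# target column; returns list(table, target, cohort)
cohort_table <- function(cfg, target_col = "ucla", rule = "fixed",
                         cutoff = 40, demographics = TRUE) {
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  paths <- sort(list.files(file.path(dir, "transcripts"), full.names = TRUE))
  feats <- extract_features_dir(paths, templates = test_templates,
                                lexicons = test_lexicons)
  demo <- if (demographics) {
    co$scores[, c("participant_id", "gender", "age", "education",
                  "caucasian", "not_single")]
  } else NULL
  tab <- assemble_feature_table(feats,
                                co$scores[, c("participant_id", target_col)],
                                demographics = demo)
  tgt <- binarize_target(tab$scores[[target_col]], rule, cutoff,
                         name = target_col)
  unlink(dir, recursive = TRUE)
  list(table = tab, target = tgt, cohort = co)
}

null_config <- function(n, seed) {
  generator_config(n_participants = n, beta_fpp_density = 0,
                   beta_negative_sentiment = 0, beta_response_length = 0,
                   beta_relationship_count = 0, seed = seed)
}
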