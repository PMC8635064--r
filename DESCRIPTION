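Package: sociolex
Title: Linguistic Markers of Social Isolation and Loneliness in Interview Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting social isolation and loneliness in older
    adults from semi-structured interview transcripts. Parses Q/A-dialect
    transcripts, localizes template interview questions by TF-IDF cosine
    matching, extracts linguistic features (parts of speech, vocabulary
    richness, Yngve syntactic complexity, sentence similarity, lexicon
    sentiment, response length), pronoun densities and relationship-word
    counts, ranks features by Gini impurity, and evaluates binary
    classifiers of loneliness and social-support scales with
    leave-one-subject-out cross-validation. Includes a synthetic
    interview-cohort generator with controllable effect sizes for
    end-to-end testing, and group-comparison statistics for cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    optparse
Config/testthat/edition: 3
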