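# build a feature_table directly from a matrix (bypassing text extraction)
make_table <- function(x, scores = NULL) {
  ids <- sprintf("P%02d", seq_len(nrow(x)))
  feats <- cbind(data.frame(participant_id = ids), as.data.frame(x))
  sc <- data.frame(participant_id = ids,
                   score = scores %||% rep(0, nrow(x)))
  assemble_feature_table(feats, sc)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature table assembly joins, imputes and logs", {
  f <- data.frame(participant_id = c("a", "b", "c"), x1 = 1:3, x2 = c(4, NA, 6))
  s <- data.frame(participant_id = c("a", "b", "c", "d"), ucla = c(30, 45, 50, 60))
  tab <- assemble_feature_table(f, s)
  expect_equal(tab$participant_id, c("a", "b", "c"))
  expect_equal(tab$x$x2[2], 5)           # median of 4, 6
  expect_match(tab$imputation_log, "x2")
  expect_equal(tab$dropped, "d")
  expect_error(assemble_feature_table(rbind(f, f[1, ]), s), "duplicate")
  # categorical demographics are one-hot encoded
  d <- data.frame(participant_id = c("a", "b", "c"),
                  gender = c("woman", "man", "woman"), age = c(80, 85, 90))
  tab2 <- assemble_feature_table(f, s, d)
  expect_true(all(c("gender_man", "gender_woman", "age") %in% names(tab2$x)))
  expect_equal(tab2$x$gender_woman, c(1, 0, 1))
})

test_that("target binarization follows the strict-cutoff rule", {
  expect_equal(binarize_target(c(40, 41), "fixed", 40)$labels, c(0L, 1L))
  bt <- binarize_target(c(1, 2, 3, 4), "median")
  expect_equal(bt$cutoff_value, 2.5)
  expect_equal(bt$labels, c(0L, 0L, 1L, 1L))
  # scores exactly at the printed median cutoff are labeled 0
  ess_i <- c(0.5, 1, 2, 2, 2, 2.5, 3, 3)
  bt2 <- binarize_target(ess_i, "median", name = "ess_i")
  expect_equal(bt2$cutoff_value, 2.0)
  expect_equal(bt2$labels[ess_i <= 2], rep(0L, sum(ess_i <= 2)))
  bt3 <- binarize_target(c(1, 2, 3, 4, 10), "pct75")
  expect_equal(bt3$cutoff_value, unname(quantile(c(1, 2, 3, 4, 10), 0.75)))
  expect_error(binarize_target(rep(3, 5), "median"), "degenerate")
  expect_true(is.na(binarize_target(c(1, NA, 5), "fixed", 3)$labels[2]))
})

test_that("confusion metrics handle perfect and degenerate classifiers", {
  perfect <- confusion_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  z <- confusion_metrics(c(TP = 0, FP = 0, TN = 4, FN = 0))
  expect_equal(unname(z["sensitivity"]), 0)
  expect_equal(attr(z, "flags"), "zero_denominator")
})

test_that("weighted F1 lies between the two per-class F1 values", {
  set.seed(3)
  for (i in 1:30) {
    cm <- c(TP = sample(1:40, 1), FP = sample(1:40, 1),
            TN = sample(1:40, 1), FN = sample(1:40, 1))
    m <- confusion_metrics(cm)
    f1_pos <- 2 * cm["TP"] / (2 * cm["TP"] + cm["FP"] + cm["FN"])
    f1_neg <- 2 * cm["TN"] / (2 * cm["TN"] + cm["FN"] + cm["FP"])
    expect_gte(m[["f1_weighted"]], min(f1_pos, f1_neg) - 1e-12)
    expect_lte(m[["f1_weighted"]], max(f1_pos, f1_neg) + 1e-12)
    expect_equal(sum(cm), cm[["TP"]] + cm[["FP"]] + cm[["TN"]] + cm[["FN"]])
  }
})

test_that("roc_auc equals the all-pairs oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("gini gain matches exhaustive threshold enumeration", {
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  sep <- make_table(data.frame(f = c(1, 2, 3, 4, 10, 11, 12, 13)), y)
  tgt <- binarize_target(y, "fixed", 0.5)
  rk <- gini_rank(sep, tgt, features = "f")
  expect_equal(rk$gain, 0.5)
  const <- make_table(data.frame(f = rep(2, 8)), y)
  expect_equal(gini_rank(const, tgt, features = "f")$gain, 0)
  set.seed(5)
  x <- data.frame(a = rnorm(8), b = sample(c(1, 2), 8, TRUE),
                  c = runif(8), d = rep(1, 8))
  tab <- make_table(x, y)
  rk2 <- gini_rank(tab, tgt)
  for (f in names(x)) {
    expect_equal(rk2$gain[rk2$feature == f], oracle_gini_gain(x[[f]], y),
                 tolerance = 1e-12)
  }
  expect_error(gini_rank(tab, binarize_target(rep(c(0, 1), 4) * 0 + 1,
                                              "fixed", 0)), "constant target")
})

test_that("gini gain is invariant to strictly monotone feature transforms", {
  set.seed(8)
  y <- rbinom(12, 1, 0.5); y[1:2] <- c(0, 1)
  x <- rnorm(12)
  g0 <- oracle_gini_gain(x, y)
  tab_exp <- make_table(data.frame(f = exp(x)), y)
  tab_cub <- make_table(data.frame(f = x^3), y)
  tgt <- binarize_target(y, "fixed", 0.5)
  expect_equal(gini_rank(tab_exp, tgt, "f")$gain, g0, tolerance = 1e-12)
  expect_equal(gini_rank(tab_cub, tgt, "f")$gain, g0, tolerance = 1e-12)
})

test_that("gini rank breaks ties alphabetically", {
  y <- c(0, 0, 1, 1)
  tab <- make_table(data.frame(zeta = c(1, 2, 9, 10), alpha = c(1, 2, 9, 10)), y)
  rk <- gini_rank(tab, binarize_target(y, "fixed", 0.5))
  expect_equal(rk$feature, c("alpha", "zeta"))
})

test_that("LOOCV separates a separable cohort and nails a label-copy feature", {
  set.seed(21)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  x <- data.frame(f1 = y * 6 + rnorm(n, sd = 0.3),
                  f2 = -y * 6 + rnorm(n, sd = 0.3))
  tab <- make_table(x, y)
  tgt <- binarize_target(y, "fixed", 0.5)
  ev <- loocv_evaluate(tab, tgt, model_spec("svm_rbf", seed = 4))
  expect_equal(unname(ev$confusion[c("FP", "FN")]), c(0L, 0L))
  expect_equal(ev$auc, 1)
  # single feature equal to the label
  tab2 <- make_table(data.frame(f = y), y)
  for (fam in c("tree", "knn")) {
    ev2 <- loocv_evaluate(tab2, tgt, model_spec(fam, seed = 1))
    expect_equal(ev2$sensitivity, 1)
    expect_equal(ev2$specificity, 1)
  }
})

test_that("LOOCV is invariant to participant row order", {
  set.seed(31)
  n <- 16
  y <- rbinom(n, 1, 0.5); y[1:4] <- c(0, 0, 1, 1)
  x <- data.frame(a = rnorm(n) + y, b = rnorm(n))
  tab <- make_table(x, y)
  tgt <- binarize_target(y, "fixed", 0.5)
  perm <- sample(n)
  tab_p <- make_table(x[perm, , drop = FALSE], y[perm])
  tgt_p <- binarize_target(y[perm], "fixed", 0.5)
  for (fam in c("knn", "tree", "svm_rbf")) {
    ev1 <- loocv_evaluate(tab, tgt, model_spec(fam, seed = 2))
    ev2 <- loocv_evaluate(tab_p, tgt_p, model_spec(fam, seed = 2))
    expect_equal(ev1$confusion, ev2$confusion)
    expect_equal(ev1$auc, ev2$auc)
    expect_equal(sum(ev1$confusion), n)
  }
})

test_that("LOOCV errors when a class would vanish from a training fold", {
  y <- c(0, 1, 1, 1, 1, 1)
  tab <- make_table(data.frame(f = rnorm(6)), y)
  expect_error(loocv_evaluate(tab, binarize_target(y, "fixed", 0.5),
                              model_spec("tree")), "per class")
})

test_that("shuffled labels give chance-level pooled AUC", {
  set.seed(77)
  n <- 40
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  aucs <- replicate(60, {
    y <- sample(rep(c(0, 1), each = n / 2))
    tab <- make_table(x, y)
    loocv_evaluate(tab, binarize_target(y, "fixed", 0.5),
                   model_spec("knn", seed = 1))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("the three ANN activations train and the logistic net matches nnet", {
  skip_if_not_installed("nnet")
  set.seed(12)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = y * 3 + rnorm(n, sd = 0.5), b = rnorm(n))
  for (act in c("logistic", "tanh", "relu")) {
    fit <- mlp_fit(x, y, hidden = 20, activation = act, seed = 5)
    expect_equal(roc_auc(predict(fit, x), y), 1)
  }
  # independent reference: single-hidden-layer logistic net from nnet
  ref <- nnet::nnet(x, y, size = 20, decay = 1e-4, maxit = 500, trace = FALSE)
  expect_equal(roc_auc(drop(predict(ref, x)), y), 1)
})

test_that("incremental selection finds a small planted subset", {
  set.seed(19)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(x) <- paste0("noise", 1:10)
  x$signal <- y * 4 + rnorm(n, sd = 0.5)
  tab <- make_table(x, y)
  tgt <- binarize_target(y, "fixed", 0.5)
  sel <- incremental_selection(tab, tgt, model_spec("tree", seed = 3),
                               k_max = 5)
  expect_true("signal" %in% sel$best_features)
  expect_lte(sel$best_k, 3)
  expect_equal(nrow(sel$curve), 5)
  sel1 <- incremental_selection(tab, tgt, model_spec("tree", seed = 3),
                                k_max = 1)
  expect_equal(nrow(sel1$curve), 1)
})
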