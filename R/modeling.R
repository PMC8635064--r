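#' Assemble the participant-by-feature modeling table
#'
#' Inner-joins extracted features, target scale scores and (optionally)
#' sociodemographics on participant id. Categorical demographic columns
#' are one-hot encoded; missing numeric feature values are imputed by the
#' column median, with an imputation log. Participants present in one
#' input but not another are dropped and logged.
#'
#' @param features data.frame with `participant_id` plus numeric feature
#'   columns (as from [extract_features_dir()]).
#' @param scores data.frame with `participant_id` plus target scale
#'   columns (e.g. `ucla`, `ess_e`, `ess_i`, `ess_ni`, `ssi`).
#' @param demographics Optional data.frame with `participant_id` plus
#'   demographic columns; character/factor columns are one-hot encoded.
#' @return A `feature_table`: list with `participant_id`, `x` (numeric
#'   feature data.frame), `scores` (data.frame), `imputation_log`,
#'   `dropped`.
#' @export
assemble_feature_table <- function(features, scores, demographics = NULL) {
  stopifnot("participant_id" %in% names(features),
            "participant_id" %in% names(scores))
  for (d in list(features, scores, demographics)) {
    if (!is.null(d) && anyDuplicated(d$participant_id)) {
      stop("duplicate participant ids in input table")
    }
  }
  ids <- intersect(features$participant_id, scores$participant_id)
  if (!is.null(demographics)) ids <- intersect(ids, demographics$participant_id)
  dropped <- setdiff(unique(c(features$participant_id, scores$participant_id,
                              demographics$participant_id)), ids)
  x <- features[match(ids, features$participant_id),
                setdiff(names(features), "participant_id"), drop = FALSE]
  if (!is.null(demographics)) {
    dd <- demographics[match(ids, demographics$participant_id),
                       setdiff(names(demographics), "participant_id"),
                       drop = FALSE]
    x <- cbind(x, one_hot(dd))
  }
  if (anyDuplicated(names(x))) stop("duplicate feature column names")
  log <- character(0)
  for (cn in names(x)) {
    miss <- is.na(x[[cn]])
    if (any(miss)) {
      med <- stats::median(x[[cn]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      x[[cn]][miss] <- med
      log <- c(log, sprintf("%s: imputed %d value(s) to median %.4g",
                            cn, sum(miss), med))
    }
  }
  sc <- scores[match(ids, scores$participant_id),
               setdiff(names(scores), "participant_id"), drop = FALSE]
  rownames(x) <- rownames(sc) <- NULL
  structure(list(participant_id = ids, x = x, scores = sc,
                 imputation_log = log, dropped = dropped),
            class = "feature_table")
}

one_hot <- function(d) {
  out <- list()
  for (cn in names(d)) {
    v <- d[[cn]]
    if (is.numeric(v)) {
      out[[cn]] <- v
    } else {
      v <- as.character(v)
      for (lev in sort(unique(v[!is.na(v)]))) {
        out[[paste0(cn, "_", lev)]] <- as.numeric(v == lev)
      }
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", length(x$participant_id), "participants x",
      ncol(x$x), "features;", ncol(x$scores), "target scores\n")
  invisible(x)
}

#' Binarize a target scale score
#'
#' `label = 1` iff the score is strictly greater than the cutoff. The
#' fixed rule uses a supplied cutoff (40 on the UCLA-3 loneliness scale:
#' scores above 40 are categorized lonely); the `median` and `pct75`
#' rules take the empirical 50th / 75th percentile of the observed
#' scores.
#' @param scores Numeric vector (NAs allowed; their labels are `NA`).
#' @param rule `"fixed"`, `"median"` or `"pct75"`.
#' @param cutoff Cutoff for the fixed rule (default 40).
#' @param name Target name for reporting.
#' @return A `binary_target`: list with `name`, `rule`, `cutoff_value`,
#'   `labels` (0/1 integer vector).
#' @examples
#' binarize_target(c(40, 41), "fixed", 40)$labels
#' @export
binarize_target <- function(scores, rule = c("fixed", "median", "pct75"),
                            cutoff = 40, name = "target") {
  rule <- match.arg(rule)
  obs <- scores[!is.na(scores)]
  if (rule != "fixed") {
    if (length(unique(obs)) < 2) {
      stop("degenerate target '", name, "': all observed scores identical")
    }
    cutoff <- if (rule == "median") stats::median(obs) else
      unname(stats::quantile(obs, 0.75))
  }
  structure(list(name = name, rule = rule, cutoff_value = cutoff,
                 labels = as.integer(scores > cutoff)),
            class = "binary_target")
}

#' Model specification for the classifier suite
#'
#' Families and default hyperparameters mirror the study's classifier
#' grid: one-hidden-layer neural networks (logistic / tanh activations
#' with 200 hidden units, relu with 100, Adam), RBF-kernel SVM (cost 1,
#' tolerance 0.001, epsilon 0.1), kNN (k = 9, Chebyshev metric, distance
#' weighting), a fully grown decision tree (min leaf 1), and a small
#' random forest (8 trees, 4 attributes per split, depth limit 7).
#' @param family One of `"ann_logistic"`, `"ann_tanh"`, `"ann_relu"`,
#'   `"svm_rbf"`, `"knn"`, `"tree"`, `"random_forest"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer training seed.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("ann_logistic", "ann_tanh", "ann_relu",
                                  "svm_rbf", "knn", "tree", "random_forest"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    ann_logistic = list(hidden = 200, activation = "logistic",
                        max_epochs = 1000, tol = 1e-4),
    ann_tanh = list(hidden = 200, activation = "tanh",
                    max_epochs = 1000, tol = 1e-4),
    ann_relu = list(hidden = 100, activation = "relu",
                    max_epochs = 1000, tol = 1e-4),
    svm_rbf = list(cost = 1, tolerance = 0.001, epsilon = 0.1),
    knn = list(k = 9),
    tree = list(max_depth = 30, min_leaf = 1),
    random_forest = list(n_trees = 8, mtry = 4, max_nodes = 128)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

# fit on training data and score test rows; returns numeric scores where
# larger means more class-1
fit_and_score <- function(spec, x_train, y_train, x_test, fold_seed) {
  hp <- spec$hyperparameters
  switch(spec$family,
    ann_logistic = , ann_tanh = , ann_relu = {
      fit <- mlp_fit(x_train, y_train, hidden = hp$hidden,
                     activation = hp$activation, max_epochs = hp$max_epochs,
                     tol = hp$tol, seed = fold_seed)
      predict(fit, x_test)
    },
    svm_rbf = {
      fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                        kernel = "radial", cost = hp$cost,
                        tolerance = hp$tolerance, epsilon = hp$epsilon,
                        scale = FALSE)
      pr <- predict(fit, x_test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the decision value so larger means class "1"
      if (grepl("^0/1$", colnames(dv)[1])) -drop(dv) else drop(dv)
    },
    knn = {
      knn_score(x_train, y_train, x_test, k = hp$k)
    },
    tree = {
      df <- as.data.frame(x_train)
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$.y <- factor(y_train, levels = c(0, 1))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = hp$min_leaf, cp = 0,
                            maxdepth = hp$max_depth, xval = 0))
      nd <- as.data.frame(x_test)
      names(nd) <- paste0("f", seq_len(ncol(nd)))
      predict(fit, nd, type = "prob")[, "1"]
    },
    random_forest = {
      old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(fold_seed)
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
      fit <- randomForest::randomForest(
        x_train, factor(y_train, levels = c(0, 1)),
        ntree = hp$n_trees, mtry = min(hp$mtry, ncol(x_train)),
        maxnodes = hp$max_nodes, nodesize = 1)
      predict(fit, x_test, type = "prob")[, "1"]
    },
    stop("unknown model family: ", spec$family)
  )
}

# Chebyshev-metric, distance-weighted k-nearest-neighbor score
knn_score <- function(x_train, y_train, x_test, k = 9) {
  k <- min(k, nrow(x_train))
  apply(as.matrix(x_test), 1, function(q) {
    d <- apply(abs(sweep(as.matrix(x_train), 2, q)), 1, max)
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (any(dn == 0)) return(mean(y_train[nn[dn == 0]]))
    w <- 1 / dn
    sum(w * y_train[nn]) / sum(w)
  })
}

# score threshold separating predicted classes; decision-value models
# (svm) split at 0, probability models at 0.5
score_threshold <- function(family) if (family == "svm_rbf") 0 else 0.5

#' Leave-one-subject-out cross-validated evaluation
#'
#' For each participant the model is fit on all others — features
#' z-scored with training-fold statistics only — and the held-out label
#' and decision score are predicted. Fold scores are pooled into one
#' confusion matrix and one ROC AUC. Deterministic given the spec seed.
#' @param table A `feature_table`.
#' @param target A `binary_target` aligned with the table rows
#'   (participants with `NA` labels are dropped for this target).
#' @param spec A `model_spec`.
#' @param feature_subset Character vector of feature column names to use
#'   (default: all).
#' @return An `eval_result`: list with `folds` (data.frame of per-fold
#'   id, label, score, predicted), `confusion` (TP/FP/TN/FN), and the
#'   metrics `sensitivity`, `specificity`, `f1_weighted`, `auc`.
#' @export
loocv_evaluate <- function(table, target, spec, feature_subset = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(target, "binary_target"),
            inherits(spec, "model_spec"))
  if (is.null(feature_subset)) feature_subset <- names(table$x)
  if (length(feature_subset) == 0) stop("empty feature subset")
  missing_f <- setdiff(feature_subset, names(table$x))
  if (length(missing_f) > 0) stop("unknown features: ", paste(missing_f, collapse = ", "))
  keep <- !is.na(target$labels)
  y <- target$labels[keep]
  x <- as.matrix(table$x[keep, feature_subset, drop = FALSE])
  ids <- table$participant_id[keep]
  n <- length(y)
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    stop("need at least 2 participants per class for LOOCV")
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2) stop("a class is absent from a training fold")
    mu <- colMeans(x[-i, , drop = FALSE])
    sg <- apply(x[-i, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | is.na(sg)] <- 1
    xt <- sweep(sweep(x[-i, , drop = FALSE], 2, mu), 2, sg, "/")
    xh <- sweep(sweep(x[i, , drop = FALSE], 2, mu), 2, sg, "/")
    # one seed for every fold keeps results invariant to row order
    scores[i] <- fit_and_score(spec, xt, y[-i], xh, fold_seed = spec$seed)
  }
  pred <- as.integer(scores > score_threshold(spec$family))
  cm <- c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
          TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
  metrics <- confusion_metrics(cm)
  structure(list(
    folds = data.frame(participant_id = ids, label = y, score = scores,
                       predicted = pred, stringsAsFactors = FALSE),
    confusion = cm,
    sensitivity = metrics[["sensitivity"]],
    specificity = metrics[["specificity"]],
    f1_weighted = metrics[["f1_weighted"]],
    auc = roc_auc(scores, y)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>", sum(x$confusion), "participants\n")
  cat(sprintf("  confusion TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  F1(weighted) %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$f1_weighted, x$auc))
  invisible(x)
}

#' Sensitivity, specificity and support-weighted F1 from a confusion matrix
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`; the weighted
#' F1 is the support-weighted mean of the two per-class F1 scores (class
#' supports `TP+FN` and `TN+FP`) — the averaging mode that reconciles
#' the published confusion matrices with their printed F1 values. Zero
#' denominators yield 0 with a flag.
#' @param cm Named numeric with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric: `sensitivity`, `specificity`, `f1_weighted`.
#' @examples
#' confusion_metrics(c(TP = 24, FP = 12, TN = 37, FN = 11))
#' @export
confusion_metrics <- function(cm) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(cm)), all(cm >= 0),
            sum(cm) > 0)
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  safe <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec1 <- safe(tp, tp + fp); rec1 <- sens
  f1_1 <- safe(2 * prec1 * rec1, prec1 + rec1)
  prec0 <- safe(tn, tn + fn); rec0 <- spec
  f1_0 <- safe(2 * prec0 * rec0, prec0 + rec0)
  n1 <- tp + fn; n0 <- tn + fp
  fl <- if (any(c(tp + fn, tn + fp, prec1 + rec1, prec0 + rec0) == 0))
    "zero_denominator" else NULL
  flagged(c(sensitivity = sens, specificity = spec,
            f1_weighted = (n1 * f1_1 + n0 * f1_0) / (n1 + n0)), fl)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, counting ties as one half.
#' @param scores Numeric decision scores (larger = more positive class).
#' @param labels 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank features by Gini impurity reduction
#'
#' For each feature, the gain is the parent Gini impurity
#' `1 - p0^2 - p1^2` minus the minimum support-weighted child impurity
#' over all single-threshold binary splits of that feature (a decision
#' stump); features are ranked by decreasing gain, ties broken
#' alphabetically. A feature that perfectly separates a balanced target
#' gains 0.5; a constant feature gains 0.
#' @param table A `feature_table`.
#' @param target A `binary_target` aligned with the table rows.
#' @param features Character vector of columns to rank (default all).
#' @return data.frame with `feature`, `gain`, `rank`.
#' @export
gini_rank <- function(table, target, features = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(target, "binary_target"))
  if (is.null(features)) features <- names(table$x)
  keep <- !is.na(target$labels)
  y <- target$labels[keep]
  if (length(unique(y)) < 2) stop("constant target: cannot rank features")
  gains <- vapply(features, function(f) {
    gini_gain(table$x[[f]][keep], y)
  }, numeric(1))
  ord <- order(-gains, features)
  data.frame(feature = features[ord], gain = unname(gains[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

gini_impurity <- function(y) {
  p <- table(factor(y, levels = c(0, 1))) / length(y)
  1 - sum(p^2)
}

# best single-threshold split gain of one feature, via sorted cumulative
# class counts; thresholds fall between distinct consecutive values
gini_gain <- function(x, y) {
  n <- length(y)
  parent <- gini_impurity(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cum1 <- cumsum(ys); cum0 <- cumsum(1 - ys)
  cut_ok <- which(diff(xs) > 0)
  if (length(cut_ok) == 0) return(0)
  nl <- cut_ok
  l1 <- cum1[cut_ok]; l0 <- cum0[cut_ok]
  r1 <- cum1[n] - l1; r0 <- cum0[n] - l0
  nr <- n - nl
  imp_l <- 1 - (l1 / nl)^2 - (l0 / nl)^2
  imp_r <- 1 - (r1 / nr)^2 - (r0 / nr)^2
  child <- (nl * imp_l + nr * imp_r) / n
  parent - min(child)
}

#' Incremental top-k feature selection over a Gini ranking
#'
#' Evaluates [loocv_evaluate()] on the top-1, top-2, ..., top-`k_max`
#' ranked features and returns the k maximizing AUC (ties to the smaller
#' k) together with the full performance curve. The ranking is computed
#' once on the full table and frozen, which mirrors the incremental
#' procedure but carries an optimistic selection bias (documented in the
#' methods vignette).
#' @param table A `feature_table`.
#' @param target A `binary_target`.
#' @param spec A `model_spec`.
#' @param ranked data.frame from [gini_rank()] (computed if `NULL`).
#' @param k_max Largest subset size to try.
#' @return List with `best_k`, `best_features`, `best` (the
#'   `eval_result` at `best_k`) and `curve` (data.frame k, auc,
#'   f1_weighted).
#' @export
incremental_selection <- function(table, target, spec, ranked = NULL,
                                  k_max = 10) {
  if (is.null(ranked)) ranked <- gini_rank(table, target)
  stopifnot(k_max >= 1, k_max <= nrow(ranked))
  evals <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    evals[[k]] <- loocv_evaluate(table, target, spec,
                                 feature_subset = ranked$feature[seq_len(k)])
  }
  curve <- data.frame(
    k = seq_len(k_max),
    auc = vapply(evals, `[[`, numeric(1), "auc"),
    f1_weighted = vapply(evals, `[[`, numeric(1), "f1_weighted")
  )
  best_k <- which.max(curve$auc)  # earliest (smallest k) wins ties
  list(best_k = best_k, best_features = ranked$feature[seq_len(best_k)],
       best = evals[[best_k]], curve = curve)
}
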