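# Random-forest evaluation of feature tables: stratified 5-fold
# cross-validation, impurity importances, top-k multimodal fusion and the
# comparison against behavioural reference accuracy.

#' Random-forest configuration
#'
#' Defaults reproduce the study's classifier settings: 100 trees, maximum
#' depth 10, minimum split size 2 and leaf size 1, bootstrap sampling, Gini
#' impurity, square-root feature subsampling ("auto" rule for
#' classification), fixed random state 42, balanced class weights, no
#' out-of-bag scoring, and 5-fold stratified cross-validation in which each
#' fold's 20% hold-out is the test set.
#'
#' @param n_estimators,max_depth,min_samples_split,min_samples_leaf,bootstrap,criterion,max_features,random_state,class_weight,oob,n_folds,test_fraction
#'   See description; passed to the forest backend.
#' @return A `model_config` list.
#' @export
model_config <- function(n_estimators = 100, max_depth = 10,
                         min_samples_split = 2, min_samples_leaf = 1,
                         bootstrap = TRUE, criterion = "gini",
                         max_features = "sqrt", random_state = 42,
                         class_weight = "balanced", oob = FALSE,
                         n_folds = 5, test_fraction = 0.20) {
  if (criterion != "gini") stop("only the Gini criterion is supported", call. = FALSE)
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf, bootstrap = bootstrap,
                 criterion = criterion, max_features = max_features,
                 random_state = random_state, class_weight = class_weight,
                 oob = oob, n_folds = n_folds, test_fraction = test_fraction),
            class = "model_config")
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin. Dealing continues cyclically from one class to the next so
# that total fold sizes stay balanced (difference at most one) even when the
# per-class counts leave remainders; otherwise the fold-mean of accuracies
# can drift from the pooled rate for degenerate constant classifiers.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    start <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (start + seq_along(idx) - 1L) %% n_folds + 1L
      start <- start + length(idx)
    }
    fold
  })
}

fold_metrics <- function(truth, pred) {
  acc <- mean(pred == truth)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = acc, precision = precision, f1 = f1, recall = recall)
}

#' Train and evaluate a random forest by stratified cross-validation
#'
#' Partitions the trials into `config$n_folds` stratified folds; each fold in
#' turn is the 20% test split while the forest is fitted on the remainder.
#' Accuracy, precision and F1 (positive class = correct response) are scored
#' on every hold-out and the fold mean is the reported result. Impurity
#' importances are averaged over folds and normalised to sum 1.
#'
#' @param table A `feature_table`.
#' @param config A [model_config()].
#' @param seed Seed controlling folds and tree growing; defaults to the
#'   config's `random_state`, making repeated calls identical.
#' @return An `rf_eval` object: `folds` (per-fold metric data frame), `mean`
#'   and `sd` of each metric, `importances` (named, sums to 1), `level`,
#'   `subject_id`, dimensions and the config.
#' @export
train_eval <- function(table, config = model_config(),
                       seed = config$random_state) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < config$n_folds) {
    stop("need at least n_folds trials in each class", call. = FALSE)
  }
  fold <- stratified_folds(y, config$n_folds, seed)
  p <- ncol(table$matrix)
  mtry <- if (identical(config$max_features, "sqrt") ||
              identical(config$max_features, "auto")) {
    max(1L, floor(sqrt(p)))
  } else {
    min(p, max(1L, as.integer(config$max_features)))
  }
  yf <- factor(y, levels = c(0, 1))
  class_weights <- if (identical(config$class_weight, "balanced")) {
    n <- length(y)
    as.numeric(n / (2 * table(yf)))
  } else {
    c(1, 1)
  }
  metrics <- matrix(NA_real_, config$n_folds, 4,
                    dimnames = list(NULL, c("accuracy", "precision", "f1",
                                            "recall")))
  imp <- matrix(0, config$n_folds, p,
                dimnames = list(NULL, colnames(table$matrix)))
  df <- as.data.frame(table$matrix)
  names(df) <- paste0("f", seq_len(p))   # syntactic names for the backend
  for (k in seq_len(config$n_folds)) {
    tr <- fold != k
    if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) {
      stop("a class is absent from a fold; reduce n_folds", call. = FALSE)
    }
    fit <- ranger::ranger(
      x = df[tr, , drop = FALSE], y = yf[tr],
      num.trees = config$n_estimators,
      mtry = mtry,
      min.node.size = config$min_samples_leaf,
      max.depth = config$max_depth,
      replace = config$bootstrap,
      sample.fraction = 1,
      splitrule = "gini",
      class.weights = class_weights,
      importance = "impurity",
      oob.error = config$oob,
      seed = seed + k,
      num.threads = 1
    )
    # prediction runs under a derived seed: vote ties are broken via the R
    # RNG, which would otherwise make repeated evaluations differ
    pred <- with_seed(seed + 7919 + k, as.integer(as.character(
      predict(fit, data = df[!tr, , drop = FALSE],
              num.threads = 1)$predictions)))
    metrics[k, ] <- fold_metrics(y[!tr], pred)
    fi <- fit$variable.importance
    total <- sum(fi)
    imp[k, ] <- if (total > 0) fi / total else rep(1 / p, p)
  }
  importances <- colMeans(imp)
  importances <- importances / sum(importances)
  structure(list(
    folds = data.frame(fold = seq_len(config$n_folds), metrics),
    mean = colMeans(metrics),
    sd = apply(metrics, 2L, sd),
    importances = importances,
    level = if (length(unique(table$subject_ids)) > 1L) "group" else "subject",
    subject_id = if (length(unique(table$subject_ids)) == 1L)
      unique(table$subject_ids) else NA_character_,
    n_trials = nrow(table$matrix),
    n_features = p,
    config = config,
    seed = seed
  ), class = "rf_eval")
}

#' @export
print.rf_eval <- function(x, ...) {
  cat(sprintf("<rf_eval> %s-level%s: %d trials x %d features, %d folds\n",
              x$level,
              if (!is.na(x$subject_id)) paste0(" (", x$subject_id, ")") else "",
              x$n_trials, x$n_features, nrow(x$folds)))
  cat(sprintf("  accuracy %.3f (sd %.3f), precision %.3f, F1 %.3f\n",
              x$mean["accuracy"], x$sd["accuracy"],
              x$mean["precision"], x$mean["f1"]))
  invisible(x)
}

#' @export
summary.rf_eval <- function(object, n_top = 10, ...) {
  print(object)
  cat("  top features by impurity importance:\n")
  top <- importance_ranking(object, min(n_top, object$n_features))
  for (nm in top) {
    cat(sprintf("    %-36s %.4f\n", nm, object$importances[nm]))
  }
  invisible(object)
}

#' Top-k features by impurity importance
#'
#' Importances are the fold-averaged, normalised impurity scores of a fitted
#' evaluation; ties break deterministically by feature name.
#'
#' @param report An `rf_eval`.
#' @param k Number of features to return (<= feature count).
#' @return Character vector of k feature names, best first.
#' @export
importance_ranking <- function(report, k) {
  stopifnot(inherits(report, "rf_eval"))
  imp <- report$importances
  if (k > length(imp)) stop("`k` exceeds the feature count", call. = FALSE)
  names(imp)[order(-imp, names(imp))][seq_len(k)]
}

#' Fuse the top-k features of two modalities
#'
#' Column-concatenates the top `k_each` features from the EEG and image
#' rankings into one multimodal table of width `2 * k_each` (ten features at
#' the default 5 + 5). Rankings default to fresh evaluations of each table.
#'
#' @param eeg_table,image_table Row-aligned `feature_table`s.
#' @param k_each Features taken from each modality (>= 1).
#' @param eeg_ranking,image_ranking Optional precomputed rankings
#'   (character vectors, best first), e.g. from a group-level evaluation.
#' @param config,seed Passed to [train_eval()] when a ranking is computed.
#' @return The fused `feature_table`.
#' @export
fuse <- function(eeg_table, image_table, k_each = 5,
                 eeg_ranking = NULL, image_ranking = NULL,
                 config = model_config(), seed = config$random_state) {
  if (k_each < 1) stop("`k_each` must be >= 1", call. = FALSE)
  eeg_ranking <- eeg_ranking %||%
    importance_ranking(train_eval(eeg_table, config, seed), ncol(eeg_table$matrix))
  image_ranking <- image_ranking %||%
    importance_ranking(train_eval(image_table, config, seed), ncol(image_table$matrix))
  bind_features(select_features(eeg_table, eeg_ranking[seq_len(k_each)]),
                select_features(image_table, image_ranking[seq_len(k_each)]))
}

#' Behavioural reference accuracy
#'
#' The participant's own proportion of correct responses — the bar a
#' decision-correctness predictor must beat to be informative.
#'
#' @param behavior Behaviour table.
#' @param subject_id Optional subject; `NULL` pools all rows.
#' @return Fraction in \[0, 1\].
#' @export
reference_accuracy <- function(behavior, subject_id = NULL) {
  rows <- if (is.null(subject_id)) behavior else
    behavior[behavior$subject_id == subject_id, , drop = FALSE]
  if (!nrow(rows)) stop("no behaviour rows selected", call. = FALSE)
  mean(rows$label)
}

#' Compare model accuracy to the behavioural reference
#'
#' Passing requires the mean cross-validated accuracy to *strictly* exceed
#' the reference accuracy; equality fails.
#'
#' @param report An `rf_eval`.
#' @param reference Reference accuracy in \[0, 1\].
#' @return List with `passes_reference` and `margin` (accuracy - reference).
#' @export
compare_to_reference <- function(report, reference) {
  stopifnot(inherits(report, "rf_eval"))
  stopifnot_scalar(reference, "reference", lower = 0, upper = 1)
  acc <- unname(report$mean["accuracy"])
  list(passes_reference = acc > reference, margin = acc - reference)
}

#' Paired t-test across subjects
#'
#' Two-sided paired t-test on per-subject metric differences (df = n - 1).
#' Zero-variance differences are reported as degenerate: t = 0, p = 1 for
#' identical vectors; |t| = Inf, p = 0 for a constant non-zero difference.
#'
#' @param values_a,values_b Equal-length paired per-subject metrics.
#' @param contrast Label for the comparison.
#' @return A `paired_comparison`: `contrast`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_difference`, `degenerate`.
#' @export
paired_subject_test <- function(values_a, values_b, contrast = "a vs b") {
  n <- length(values_a)
  if (length(values_b) != n || n < 2L) {
    stop("need equal-length paired vectors with n >= 2", call. = FALSE)
  }
  d <- values_a - values_b
  if (sd(d) == 0) {
    res <- list(contrast = contrast,
                t_statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                degrees_of_freedom = n - 1L,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d),
                degenerate = TRUE)
  } else {
    tt <- t.test(values_a, values_b, paired = TRUE)
    res <- list(contrast = contrast,
                t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_value = tt$p.value,
                mean_difference = unname(tt$estimate),
                degenerate = FALSE)
  }
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3g, p = %.3g (mean diff %.4f)%s\n",
              x$contrast, x$degrees_of_freedom, x$t_statistic, x$p_value,
              x$mean_difference, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
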