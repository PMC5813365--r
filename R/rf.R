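# Biomarker module: CPM/log2 normalization, balanced-bootstrap random
# forests (equal per-class draws per tree, so votes are not dominated by the
# majority class), stratified cross-validated rank AUC, and backward feature
# pruning over geometrically shrinking top-importance subsets, reporting both
# the full and the best model.

#' Normalize a count matrix into a feature table
#'
#' Counts-per-million per sample, then log2(x + 1); features with zero total
#' count are dropped.
#'
#' @param matrix numeric count matrix (features x samples).
#' @param sheet sample sheet data.frame (sample_id, group) covering all
#'   columns.
#' @return object of class `feature_table`: list(x = samples x features
#'   matrix, labels = 2-level factor).
#' @export
normalize_counts <- function(matrix, sheet) {
  tot <- colSums(matrix)
  if (any(tot == 0)) {
    stop("sample with zero total count: ",
         colnames(matrix)[tot == 0][1L], call. = FALSE)
  }
  keep <- rowSums(matrix) > 0
  cpm <- sweep(matrix[keep, , drop = FALSE], 2L, tot, "/") * 1e6
  x <- t(log2(cpm + 1))
  labels <- factor(sheet$group[match(rownames(x), sheet$sample_id)])
  if (anyNA(labels)) stop("sample missing from sample sheet", call. = FALSE)
  feature_table(x, labels)
}

#' Construct a feature table
#' @param x samples x features numeric matrix (rownames = samples).
#' @param labels factor (or coercible) with exactly 2 levels, >= 2 samples
#'   per class.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes",
                                  call. = FALSE)
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class",
                                    call. = FALSE)
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, labels = labels), class = "feature_table")
}

#' Balanced-bootstrap random forest
#'
#' Each tree's bootstrap draws m samples with replacement from each class,
#' where m is the minority class size. The OOB error is the fraction of
#' samples misvoted by the trees whose bootstrap excluded them.
#'
#' @param table a [feature_table()].
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; identical seed and input give an identical
#'   forest.
#' @param features optional feature subset (column names).
#' @return list(model (randomForest), oob_error, inbag (samples x trees draw
#'   counts), m).
#' @export
balanced_rf <- function(table, n_trees = 1000L, seed = 1L, features = NULL) {
  x <- table$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- table$labels
  m <- min(table(y))
  model <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees, replace = TRUE,
                               strata = y, sampsize = c(m, m),
                               keep.inbag = TRUE, importance = FALSE))
  oob <- mean(model$predicted != y, na.rm = TRUE)
  list(model = model, oob_error = oob, inbag = model$inbag, m = m)
}

# Rank-based (Mann-Whitney) AUC of scores for the positive class; tied
# scores contribute 1/2.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin over k folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated AUC of a balanced forest on a feature subset
#'
#' Stratified k-fold with k = min(10, minority class size). Per fold a
#' balanced forest is fitted on the training folds and held-out class-2
#' probabilities recorded; the AUC is the rank statistic on the pooled
#' out-of-fold probabilities.
#'
#' @param table a [feature_table()].
#' @param features feature subset (column names); NULL = all.
#' @param n_trees trees per fold forest.
#' @param seed integer seed governing fold assignment and fold forests.
#' @return list(auc, probabilities (per sample, out-of-fold), folds, k).
#' @export
cv_auc <- function(table, features = NULL, n_trees = 1000L, seed = 1L) {
  y <- table$labels
  k <- min(10L, min(table(y)))
  if (k < 2L) stop("minority class too small for cross-validation",
                   call. = FALSE)
  fold <- stratified_folds(y, k, derive_seed(seed, 1L))
  prob <- rep(NA_real_, length(y))
  pos_level <- levels(y)[2L]
  for (f in seq_len(k)) {
    tr <- fold != f
    # bypass the >=2-per-class entry check: with a minority class of 2,
    # 2-fold CV legitimately trains on a single minority sample
    sub <- structure(list(x = table$x[tr, , drop = FALSE],
                          labels = factor(y[tr], levels = levels(y))),
                     class = "feature_table")
    fit <- balanced_rf(sub, n_trees, derive_seed(seed, 100L + f), features)
    newx <- table$x[!tr, , drop = FALSE]
    if (!is.null(features)) newx <- newx[, features, drop = FALSE]
    prob[!tr] <- predict(fit$model, newx, type = "prob")[, pos_level]
  }
  list(auc = rank_auc(prob, y == pos_level), probabilities = prob,
       folds = fold, k = k)
}

#' Backward feature pruning with full- and best-model reporting
#'
#' Features are ranked by full-model impurity (Gini) importance; nested
#' top-ranked subsets of sizes p, ceil(p/2), ceil(p/4), ..., 1 are evaluated
#' by cross-validated AUC; the best model is the subset maximizing the AUC
#' (ties -> smallest subset).
#'
#' @param table a [feature_table()].
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed.
#' @return object of class `classifier_result` with `full`, `best` (each:
#'   selected_features, oob_error, cv_auc, probabilities), `importances`,
#'   `path` (subset size vs AUC), `seed`.
#' @export
prune_features <- function(table, n_trees = 1000L, seed = 1L) {
  p <- ncol(table$x)
  if (p < 2L) stop("need >= 2 features to prune", call. = FALSE)
  full_fit <- balanced_rf(table, n_trees, derive_seed(seed, 2L))
  imp <- full_fit$model$importance[, "MeanDecreaseGini"]
  ranked <- colnames(table$x)[order(-imp, colnames(table$x))]

  sizes <- p
  while (sizes[length(sizes)] > 1L) {
    sizes <- c(sizes, as.integer(ceiling(sizes[length(sizes)] / 2)))
  }
  sizes <- unique(sizes)
  evals <- lapply(seq_along(sizes), function(i) {
    feats <- ranked[seq_len(sizes[i])]
    cv <- cv_auc(table, feats, n_trees, derive_seed(seed, 200L + i))
    list(size = sizes[i], features = feats, auc = cv$auc,
         probabilities = cv$probabilities)
  })
  aucs <- vapply(evals, `[[`, 0, "auc")
  # maximize AUC; ties -> smallest subset (sizes are descending)
  best_i <- which(aucs == max(aucs))
  best_i <- best_i[length(best_i)]
  best <- evals[[best_i]]
  best_fit <- balanced_rf(table, n_trees, derive_seed(seed, 3L),
                          best$features)
  full_eval <- evals[[1L]]
  structure(list(
    full = list(selected_features = ranked, oob_error = full_fit$oob_error,
                cv_auc = full_eval$auc,
                probabilities = full_eval$probabilities),
    best = list(selected_features = best$features,
                oob_error = best_fit$oob_error, cv_auc = best$auc,
                probabilities = best$probabilities),
    importances = setNames(as.numeric(imp), names(imp)),
    path = data.frame(size = sizes, cv_auc = aucs), seed = seed),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat("Balanced random-forest classifier with feature pruning\n")
  cat(sprintf("  full model: %d features, OOB error %.3f, CV AUC %.3f\n",
              length(x$full$selected_features), x$full$oob_error,
              x$full$cv_auc))
  cat(sprintf("  best model: %d features, OOB error %.3f, CV AUC %.3f\n",
              length(x$best$selected_features), x$best$oob_error,
              x$best$cv_auc))
  cat("  top features:",
      paste(head(x$best$selected_features, 5L), collapse = ", "), "\n")
  invisible(x)
}
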