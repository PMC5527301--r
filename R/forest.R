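## R-side random-forest interface (classifier backend lives in src/forest.cpp).

#' Random-forest classification (train on one set, predict another)
#'
#' Bagged CART trees with Gini splitting and per-node feature subsampling;
#' majority vote, ties resolved to the first class level. Deterministic under
#' `set.seed()`.
#'
#' @param x_train,x_test numeric feature matrices with identical columns.
#' @param y_train factor (or coercible) class labels for the training rows.
#' @param n_trees number of trees.
#' @param mtry features tried per split; default `floor(sqrt(ncol))`.
#' @param min_node minimum node size to attempt a split.
#' @return factor of predicted labels for `x_test` rows.
#' @export
rf_classify <- function(x_train, y_train, x_test, n_trees = 1000,
                        mtry = NULL, min_node = 1) {
  y_train <- factor(y_train)
  if (nlevels(y_train) < 2) stop("need at least 2 classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x_train))))
  pred <- .rf_train_predict(as.matrix(x_train),
                            as.integer(y_train) - 1L,
                            as.matrix(x_test),
                            nlevels(y_train),
                            as.integer(n_trees), as.integer(mtry),
                            as.integer(min_node))
  factor(levels(y_train)[pred + 1L], levels = levels(y_train))
}

# resolve the usable fold count, warning when stratification degrades
resolve_folds <- function(labels, n_folds) {
  min_class <- min(table(as.character(labels)))
  if (min_class == 1L)
    warning("a class has a single sample; stratification falls back to ",
            "merged folds for that class")
  if (n_folds > max(2L, min_class)) {
    n_folds_new <- max(2L, min(n_folds, min_class))
    warning(sprintf("n_folds reduced from %d to %d (smallest class has %d samples)",
                    n_folds, n_folds_new, min_class))
    return(n_folds_new)
  }
  n_folds
}

#' Cross-validated classifier error for couple labels
#'
#' Stratified k-fold cross-validated misclassification rate of the
#' random-forest classifier predicting couple labels from rarefied OTU
#' counts. Full-scale defaults mirror the canonical analysis (1,000 trees,
#' 10-fold CV); tests run declared scaled-down configurations.
#'
#' @param x an `otu_table` (features = rarefied counts), or numeric matrix.
#' @param labels class label per sample (couples, sex, ...).
#' @param n_trees trees per forest.
#' @param n_folds cross-validation folds (reduced with a warning when a class
#'   is smaller than `n_folds`).
#' @param n_repeats CV repetitions; the error is averaged over repeats (finer
#'   granularity for permutation nulls).
#' @param mtry features tried per split (default `sqrt(p)`).
#' @param seed integer seed.
#' @return list with `error`, `accuracy`, `per_fold_sd` (sd of per-fold error
#'   rates), `fold_errors`, `n_folds`, `n_repeats`.
#' @export
couple_classifier_error <- function(x, labels, n_trees = 1000, n_folds = 10,
                                    n_repeats = 1, mtry = NULL, seed = NULL) {
  feat <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  n_folds <- resolve_folds(labels, n_folds)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(feat))))
  res <- with_seed(seed, {
    .rf_cv_error(as.matrix(feat), as.integer(labels) - 1L, nlevels(labels),
                 as.integer(n_folds), as.integer(n_repeats),
                 as.integer(n_trees), as.integer(mtry), 1L)
  })
  fold_err <- res$fold_errors
  list(error = res$error, accuracy = 1 - res$error,
       per_fold_sd = if (length(fold_err) > 1) sd(fold_err) else NA_real_,
       fold_errors = fold_err,
       n_folds = n_folds, n_repeats = n_repeats)
}

#' Classifier accuracy for an arbitrary metadata label
#'
#' Applies the couple-classifier contract to any categorical metadata column
#' (sex, couple, body location, ...), overall and optionally per body
#' location.
#'
#' @param x an `otu_table`.
#' @param meta a `sample_frame` covering the table samples.
#' @param label metadata column to predict.
#' @param per_location also compute accuracy within each body location.
#' @param n_trees,n_folds,n_repeats,mtry,seed see [couple_classifier_error()].
#' @return data.frame with one row per stratum (`(overall)` first):
#'   location, accuracy, error, per_fold_sd, n.
#' @export
classify_metadata_label <- function(x, meta, label, per_location = FALSE,
                                    n_trees = 1000, n_folds = 10,
                                    n_repeats = 1, mtry = NULL, seed = NULL) {
  if (!label %in% names(meta)) stop("unknown label: ", label)
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  if (length(unique(meta[[label]])) < 2)
    stop("label '", label, "' has a single class")
  with_seed(seed, {
    strata <- list(`(overall)` = seq_len(nrow(meta)))
    if (per_location)
      strata <- c(strata, split(seq_len(nrow(meta)), meta$body_location))
    rows <- lapply(names(strata), function(loc) {
      idx <- strata[[loc]]
      lab <- meta[[label]][idx]
      if (length(unique(lab)) < 2) return(NULL)
      res <- couple_classifier_error(
        subset_samples(x, samples = idx), lab,
        n_trees = n_trees, n_folds = n_folds, n_repeats = n_repeats,
        mtry = mtry)
      data.frame(label = label, location = loc, accuracy = res$accuracy,
                 error = res$error, per_fold_sd = res$per_fold_sd,
                 n = length(idx), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
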