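# k-fold cross-validation: splitting and the pooled-prediction harness.

#' Random k-fold assignment
#'
#' Randomly partitions `length(labels)` samples into `n_folds` folds with
#' sizes differing by at most one. With `stratify = TRUE` (classification)
#' each class is dealt cyclically across folds after shuffling, so per-class
#' fold counts also differ by at most one; classes smaller than `n_folds`
#' raise an error.
#'
#' @param labels Class labels (used for stratification and length).
#' @param n_folds Number of folds; default 5.
#' @param stratify Stratify by label?
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return An object of class `uelfa_cvsplit`: `fold_of` (integer vector),
#'   `n_folds`, `seed`.
#' @export
kfold_split <- function(labels, n_folds = 5, stratify = TRUE, seed = NULL) {
  n <- length(labels)
  assert_that(n >= n_folds, "need at least as many samples as folds")
  fold_of <- integer(n)
  with_seed(seed, {
    if (stratify) {
      sizes <- integer(n_folds)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < n_folds) {
          stop("class '", cl, "' has fewer members (", length(idx),
               ") than folds (", n_folds, "); cannot stratify", call. = FALSE)
        }
        idx <- idx[sample.int(length(idx))]
        start <- which.min(sizes)
        f <- ((start - 1L + seq_along(idx) - 1L) %% n_folds) + 1L
        fold_of[idx] <- f
        sizes <- sizes + tabulate(f, n_folds)
      }
    } else {
      perm <- sample.int(n)
      fold_of[perm] <- rep_len(seq_len(n_folds), n)
    }
  })
  structure(list(fold_of = fold_of, n_folds = as.integer(n_folds),
                 stratified = stratify, seed = seed),
            class = "uelfa_cvsplit")
}

#' Cross-validated KNN / GPR evaluation
#'
#' Runs k-fold cross-validation of either model on a dataset in the standard
#' schema (see [generate_dataset()]): each sample is predicted exactly once
#' by a model not trained on it, and the pooled out-of-fold predictions are
#' summarised. Classification (`"knn"`) uses stratified folds on
#' `class_label`; regression (`"gpr"`) uses plain random folds and predicts
#' `true_conc_ng_ml`.
#'
#' @param data Dataset `data.frame` with columns `R`, `G`, `B`,
#'   `class_label` and `true_conc_ng_ml`.
#' @param model_kind `"knn"` or `"gpr"`.
#' @param k Neighbour count for KNN.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed driving the split and (for GPR) the per-fold
#'   optimiser restarts.
#' @param optimize,restarts Passed to [gpr_fit()].
#' @return A list (`uelfa_cv`): `predictions` (data.frame with `index`,
#'   `fold`, `truth`, `predicted`), `metrics` (confusion matrix + accuracies
#'   for KNN; `r_squared`, `rmse` and [bland_altman()] for GPR), `model_kind`,
#'   `n_folds`, `seed`.
#' @export
cross_validate <- function(data, model_kind = c("knn", "gpr"), k = 5,
                           n_folds = 5, seed = NULL, optimize = TRUE,
                           restarts = 3) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(data[, c("R", "G", "B")])
  n <- nrow(X)
  if (model_kind == "knn") {
    truth <- as.character(data$class_label)
    split <- kfold_split(truth, n_folds, stratify = TRUE, seed = seed)
  } else {
    truth <- as.numeric(data$true_conc_ng_ml)
    split <- kfold_split(truth, n_folds, stratify = FALSE, seed = seed)
  }

  predicted <- if (model_kind == "knn") character(n) else numeric(n)
  for (f in seq_len(split$n_folds)) {
    test <- split$fold_of == f
    if (model_kind == "knn") {
      m <- knn_model(X[!test, , drop = FALSE], truth[!test], k = k)
      predicted[test] <- knn_predict(m, X[test, , drop = FALSE])
    } else {
      fold_seed <- if (is.null(seed)) NULL else as.integer(seed) + f
      m <- gpr_fit(X[!test, , drop = FALSE], truth[!test],
                   optimize = optimize, restarts = restarts, seed = fold_seed)
      predicted[test] <- gpr_predict(m, X[test, , drop = FALSE])$mean
    }
  }

  metrics <- if (model_kind == "knn") {
    cm <- confusion_and_accuracy(truth, predicted)
    list(confusion = cm, overall_accuracy = cm$overall_accuracy,
         macro_recall = cm$macro_recall)
  } else {
    list(r_squared = r_squared(predicted, truth),
         rmse = sqrt(mean((predicted - truth)^2)),
         bland_altman = bland_altman(predicted, truth))
  }
  structure(
    list(predictions = data.frame(index = seq_len(n), fold = split$fold_of,
                                  truth = truth, predicted = predicted),
         metrics = metrics, model_kind = model_kind,
         n_folds = split$n_folds, k = if (model_kind == "knn") k else NULL,
         seed = seed),
    class = "uelfa_cv"
  )
}

#' @export
print.uelfa_cv <- function(x, ...) {
  cat("Cross-validated", toupper(x$model_kind), "(", x$n_folds, "folds )\n")
  if (x$model_kind == "knn") {
    cat(sprintf("  overall accuracy: %.2f%%\n",
                100 * x$metrics$overall_accuracy))
  } else {
    cat(sprintf("  pooled R^2: %.6f   RMSE: %.4g ng/mL\n",
                x$metrics$r_squared, x$metrics$rmse))
  }
  invisible(x)
}
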