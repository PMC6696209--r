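#' Gini impurity of a class-probability vector
#'
#' `1 - sum(p^2)`: the node heterogeneity used by classification trees
#' for split selection; summed decreases of this quantity over an
#' ensemble of trees give impurity-based feature importance.
#'
#' @param p nonnegative probability vector summing to 1.
#' @return Gini impurity in `[0, 1 - 1/length(p)]`.
#' @export
#' @examples
#' gini_impurity(c(0.5, 0.5))  # 0.5
gini_impurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid probability vector: entries must be nonnegative and sum to 1")
  1 - sum(p^2)
}

.forest_frame <- function(table, ids) {
  df <- as.data.frame(table$values[, ids, drop = FALSE])
  names(df) <- make.names(ids)   # ranger needs syntactic names
  df$.group <- table$group
  df
}

#' Fit a random forest classifying PD versus controls
#'
#' Trains an ensemble of classification trees on bootstrap samples with
#' random feature subsetting (via \pkg{ranger}) and returns the
#' mean-decrease-in-Gini-impurity importance of each measure,
#' normalized to sum to 1, together with the out-of-bag error.
#'
#' @param table a complete `measure_table` with both classes present.
#' @param ids measures to use as predictors (default: all).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; identical seeds give identical forests.
#' @param mtry feature-subset size per split (default
#'   `floor(sqrt(#ids))`).
#' @return List with `importances` (named, sums to 1), `oob_error`
#'   (fraction), `n_trees`, and the fitted `ranger` object as `fit`.
#' @export
fit_forest <- function(table, ids = measure_ids(table), n_trees = 500,
                       seed = 1L, mtry = NULL) {
  stopifnot(inherits(table, "measure_table"))
  if (anyNA(table$values[, ids])) stop("forest needs complete data")
  if (nlevels(droplevels(table$group)) < 2)
    stop("single-class input: both PD and HC subjects are required")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(ids))))
  df <- .forest_frame(table, ids)
  fit <- ranger::ranger(dependent.variable.name = ".group", data = df,
                        num.trees = n_trees, mtry = mtry,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  names(imp) <- ids[match(names(imp), make.names(ids))]
  list(importances = imp, oob_error = fit$prediction.error,
       n_trees = n_trees, fit = fit)
}

#' Random-forest k-fold cross-validation report
#'
#' Randomized k-fold cross-validation (default 10-fold: 90% of subjects
#' train, 10% validate) of the PD-versus-control random forest.
#' Accuracy and precision (positive class PD) are computed on each
#' held-out fold and reported as mean and SD across folds, in percent.
#' Folds are drawn at random without stratification; a fold in which no
#' subject is predicted PD has undefined precision and is excluded from
#' the precision summary with a warning.
#'
#' @inheritParams fit_forest
#' @param folds number of folds (default 10).
#' @param repeats number of independent fold assignments averaged over
#'   (default 1); fold metrics of all repeats are pooled.
#' @return List of class `forest_report`: `accuracy_mean`,
#'   `accuracy_sd`, `precision_mean`, `precision_sd` (percent),
#'   `fold_accuracy`, `fold_precision` (per fold, percent),
#'   `importances` and `oob_error` from a fit on all subjects, `folds`,
#'   `seed`.
#' @export
cross_validate_forest <- function(table, ids = measure_ids(table),
                                  folds = 10, seed = 1L, n_trees = 500,
                                  mtry = NULL, repeats = 1) {
  stopifnot(folds >= 2)
  n <- nrow(table$values)
  stopifnot(folds <= n)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(ids))))
  df <- .forest_frame(table, ids)
  set.seed(seed)
  acc <- prec <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_of <- sample(rep_len(seq_len(folds), n))
    for (k in seq_len(folds)) {
      test_idx <- which(fold_of == k)
      train <- df[-test_idx, , drop = FALSE]
      if (nlevels(droplevels(train$.group)) < 2)
        stop("training split of fold ", k, " contains a single class")
      fit <- ranger::ranger(dependent.variable.name = ".group",
                            data = train, num.trees = n_trees,
                            mtry = mtry, seed = seed + 1000L * r + k,
                            num.threads = 1)
      pred <- stats::predict(fit, df[test_idx, , drop = FALSE])$predictions
      truth <- df$.group[test_idx]
      acc <- c(acc, 100 * mean(pred == truth))
      if (any(pred == "PD")) {
        prec <- c(prec, 100 * mean(truth[pred == "PD"] == "PD"))
      } else {
        warning("fold ", k, ": no subject predicted PD; precision ",
                "undefined and excluded")
        prec <- c(prec, NA_real_)
      }
    }
  }
  full <- fit_forest(table, ids, n_trees = n_trees, seed = seed, mtry = mtry)
  structure(list(accuracy_mean = mean(acc),
                 accuracy_sd = stats::sd(acc),
                 precision_mean = mean(prec, na.rm = TRUE),
                 precision_sd = stats::sd(prec[!is.na(prec)]),
                 fold_accuracy = acc, fold_precision = prec,
                 importances = full$importances,
                 oob_error = full$oob_error,
                 folds = folds, seed = seed),
            class = "forest_report")
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("<forest_report> %d-fold CV: accuracy %.1f +/- %.1f %%, precision %.1f +/- %.1f %% (OOB error %.3f)\n",
              x$folds, x$accuracy_mean, x$accuracy_sd,
              x$precision_mean, x$precision_sd, x$oob_error))
  invisible(x)
}
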