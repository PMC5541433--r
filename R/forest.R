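#' Regression random forest
#'
#' A self-contained CART regression forest: bootstrap resampling, random
#' feature subsets of size `mtry` at each node, variance-reduction splits,
#' out-of-bag (OOB) predictions and OOB permutation importance. It follows
#' the conventions of classical regression forests (`ntree` trees, default
#' `mtry = floor(p/3)`, terminal nodes of at most `min_node` samples are not
#' split further).
#'
#' The fit is fully determined by R's RNG state: call `set.seed()` (or pass
#' `seed`) for reproducibility.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y numeric response, one value per row of `x`.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `max(floor(p/3), 1)`.
#' @param min_node minimal node size below which splitting stops (default 5).
#' @param importance compute OOB permutation importance (default `FALSE`).
#'   The importance of a feature is the mean increase in a tree's OOB mean
#'   squared error when that feature's OOB values are permuted.
#' @param seed optional integer seed applied before fitting.
#' @return An object of class `regression_forest` with elements `trees`
#'   (opaque), `oob_pred`, `oob_count`, `importance` (or `NULL`), `mtry`,
#'   `ntree`, `feature_names`, `y_range`, and `oob_r2` (1 - OOB MSE /
#'   Var(y)).
#' @examples
#' x <- matrix(runif(200), 50, 4)
#' y <- 2 * x[, 1] + rnorm(50, sd = 0.1)
#' fit <- regression_forest(x, y, ntree = 100, importance = TRUE, seed = 1)
#' fit$oob_r2
#' @export
regression_forest <- function(x, y, ntree = 500, mtry = NULL, min_node = 5,
                              importance = FALSE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 2) stop("need at least 2 samples to fit a forest")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (ntree < 1) stop("ntree must be >= 1")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(floor(p / 3), 1)
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ncol(x)]")
  if (!is.null(seed)) set.seed(seed)

  fit <- rf_fit_cpp(x, y, as.integer(ntree), as.integer(mtry),
                    as.integer(min_node), isTRUE(importance))
  oob <- fit$oob_pred
  vy <- var(y)
  oob_r2 <- if (is.finite(vy) && vy > 0) {
    ok <- !is.na(oob)
    1 - mean((oob[ok] - y[ok])^2) / vy
  } else NA_real_
  imp <- fit$importance
  if (!is.null(imp)) names(imp) <- colnames(x)
  structure(
    list(trees = fit$trees, oob_pred = oob, oob_count = fit$oob_count,
         importance = imp, mtry = mtry, ntree = ntree,
         feature_names = colnames(x), y_range = range(y), oob_r2 = oob_r2),
    class = "regression_forest")
}

#' Predict from a regression forest
#'
#' @param object a [regression_forest()] fit.
#' @param newdata numeric matrix with the same columns (by name if the
#'   training matrix was named) as the training data.
#' @param ... unused.
#' @return numeric vector of predictions, one per row of `newdata`.
#' @export
predict.regression_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(newdata)))
      stop("newdata must have column names matching the training features")
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing))
      stop("newdata lacks features: ", paste(missing, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  rf_predict_cpp(object$trees, newdata)
}

#' @export
print.regression_forest <- function(x, ...) {
  cat("Regression random forest\n")
  cat(sprintf("  trees: %d, mtry: %d, features: %d\n",
              x$ntree, x$mtry, length(x$feature_names)))
  cat(sprintf("  OOB R-squared: %.4f\n", x$oob_r2))
  invisible(x)
}
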