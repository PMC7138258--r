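#' Random-forest regressor
#'
#' Bagged ensemble of CART regression trees with variance-reduction splits;
#' the ensemble estimate is the unweighted mean of the tree predictions, so
#' predictions always lie inside the convex hull of the training labels.
#' Defaults mirror the classic scikit-learn regressor: 100 trees, bootstrap
#' resampling, all features considered at every split, nodes grown to purity
#' (`min_split = 2`, `min_leaf = 1`, no depth cap). Deterministic under a
#' fixed seed.
#'
#' @param x numeric feature matrix (rows = samples)
#' @param y numeric labels
#' @param n_trees ensemble size
#' @param mtry features considered per split (default: all)
#' @param min_split minimum node size to attempt a split
#' @param min_leaf minimum samples per child
#' @param max_depth depth cap (0 = unlimited)
#' @param bootstrap draw a bootstrap sample per tree
#' @param seed integer seed
#' @return object of class `cepaq_rf`
#' @export
rf_fit <- function(x, y, n_trees = 100L, mtry = ncol(x), min_split = 2L,
                   min_leaf = 1L, max_depth = 0L, bootstrap = TRUE,
                   seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(y) != nrow(x)) stop("feature/label length mismatch")
  trees <- rf_train_cpp(x, as.double(y), as.integer(n_trees),
                        as.integer(mtry), as.integer(min_split),
                        as.integer(min_leaf), as.integer(max_depth),
                        isTRUE(bootstrap), as.integer(seed))
  structure(list(trees = trees, p = ncol(x),
                 label_range = range(y),
                 params = list(n_trees = n_trees, mtry = mtry,
                               min_split = min_split, min_leaf = min_leaf,
                               max_depth = max_depth, bootstrap = bootstrap,
                               seed = seed)),
            class = "cepaq_rf")
}

#' @param object a `cepaq_rf`
#' @param newdata numeric feature matrix
#' @param ... unused
#' @rdname rf_fit
#' @export
predict.cepaq_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    stop("expected ", object$p, " features, got ", ncol(newdata))
  rf_predict_cpp(object$trees, newdata)
}

#' @export
print.cepaq_rf <- function(x, ...) {
  cat("cepaq random forest:", x$params$n_trees, "trees,", x$p, "features\n")
  invisible(x)
}
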