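#' Gradient-boosted regression trees with Huber loss
#'
#' A deterministic GBRT regressor: an additive ensemble of depth-limited
#' regression trees fitted sequentially to Huber pseudo-residuals, with
#' per-leaf Huber (M-regression) updates and shrinkage by the learning
#' rate.  There is no row or feature subsampling, so a fit is fully
#' reproducible from the data alone.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y numeric response.
#' @param n_trees number of boosting iterations.
#' @param learning_rate shrinkage applied to every tree's contribution.
#' @param max_depth maximum depth of each tree.
#' @param huber_alpha quantile of absolute residuals used as the Huber
#'   transition point each iteration (0.9, the usual default).
#' @param min_leaf minimum observations per leaf.
#' @return An object of class `gbrt`.
#' @export
gbrt_fit <- function(x, y, n_trees = 100, learning_rate = 0.1, max_depth = 3,
                     huber_alpha = 0.9, min_leaf = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop("empty training set")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("gbrt_fit does not accept missing values")
  fit <- .gbrt_fit_cpp(x, as.double(y), as.integer(n_trees),
                       as.double(learning_rate), as.integer(max_depth),
                       as.double(huber_alpha), as.integer(min_leaf))
  structure(list(fit = fit, n_trees = n_trees, learning_rate = learning_rate,
                 max_depth = max_depth, p = ncol(x)),
            class = "gbrt")
}

#' @param object,newdata,... standard predict arguments; `n_trees` truncates
#'   the ensemble to its first `n_trees` trees (staged prediction).
#' @rdname gbrt_fit
#' @export
predict.gbrt <- function(object, newdata, n_trees = object$n_trees, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p) stop("feature count mismatch")
  .gbrt_predict_cpp(object$fit, newdata, as.integer(n_trees))
}

#' Staged predictions at several ensemble sizes from a single fit
#'
#' @param object fitted `gbrt`.
#' @param newdata feature matrix.
#' @param stages integer vector of ensemble sizes.
#' @return Matrix with one column per stage (columns named by stage),
#'   rows matching `newdata`.
#' @export
gbrt_staged_predict <- function(object, newdata, stages) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  ord <- order(stages)
  out <- .gbrt_staged_predict_cpp(object$fit, newdata, as.integer(stages[ord]))
  out <- out[, order(ord), drop = FALSE]
  colnames(out) <- as.character(stages)
  out
}
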