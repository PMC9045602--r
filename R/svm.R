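#' L2-regularized linear support-vector classifier
#'
#' Linear SVM with squared-hinge loss, solved with BFGS on the smooth
#' primal objective
#' \deqn{\min_{w,b}\; \tfrac12 \|w\|^2 + C \sum_i \max(0, 1 - y_i(w'x_i+b))^2.}
#' The squared hinge keeps the objective differentiable so the fit is
#' deterministic; this is the L2-SVM variant used by liblinear.
#'
#' @param x numeric feature matrix.
#' @param y labels in \{0, 1\} (or a two-level factor).
#' @param cost regularization constant C.
#' @return Object of class `linear_svc` with elements `w`, `b`, `levels`.
#' @export
linear_svc <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("linear_svc needs exactly two classes")
  ypm <- ifelse(y == lev[2L], 1, -1)
  n <- nrow(x); p <- ncol(x)

  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- 1 - ypm * (drop(x %*% w) + b)
    0.5 * sum(w^2) + cost * sum(pmax(m, 0)^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- 1 - ypm * (drop(x %*% w) + b)
    act <- m > 0
    gw <- w - 2 * cost * drop(crossprod(x[act, , drop = FALSE],
                                        ypm[act] * m[act]))
    gb <- -2 * cost * sum(ypm[act] * m[act])
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1L], levels = lev),
            class = "linear_svc")
}

#' @param object,newdata,... standard predict arguments.
#' @rdname linear_svc
#' @export
predict.linear_svc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$w) + object$b
  ifelse(score > 0, object$levels[2L], object$levels[1L])
}
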