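#' Proxy-A distance between a training set and a held-out subject
#'
#' A linear support-vector classifier is trained to distinguish training
#' rows (label 0) from held-out rows (label 1); its generalization error
#' epsilon is estimated by stratified k-fold cross-validation and the
#' Proxy-A distance is PAD = 2(1 - 2 epsilon).  With 0/1 labels the
#' misclassification rate equals the classifier's MAE.  Small PAD means
#' the classifier cannot tell the sets apart - the distributions are
#' similar; values near 2 mean linear separability.  Negative estimates
#' are possible and preserved.
#'
#' The majority side is subsampled (seeded) to the minority size before
#' fitting so epsilon is not dominated by class imbalance; features are
#' standardized on the pooled task.
#'
#' @param train_x,held_x feature matrices (raw scale).
#' @param seed RNG seed for subsampling and fold assignment.
#' @param folds cross-validation folds (reduced automatically when a
#'   side is small; fewer than 2 rows per side is undefined).
#' @param cost SVM regularization constant.
#' @return list with `epsilon`, `pad`, `n_train`, `n_held`, `folds`;
#'   `NULL` (with a warning) when undefined.
#' @export
proxy_a_distance <- function(train_x, held_x, seed = 1, folds = 5, cost = 1) {
  train_x <- as.matrix(train_x); held_x <- as.matrix(held_x)
  n0 <- nrow(train_x); n1 <- nrow(held_x)
  if (n0 < 2 || n1 < 2) {
    warning("fewer than 2 instances on one side; PAD undefined")
    return(NULL)
  }
  set.seed(seed)
  n_min <- min(n0, n1)
  i0 <- if (n0 > n_min) sort(sample.int(n0, n_min)) else seq_len(n0)
  i1 <- if (n1 > n_min) sort(sample.int(n1, n_min)) else seq_len(n1)
  x <- rbind(train_x[i0, , drop = FALSE], held_x[i1, , drop = FALSE])
  yl <- c(rep(0L, length(i0)), rep(1L, length(i1)))
  std <- fit_standardizer(x)
  x <- apply_standardizer(std, x)

  kf <- max(2L, min(folds, n_min))
  # stratified fold assignment: shuffle within class, deal round-robin
  fold <- integer(length(yl))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(yl == cl))
    fold[idx] <- rep_len(seq_len(kf), length(idx))
  }
  errs <- vapply(seq_len(kf), function(f) {
    tr <- fold != f
    if (length(unique(yl[tr])) < 2L) return(NA_real_)
    m <- linear_svc(x[tr, , drop = FALSE], yl[tr], cost = cost)
    mean(predict(m, x[!tr, , drop = FALSE]) != yl[!tr])
  }, numeric(1))
  eps <- mean(errs, na.rm = TRUE)
  list(epsilon = eps, pad = 2 * (1 - 2 * eps),
       n_train = length(i0), n_held = length(i1), folds = kf)
}

#' PAD table over the LOSO experiment structure
#'
#' One Proxy-A distance per (validation subject, training mode,
#' personalization k): the candidate training set is assembled and
#' personalized exactly as in [run_loso_grid()] and compared with the
#' subject's own instances.
#'
#' @param instances aligned instance table.
#' @param item outcome item.
#' @param ks personalization neighbor counts (`Inf` = all).
#' @param modes training modes.
#' @param seed RNG seed.
#' @param min_ema validation inclusion threshold.
#' @return data.table with one row per (subject, mode, k): `epsilon`,
#'   `pad`, instance counts.
#' @export
pad_table <- function(instances, item, ks = c(5, 10, 50, 100, 500, Inf),
                      modes = c("single", "combined"), seed = 1,
                      min_ema = 30) {
  dt <- as.data.table(instances)
  dt <- dt[dt$item == item]
  subjects <- select_validation_subjects(dt, min_ema = min_ema)
  fn <- feature_names(TRUE)
  recs <- list()
  for (s in subjects) {
    held <- as.matrix(dt[subject == s, ..fn])
    for (mode in modes) {
      train <- build_training_set(dt, s, mode)
      tx_raw <- as.matrix(train[, ..fn])
      std <- fit_standardizer(tx_raw)
      tx <- apply_standardizer(std, tx_raw)
      hx <- apply_standardizer(std, held)
      for (ki in ks) {
        keep <- personalize_indices(tx, hx, ki)
        res <- proxy_a_distance(tx_raw[keep, , drop = FALSE], held,
                                seed = derive_seed(seed, match(s, subjects),
                                                   match(mode, modes),
                                                   which(ki == ks)))
        if (is.null(res)) next
        recs[[length(recs) + 1L]] <- data.table(
          subject = s, item = item, mode = mode, k = ki,
          epsilon = res$epsilon, pad = res$pad,
          n_train = res$n_train, n_held = res$n_held)
      }
    }
  }
  rbindlist(recs)
}
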