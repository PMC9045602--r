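#' The declared hyperparameter grid
#'
#' Full grid: learning rate \{0.001, 0.01, 0.1, 1.0\} x number of trees
#' \{20, 100, 1000\} x tree depth \{3, 7, 10\} x SMOTE \{on, off\} x
#' personalization neighbors k \{5, 10, 50, 100, 500, all\} - 432
#' configurations.  `Inf` encodes k = "all" (no personalization).
#'
#' @param learning_rate,n_trees,depth,smote,k optionally reduced value
#'   sets; values must come from the declared sets.
#' @return data.table with one row per configuration and a `config_id`.
#' @export
hyper_grid <- function(learning_rate = c(0.001, 0.01, 0.1, 1.0),
                       n_trees = c(20, 100, 1000),
                       depth = c(3, 7, 10),
                       smote = c(TRUE, FALSE),
                       k = c(5, 10, 50, 100, 500, Inf)) {
  declared <- list(learning_rate = c(0.001, 0.01, 0.1, 1.0),
                   n_trees = c(20, 100, 1000), depth = c(3, 7, 10),
                   smote = c(TRUE, FALSE), k = c(5, 10, 50, 100, 500, Inf))
  args <- list(learning_rate = learning_rate, n_trees = n_trees,
               depth = depth, smote = smote, k = k)
  for (nm in names(args)) {
    if (!all(args[[nm]] %in% declared[[nm]])) {
      stop("values of ", nm, " outside the declared grid")
    }
  }
  g <- CJ(learning_rate = learning_rate, n_trees = n_trees, depth = depth,
          smote = smote, k = k)
  g[, config_id := sprintf("lr%g_t%g_d%g_s%d_k%s", learning_rate, n_trees,
                           depth, as.integer(smote),
                           ifelse(is.finite(k), as.character(k), "all"))]
  g[]
}

#' Assemble the training set for one held-out subject
#'
#' `"single"` keeps instances from the held-out subject's own study;
#' `"combined"` keeps instances from both studies; either way all of the
#' held-out subject's instances are excluded.  `"baseline"` marks the
#' compared mode's data for constant mean prediction.
#'
#' @param instances aligned instance table (one outcome item).
#' @param held_out subject id, present in `instances`.
#' @param mode `"single"`, `"combined"` or `"baseline"`.
#' @return data.table of training instances.
#' @export
build_training_set <- function(instances, held_out,
                               mode = c("single", "combined", "baseline")) {
  mode <- match.arg(mode)
  dt <- as.data.table(instances)
  if (!held_out %in% dt$subject) stop("held-out subject not in instances")
  own_study <- dt[subject == held_out]$study[1L]
  out <- dt[subject != held_out]
  if (mode == "single") out <- out[study == own_study]
  out
}

#' Per-feature standardization fit on a training set
#'
#' @param x training feature matrix.
#' @return list with `center`, `scale` (zero-variance features get
#'   scale 1).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

#' @param std a standardizer from [fit_standardizer()].
#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(std, x) {
  sweep(sweep(as.matrix(x), 2, std$center), 2, std$scale, "/")
}

#' Restrict a training set to the held-out subject's nearest neighbors
#'
#' For each held-out instance the k nearest training instances under
#' Euclidean distance in standardized feature space are collected; the
#' personalized training set is their union (duplicates kept once).
#' `k = Inf` (all) returns the input unchanged; `k` larger than the
#' training size returns the full set with a note.
#'
#' @param train_x standardized training feature matrix.
#' @param held_x standardized held-out feature matrix.
#' @param k neighbors per held-out instance.
#' @return Sorted integer vector of retained training row indices.
#' @export
personalize_indices <- function(train_x, held_x, k) {
  n <- nrow(train_x)
  if (!is.finite(k) || k >= n) {
    if (is.finite(k) && k > n) message("k exceeds training size; keeping all")
    return(seq_len(n))
  }
  nn <- FNN::get.knnx(train_x, held_x, k = k)
  sort(unique(as.vector(nn$nn.index)))
}

#' SMOTE oversampling on the rounded outcome grid
#'
#' Classes are the outcome categories after rounding normalized values
#' to \{0, 1, 2, 3\} (the common grid across studies).  Every minority
#' class is oversampled to the majority count by interpolating between a
#' minority point and one of its k nearest same-class neighbors in the
#' (already standardized) feature space; synthetic outcomes inherit the
#' class value.  A class smaller than k + 1 uses k = class size - 1; a
#' singleton class is duplicated with a warning.
#'
#' @param x standardized feature matrix.
#' @param y numeric outcomes (snapped internally to the integer grid for
#'   class definition).
#' @param k neighbors (default 5).
#' @param seed RNG seed.
#' @return list with augmented `x`, `y`, and `synthetic` (logical flag
#'   per row).
#' @export
smote_oversample <- function(x, y, k = 5, seed = 1) {
  x <- as.matrix(x)
  cls <- round(pmin(pmax(y, 0), 3))
  counts <- table(cls)
  n_max <- max(counts)
  set.seed(seed)
  add_x <- list(); add_y <- numeric(0)
  for (cv in names(counts)) {
    n_c <- counts[[cv]]
    need <- n_max - n_c
    if (need == 0L) next
    idx <- which(cls == as.numeric(cv))
    xc <- x[idx, , drop = FALSE]
    if (n_c == 1L) {
      warning("singleton class ", cv, " duplicated")
      add_x[[length(add_x) + 1L]] <-
        xc[rep(1L, need), , drop = FALSE]
      add_y <- c(add_y, rep(as.numeric(cv), need))
      next
    }
    k_eff <- min(k, n_c - 1L)
    nn <- FNN::get.knn(xc, k = k_eff)$nn.index
    base <- rep(seq_len(n_c), length.out = need)
    pick <- nn[cbind(base, sample.int(k_eff, need, replace = TRUE))]
    lam <- runif(need)
    newx <- xc[base, , drop = FALSE] +
      lam * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    add_x[[length(add_x) + 1L]] <- newx
    add_y <- c(add_y, rep(as.numeric(cv), need))
  }
  if (length(add_x)) {
    xa <- do.call(rbind, add_x)
    list(x = rbind(x, xa), y = c(y, add_y),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(xa))))
  } else {
    list(x = x, y = y, synthetic = rep(FALSE, nrow(x)))
  }
}

#' Fit the regressor for one configuration
#'
#' `"baseline"` returns the constant mean of the training outcomes; the
#' other modes fit the Huber-loss GBRT honoring the configuration.
#'
#' @param x,y training data (standardized features).
#' @param hp one-row configuration (from [hyper_grid()]).
#' @param mode `"gbrt"` or `"baseline"`.
#' @return Object with a `predict` method.
#' @export
fit_model <- function(x, y, hp, mode = c("gbrt", "baseline")) {
  mode <- match.arg(mode)
  if (length(y) == 0L) stop("empty training set")
  if (mode == "baseline") {
    structure(list(mean = mean(y)), class = "baseline_model")
  } else {
    gbrt_fit(x, y, n_trees = hp$n_trees, learning_rate = hp$learning_rate,
             max_depth = hp$depth)
  }
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  rep(object$mean, nrow(as.matrix(newdata)))
}

clip03 <- function(v) pmin(pmax(v, 0), 3)

#' Run the leave-one-subject-out experiment grid
#'
#' For every validation subject (>= `min_ema` aligned responses), every
#' training mode and every grid configuration, fits the pipeline
#' build -> personalize -> standardize -> SMOTE -> GBRT and predicts all
#' of the subject's instances.  Per fold, standardization,
#' personalization and SMOTE are computed from the training data only.
#' A constant-mean baseline prediction on the same training data is
#' recorded alongside each configuration.  Ensembles are fitted once at
#' the largest tree count per (learning rate, depth) and truncated for
#' the smaller counts, which is exact for deterministic boosting.
#'
#' @param instances aligned instance table.
#' @param item outcome item to model.
#' @param grid configurations from [hyper_grid()].
#' @param modes training modes to run.
#' @param seed master seed (drives SMOTE substreams).
#' @param min_ema validation inclusion threshold.
#' @return data.table of prediction records: identifiers, configuration,
#'   `y`, `yhat` (clipped to \[0, 3\]) and `yhat_base`.
#' @export
run_loso_grid <- function(instances, item, grid = hyper_grid(),
                          modes = c("single", "combined"), seed = 1,
                          min_ema = 30) {
  dt <- as.data.table(instances)
  dt <- dt[dt$item == item]
  subjects <- select_validation_subjects(dt, min_ema = min_ema)
  if (!length(subjects)) {
    warning("no validation subjects meet the >=", min_ema, " EMA rule")
    return(data.table())
  }
  fn <- feature_names(TRUE)
  recs <- list()
  for (s in subjects) {
    held <- dt[subject == s]
    hx_raw <- as.matrix(held[, ..fn])
    for (mode in modes) {
      train <- build_training_set(dt, s, mode)
      tx_raw <- as.matrix(train[, ..fn])
      for (ki in sort(unique(grid$k))) {
        std <- fit_standardizer(tx_raw)
        tx <- apply_standardizer(std, tx_raw)
        hx <- apply_standardizer(std, hx_raw)
        keep <- personalize_indices(tx, hx, ki)
        for (sm in unique(grid$smote)) {
          if (sm) {
            aug <- smote_oversample(tx[keep, , drop = FALSE],
                                    train$outcome[keep], k = 5,
                                    seed = derive_seed(seed, match(s, subjects),
                                                       match(mode, modes),
                                                       which(ki == sort(unique(grid$k)))))
            fx <- aug$x; fy <- aug$y
          } else {
            fx <- tx[keep, , drop = FALSE]; fy <- train$outcome[keep]
          }
          sub <- grid[smote == sm & k == ki]
          for (lr in unique(sub$learning_rate)) {
            for (dp in unique(sub$depth)) {
              tr_counts <- sort(unique(sub[learning_rate == lr &
                                             depth == dp]$n_trees))
              if (!length(tr_counts)) next
              fit <- gbrt_fit(fx, fy, n_trees = max(tr_counts),
                              learning_rate = lr, max_depth = dp)
              staged <- gbrt_staged_predict(fit, hx, tr_counts)
              for (j in seq_along(tr_counts)) {
                recs[[length(recs) + 1L]] <- data.table(
                  subject = s, study = held$study[1L], item = item,
                  mode = mode, k = ki, smote = sm, learning_rate = lr,
                  n_trees = tr_counts[j], depth = dp, date = held$date,
                  y = held$outcome, yhat = clip03(staged[, j]),
                  yhat_base = mean(fy))
              }
            }
          }
        }
      }
    }
  }
  rbindlist(recs)
}
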