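# Grid enumeration, training-set assembly, personalization, SMOTE,
# model fitting and the LOSO driver.

test_that("the declared grid enumerates 432 configurations", {
  g <- hyper_grid()
  expect_equal(nrow(g), 4 * 3 * 3 * 2 * 6)
  expect_equal(nrow(g), 432L)
  expect_equal(data.table::uniqueN(g$config_id), 432L)
  expect_error(hyper_grid(learning_rate = 0.5), "declared")
  expect_equal(nrow(hyper_grid(learning_rate = 0.1, n_trees = 100,
                               depth = 3, smote = FALSE, k = Inf)), 1L)
})

test_that("training-set assembly excludes the held-out subject per mode", {
  inst <- toy_instances(n_subjects = 4, n_per = 10)  # 2 studies x 2 subjects
  held <- "s01"  # study a
  combined <- build_training_set(inst, held, "combined")
  single <- build_training_set(inst, held, "single")
  expect_equal(nrow(combined), 30L)
  expect_equal(nrow(single), 10L)
  expect_true(all(single$study == "a"))
  for (mode in c("single", "combined", "baseline")) {
    expect_false(held %in% build_training_set(inst, held, mode)$subject)
  }
  expect_error(build_training_set(inst, "nobody", "single"), "held-out")
})

test_that("personalization keeps the k nearest training rows per held-out instance", {
  train <- matrix(c(0.1, 5, 9), ncol = 1)
  held <- matrix(0, ncol = 1)
  expect_equal(personalize_indices(train, held, 1), 1L)
  expect_equal(personalize_indices(train, held, Inf), 1:3)
  expect_message(out <- personalize_indices(train, held, 5), "keeping all")
  expect_equal(out, 1:3)

  # union property and brute-force membership on random data
  set.seed(21)
  tr <- matrix(rnorm(200), 50, 4)
  hd <- matrix(rnorm(24), 6, 4)
  k <- 3
  idx <- personalize_indices(tr, hd, k)
  expect_lte(length(idx), min(nrow(tr), k * nrow(hd)))
  brute <- sort(unique(unlist(lapply(seq_len(nrow(hd)), function(i) {
    d <- colSums((t(tr) - hd[i, ])^2)
    order(d)[seq_len(k)]
  }))))
  expect_equal(idx, brute)
})

test_that("SMOTE balances classes with convex same-class interpolations", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(16, 4), 8, 2))
  y <- c(rep(0, 20), rep(3, 8))
  out <- smote_oversample(x, y, k = 5, seed = 9)
  expect_equal(as.integer(table(round(out$y))), c(20L, 20L))
  expect_equal(sum(out$synthetic), 12L)

  # every synthetic point is x_i + lambda (x_j - x_i) for a same-class
  # x_i and x_j among its 5 nearest same-class neighbors (brute force)
  minority <- x[y == 3, , drop = FALSE]
  syn <- out$x[out$synthetic, , drop = FALSE]
  for (r in seq_len(nrow(syn))) {
    p <- syn[r, ]
    ok <- FALSE
    for (i in seq_len(nrow(minority))) {
      xi <- minority[i, ]
      d <- colSums((t(minority) - xi)^2)
      nbrs <- setdiff(order(d), i)[1:5]
      for (j in nbrs) {
        v <- minority[j, ] - xi
        lam <- if (sum(v^2) > 0) sum((p - xi) * v) / sum(v^2) else 0
        if (lam >= -1e-8 && lam <= 1 + 1e-8 &&
            sqrt(sum((xi + lam * v - p)^2)) < 1e-8) ok <- TRUE
      }
    }
    expect_true(ok)
  }
  expect_true(all(out$y[out$synthetic] == 3))

  # already balanced input is unchanged
  xb <- matrix(rnorm(40), 20, 2); yb <- rep(c(0, 1), each = 10)
  outb <- smote_oversample(xb, yb, seed = 2)
  expect_equal(outb$x, xb)
  # singleton class duplicates with a warning
  expect_warning(smote_oversample(rbind(xb, 9), c(yb, 3), seed = 2),
                 "singleton")
})

test_that("baseline predicts the training mean; GBRT honors degenerate fits", {
  x <- matrix(rnorm(40), 10, 4)
  hp <- hyper_grid(learning_rate = 0.1, n_trees = 20, depth = 3,
                   smote = FALSE, k = Inf)
  base <- fit_model(x, c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1), hp, "baseline")
  expect_equal(predict(base, x), rep(1.3, 10))
  base2 <- fit_model(x[1:4, ], c(0, 1, 2, 3), hp, "baseline")
  expect_equal(predict(base2, x[1:4, ]), rep(1.5, 4))

  const <- fit_model(x, rep(2, 10), hp, "gbrt")
  expect_equal(predict(const, x), rep(2, 10))
  expect_error(fit_model(x[0, ], numeric(0), hp), "empty")
})

test_that("training error is non-increasing in the number of trees", {
  set.seed(41)
  x <- matrix(rnorm(400), 100, 4)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(100, 0, 0.3)
  fit <- gbrt_fit(x, y, n_trees = 1000, learning_rate = 0.05, max_depth = 3)
  staged <- gbrt_staged_predict(fit, x, c(20, 100, 1000))
  maes <- colMeans(abs(staged - y))
  expect_true(all(diff(maes) <= 1e-10))
})

test_that("LOSO grid emits complete, leakage-free prediction records", {
  inst <- toy_instances(n_subjects = 3, n_per = 30, seed = 5)
  grid <- hyper_grid(learning_rate = 0.1, n_trees = 20, depth = 3,
                     smote = FALSE, k = Inf)
  pr <- run_loso_grid(inst, "sleep", grid = grid, seed = 2, min_ema = 30)
  # 3 subjects x 30 instances x 1 config x 2 modes
  expect_equal(nrow(pr), 180L)
  expect_true(all(pr$yhat >= 0 & pr$yhat <= 3))
  expect_true(all(c("single", "combined") %in% pr$mode))
  expect_true(all(!is.na(pr$yhat_base)))
  # no validation subject below the instance threshold
  expect_warning(
    empty <- run_loso_grid(toy_instances(3, 5), "sleep", grid = grid,
                           min_ema = 30),
    "validation")
  expect_equal(nrow(empty), 0L)
})

test_that("identical seed reproduces the LOSO run exactly", {
  inst <- toy_instances(n_subjects = 3, n_per = 30, seed = 6)
  grid <- hyper_grid(learning_rate = 0.1, n_trees = 20, depth = 3,
                     smote = TRUE, k = 5)
  p1 <- run_loso_grid(inst, "sleep", grid = grid, seed = 11, min_ema = 30)
  p2 <- run_loso_grid(inst, "sleep", grid = grid, seed = 11, min_ema = 30)
  expect_identical(p1, p2)
})
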