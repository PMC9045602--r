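# Nonparametric tests, effect sizes, multiplicity, confusion metrics -
# each validated against an independent brute-force or hand oracle.

# independent oracle: one-sided exact signed-rank p by explicit
# enumeration over the 2^n sign vectors via expand.grid
enum_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  ws <- signs %*% r
  if (alternative == "greater") mean(ws >= w_obs - 1e-9)
  else mean(ws <= w_obs + 1e-9)
}

test_that("exact signed-rank p equals full sign enumeration (n <= 12, ties allowed)", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties and both signs
    for (alt in c("greater", "less")) {
      expect_equal(signed_rank_test(d, alt)$p_value,
                   enum_signed_rank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("all-positive deltas of size 10 give the minimal exact one-sided p", {
  d <- seq(0.5, 5, length.out = 10)
  t <- signed_rank_test(d, "greater")
  expect_equal(t$p_value, 2^-10)
  expect_equal(t$statistic, 10 * 11 / 2)
})

test_that("symmetric +/- pairs sit at the null center", {
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  t <- signed_rank_test(d, "greater")
  expect_equal(t$statistic, length(d) * (length(d) + 1) / 4)
  expect_gt(t$p_value, 0.4)
  expect_equal(signed_rank_test(rep(0, 5))$p_value, 1)
  expect_true(signed_rank_test(rep(0, 5))$degenerate)
})

test_that("large-sample approximation agrees with wilcox.test conventions", {
  set.seed(7)
  d <- rnorm(60, 0.3)
  ours <- signed_rank_test(d, "greater", exact_max = 0)
  ref <- wilcox.test(d, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("clustered signed-rank reduces to signed ranks over cluster sums", {
  d <- c(2, 1, -0.5, 3, 1.5, -1)
  cl <- c("a", "a", "b", "b", "c", "c")
  t <- signed_rank_test(d, "greater", clustered = TRUE, cluster = cl)
  r <- rank(abs(d)) * sign(d)
  s <- tapply(r, cl, sum)
  expect_equal(t$statistic, sum(s) / sqrt(sum(s^2)))
  expect_equal(t$p_value, pnorm(sum(s) / sqrt(sum(s^2)), lower.tail = FALSE))
})

test_that("rank-biserial matches hand computation in both forms", {
  expect_equal(rank_biserial(c(2, 1, 3), c(1, 0.5, 1)), 1)  # all favorable
  expect_equal(rank_biserial(a = c(1, 2, 3), b = c(2, 3, 4)), -1)
  d <- c(3, -1, 2, -4)  # ranks of |d|: 3,1,2,4 -> (3+2 - 1-4)/10 = 0
  expect_equal(rank_biserial(d), 0)
  # unpaired: disjoint supports give +/-1; identical samples give 0
  expect_equal(rank_biserial(c(5, 6, 7), c(1, 2), paired = FALSE), 1)
  expect_equal(rank_biserial(c(1, 2), c(5, 6, 7), paired = FALSE), -1)
  expect_equal(rank_biserial(c(1, 2, 3), c(1, 2, 3), paired = FALSE), 0)
  # against the closed form 2U/(n1 n2) - 1 with U from wilcox.test
  set.seed(5)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  u <- suppressWarnings(wilcox.test(a, b)$statistic)
  expect_equal(rank_biserial(a, b, paired = FALSE),
               unname(2 * u / (12 * 15) - 1))
})

test_that("Cramer's V matches the chi-square hand computation", {
  independent <- outer(c(10, 30), c(20, 20)) / 40
  expect_equal(cramers_v(independent), 0)
  expect_equal(cramers_v(diag(c(7, 9))), 1)
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  chi2 <- sum((tab - outer(rowSums(tab), colSums(tab)) / 60)^2 /
                (outer(rowSums(tab), colSums(tab)) / 60))
  expect_equal(cramers_v(tab), sqrt(chi2 / 60))
  expect_error(cramers_v(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("BH step-up flags match the hand oracle and stay monotone", {
  expect_equal(bh_adjust(rep(1, 5)), rep(FALSE, 5))
  expect_true(bh_adjust(0.01, fdr = 0.25))
  p <- c(0.01, 0.02, 0.2, 0.9)
  expect_equal(bh_adjust(p, 0.25), c(TRUE, TRUE, FALSE, FALSE))
  # property: flags equal p.adjust comparison, monotone in p
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    flags <- bh_adjust(p, 0.25)
    expect_equal(flags, p.adjust(p, "BH") <= 0.25)
    if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
  }
})

test_that("per-subject MAE macro average differs from pooled when counts differ", {
  pred <- data.table::data.table(
    subject = c("a", "a", "a", "b", "c", "c"),
    y = c(0, 2, 1, 3, 2, 0), yhat = c(1, 1, 1, 1, 1, 1))
  m <- per_subject_mae(pred)
  expect_equal(m$per_subject[subject == "a"]$mae, mean(c(1, 1, 0)))
  expect_equal(m$macro, mean(c(2 / 3, 2, 1)))
  pooled <- mean(abs(pred$y - pred$yhat))
  expect_false(isTRUE(all.equal(m$macro, pooled)))
  perfect <- data.table::data.table(subject = "a", y = 1:3, yhat = 1:3)
  expect_equal(per_subject_mae(perfect)$macro, 0)
})

test_that("severity metrics recompute from counts", {
  # TP=3 FP=1 TN=5 FN=1 under higher_worse with threshold 1.5
  pred <- data.table::data.table(
    y    = c(3, 3, 2, 2, rep(0, 5), 1),
    yhat = c(2, 2.5, 3, 1, rep(0.5, 4), 2, 1))
  m <- severity_metrics(pred, "higher_worse")
  expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  # perfect predictions
  perf <- data.table::data.table(y = c(0, 3), yhat = c(0, 3))
  mp <- severity_metrics(perf, "higher_worse")
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv), c(1, 1, 1))
  # all predicted non-severe
  none <- data.table::data.table(y = c(0, 3), yhat = c(0, 0))
  mn <- severity_metrics(none, "higher_worse")
  expect_equal(mn$sensitivity, 0)
  expect_equal(mn$specificity, 1)
  expect_true(is.na(mn$ppv))
})

test_that("distribution comparison dispatches continuous and categorical paths", {
  set.seed(4)
  a <- rlnorm(300); b <- rlnorm(300, 1)
  cc <- compare_distributions(a, b, "continuous")
  expect_true(cc$significant)
  expect_lt(cc$effect_size, 0)  # a stochastically smaller than b
  same <- compare_distributions(a, a, "continuous")
  expect_equal(same$effect_size, 0)
  cat_res <- compare_distributions(rep(c("x", "y"), c(40, 10)),
                                   rep(c("x", "y"), c(10, 40)),
                                   "categorical")
  expect_true(cat_res$significant)
  expect_gt(cat_res$effect_size, 0.3)
  expect_error(compare_distributions(rep("x", 5), rep("x", 3),
                                     "categorical"), "categories")
})

test_that("GEE and LMM recover the exact OLS slope on noiseless data", {
  set.seed(12)
  n_subj <- 20; n_per <- 6
  dr <- data.table::data.table(
    subject = rep(sprintf("s%02d", 1:n_subj), each = n_per),
    dpad = rnorm(n_subj * n_per),
    item = "sleep", k = 5)
  dr[, dmae := 0.07 * dpad]  # noiseless: every weighted LS fit is exact
  fit <- suppressWarnings(suppressMessages(pad_mae_association(dr)))
  ols <- coef(lm(dmae ~ dpad, data = dr))[["dpad"]]
  expect_equal(ols, 0.07, tolerance = 1e-10)
  expect_equal(fit$gee[term == "dpad"]$beta, 0.07, tolerance = 1e-6)
  expect_equal(fit$lmm[term == "dpad"]$beta, 0.07, tolerance = 1e-4)

  # with noise the GEE point estimate tracks OLS and its CI covers truth
  dr[, dmae := 0.07 * dpad + rnorm(.N, 0, 0.05)]
  fit2 <- pad_mae_association(dr)
  b <- fit2$gee[term == "dpad"]
  expect_lt(abs(b$beta - coef(lm(dmae ~ dpad, data = dr))[["dpad"]]), 0.01)
  expect_true(b$ci_lo < 0.07 & b$ci_hi > 0.07)
})
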