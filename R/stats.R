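#' Per-subject mean absolute error and its macro average
#'
#' MAE is first computed within each subject and then averaged
#' unweighted across subjects, equalizing each subject's influence
#' regardless of how many responses they contributed.
#'
#' @param predictions prediction records with columns `subject`, `y`,
#'   `yhat`.
#' @return list with `per_subject` (data.table subject, mae, n) and
#'   `macro` (unweighted mean of the per-subject MAEs).
#' @export
per_subject_mae <- function(predictions) {
  dt <- as.data.table(predictions)
  per <- dt[, .(mae = mean(abs(y - yhat)), n = .N), by = subject]
  list(per_subject = per[], macro = mean(per$mae))
}

# exact one-sided upper tail P(W >= w) of the signed-rank statistic by
# full enumeration of sign assignments over the (mid)ranks r
signed_rank_exact_p <- function(r, w, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  n <- length(r)
  # dynamic enumeration over all 2^n subsets via iterative convolution of
  # achievable positive-rank sums
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  if (tail == "upper") mean(sums >= w - 1e-9) else mean(sums <= w + 1e-9)
}

#' Wilcoxon signed-rank test, plain or clustered
#'
#' Unclustered: zero differences are dropped, absolute differences are
#' midranked; for n <= `exact_max` the one-sided p-value is computed by
#' full enumeration of the 2^n sign assignments (valid under ties),
#' otherwise by normal approximation with tie correction and continuity
#' correction.  Clustered: the Rosner-Glynn-Lee form, whose variance is
#' estimated from the within-cluster sums of signed ranks
#' (Z = sum(S_i) / sqrt(sum(S_i^2))), accounting for correlation of
#' paired differences within clusters.
#'
#' @param d paired differences.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`;
#'   `"greater"` tests a positive location.
#' @param clustered use the clustered variant.
#' @param cluster cluster ids (required when `clustered`).
#' @param exact_max largest n for exact enumeration.
#' @return list (class `crossgen_test`): `method`, `statistic` (W, or Z
#'   when clustered), `p_value`, `n`, `degenerate`.
#' @export
signed_rank_test <- function(d, alternative = c("greater", "less",
                                                "two.sided"),
                             clustered = FALSE, cluster = NULL,
                             exact_max = 12) {
  alternative <- match.arg(alternative)
  if (clustered && is.null(cluster)) stop("clustered test needs cluster ids")
  keep <- d != 0
  if (clustered) cluster <- cluster[keep]
  d <- d[keep]
  n <- length(d)
  out <- list(method = if (clustered) "clustered signed-rank (RGL)"
              else "signed-rank", alternative = alternative, n = n,
              degenerate = FALSE)
  if (n == 0L) {
    out$statistic <- NA_real_; out$p_value <- 1; out$degenerate <- TRUE
    class(out) <- "crossgen_test"
    return(out)
  }
  r <- rank(abs(d))
  sgn <- sign(d)
  if (clustered) {
    s_i <- tapply(sgn * r, cluster, sum)
    v <- sum(s_i^2)
    if (v == 0) {
      out$statistic <- 0; out$p_value <- 1; out$degenerate <- TRUE
    } else {
      z <- sum(s_i) / sqrt(v)
      out$statistic <- z
      out$p_value <- switch(alternative,
                            greater = pnorm(z, lower.tail = FALSE),
                            less = pnorm(z),
                            two.sided = 2 * pnorm(-abs(z)))
    }
    class(out) <- "crossgen_test"
    return(out)
  }
  w <- sum(r[sgn > 0])
  out$statistic <- w
  if (n <= exact_max) {
    p_up <- signed_rank_exact_p(r, w, "upper")
    p_lo <- signed_rank_exact_p(r, w, "lower")
    out$p_value <- switch(alternative, greater = p_up, less = p_lo,
                          two.sided = min(1, 2 * min(p_up, p_lo)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z_up <- (w - mu - cc) / sqrt(v)
    z_lo <- (w - mu + cc) / sqrt(v)
    out$p_value <- switch(alternative,
                          greater = pnorm(z_up, lower.tail = FALSE),
                          less = pnorm(z_lo),
                          two.sided = min(1, 2 * min(
                            pnorm(z_up, lower.tail = FALSE), pnorm(z_lo))))
  }
  class(out) <- "crossgen_test"
  out
}

#' @export
print.crossgen_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %d)\n",
              x$method, x$statistic, x$p_value, x$alternative, x$n))
  invisible(x)
}

#' Rank-biserial correlation
#'
#' Paired (Wendt / King-Minium form): the difference between favorable
#' and unfavorable rank sums over the total rank sum of the nonzero
#' paired differences, in \[-1, 1\].  Unpaired: 2U/(n1 n2) - 1 from the
#' Mann-Whitney U of `a` versus `b`.
#'
#' @param a first sample, or the paired differences when `b` is `NULL`.
#' @param b second sample (paired: same length as `a`).
#' @param paired paired or independent-samples form.
#' @return Effect size in \[-1, 1\].
#' @export
rank_biserial <- function(a, b = NULL, paired = TRUE) {
  if (paired) {
    d <- if (is.null(b)) a else a - b
    if (!length(d)) stop("empty input")
    d <- d[d != 0]
    if (!length(d)) return(0)
    r <- rank(abs(d))
    (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
  } else {
    if (is.null(b)) stop("unpaired form needs both samples")
    n1 <- length(a); n2 <- length(b)
    if (!n1 || !n2) stop("empty input")
    r <- rank(c(a, b))
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    2 * u1 / (n1 * n2) - 1
  }
}

#' Cramer's V for a contingency table
#'
#' V = sqrt(chi^2 / (n (min(r, c) - 1))), in \[0, 1\].
#'
#' @param tab contingency table of nonnegative counts, at least 2 x 2.
#' @return Effect size in \[0, 1\].
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2L)) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be nonnegative")
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero-margin table")
  expected <- outer(rs, cs) / n
  chi2 <- sum((tab - expected)^2 / expected)
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

#' Benjamini-Hochberg step-up significance flags
#'
#' @param p p-values in \[0, 1\].
#' @param fdr target false discovery rate (default 0.25).
#' @return Logical rejection flags, monotone in p (rejecting a p-value
#'   rejects all smaller ones).
#' @export
bh_adjust <- function(p, fdr = 0.25) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= fdr * seq_len(m) / m)
  flags <- logical(m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

#' Compare two feature or outcome distributions across studies
#'
#' Continuous: Shapiro-Wilk normality per sample (subsampled above 5000
#' observations), two-sided Mann-Whitney U with the unpaired
#' rank-biserial correlation.  Categorical: chi-square test of
#' independence with Cramer's V.
#'
#' @param a,b the two samples (values, or category labels).
#' @param kind `"continuous"` or `"categorical"`.
#' @param alpha significance level recorded alongside.
#' @return list with test name, statistic, `p_value`, `effect_size`,
#'   `significant` and (continuous) the per-sample normality p-values.
#' @export
compare_distributions <- function(a, b, kind = c("continuous",
                                                 "categorical"),
                                  alpha = 0.05) {
  kind <- match.arg(kind)
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  if (kind == "continuous") {
    shap <- function(v) {
      if (length(unique(v)) < 3L) return(NA_real_)
      if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
      shapiro.test(v)$p.value
    }
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    list(test = "mann-whitney-u", statistic = unname(wt$statistic),
         p_value = wt$p.value,
         effect_size = rank_biserial(a, b, paired = FALSE),
         normality_p = c(a = shap(a), b = shap(b)),
         significant = wt$p.value < alpha)
  } else {
    la <- sort(unique(c(a, b)))
    if (length(la) < 2L) stop("categorical comparison needs >= 2 categories")
    tab <- rbind(table(factor(a, levels = la)), table(factor(b, levels = la)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chi-square", statistic = unname(ct$statistic),
         p_value = ct$p.value, effect_size = cramers_v(tab),
         significant = ct$p.value < alpha)
  }
}

#' Severity classification metrics from regression predictions
#'
#' Regression outputs are binarized: the true label marks the two most
#' severe categories of the item (from the aligned `severe` column or
#' recomputed from `y`), and a prediction counts as severe when it falls
#' in the severe half of the 0-3 scale - at or below 1.5 for
#' higher-is-better items (poor sleep), at or above 1.5 otherwise.
#'
#' @param predictions prediction records with `y`, `yhat` (and
#'   optionally `severe`).
#' @param direction severity direction of the item.
#' @param threshold scale midpoint used for binarization.
#' @param pooled pool instances (default); otherwise per-subject
#'   metrics are returned.
#' @return Pooled: list with counts `tp`, `fp`, `tn`, `fn` and
#'   `sensitivity`, `specificity`, `ppv`, `mae` (undefined metrics are
#'   `NA`).  Per-subject: data.table of the same per subject.
#' @export
severity_metrics <- function(predictions, direction = c("higher_worse",
                                                        "higher_better"),
                             threshold = 1.5, pooled = TRUE) {
  direction <- match.arg(direction)
  dt <- as.data.table(predictions)
  truth <- if ("severe" %in% names(dt)) dt$severe == 1L else {
    if (direction == "higher_worse") dt$y >= 2 else dt$y <= 1
  }
  pred <- if (direction == "higher_worse") dt$yhat >= threshold else
    dt$yhat <= threshold
  calc <- function(truth, pred, y, yhat) {
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         mae = mean(abs(y - yhat)))
  }
  if (pooled) {
    calc(truth, pred, dt$y, dt$yhat)
  } else {
    dt$truth_ <- truth
    dt$pred_ <- pred
    dt[, as.list(calc(truth_, pred_, y, yhat)), by = subject]
  }
}
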