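#' Per-subject paired MAE and PAD deltas across training modes
#'
#' Joins the LOSO prediction records with the PAD table into one row per
#' (item, configuration, subject) carrying the single-study, combined
#' and per-mode baseline MAEs, their difference
#' dMAE = MAE_single - MAE_combined, and the matching PADs with
#' dPAD = PAD_single - PAD_combined.
#'
#' @param predictions output of [run_loso_grid()] containing both
#'   `"single"` and `"combined"` modes.
#' @param pads optional output of [pad_table()].
#' @return data.table of paired delta rows.
#' @export
paired_delta_rows <- function(predictions, pads = NULL) {
  dt <- as.data.table(predictions)
  key_cols <- c("item", "subject", "study", "k", "smote", "learning_rate",
                "n_trees", "depth")
  mae <- dt[, .(mae = mean(abs(y - yhat)), mae_base = mean(abs(y - yhat_base))),
            by = c(key_cols, "mode")]
  wide <- dcast(mae, as.formula(paste(paste(key_cols, collapse = " + "),
                                      "~ mode")),
                value.var = c("mae", "mae_base"))
  wide[, dmae := mae_single - mae_combined]
  if (!is.null(pads) && nrow(pads)) {
    pw <- dcast(as.data.table(pads), item + subject + k ~ mode,
                value.var = "pad")
    setnames(pw, c("single", "combined"), c("pad_single", "pad_combined"),
             skip_absent = TRUE)
    wide <- merge(wide, pw, by = c("item", "subject", "k"), all.x = TRUE)
    wide[, dpad := pad_single - pad_combined]
  }
  wide[]
}

#' Sensitivity analysis of training-data comparisons across the grid
#'
#' For every configuration and comparison, a one-sided clustered
#' signed-rank test over subjects (clusters) of the alternative
#' dMAE_ij = MAE_i - MAE_j > 0 is computed, for i/j in: baseline vs
#' combined (BC), baseline vs single (BS), single vs combined (SC) and
#' combined vs single (CS); intersection columns (BC&SC, BS&CS) require
#' joint significance.  Counts are reported with and without the
#' Benjamini-Hochberg correction applied across configurations within
#' each comparison.
#'
#' @param delta_rows output of [paired_delta_rows()].
#' @param alpha per-test significance level.
#' @param fdr Benjamini-Hochberg false discovery rate.
#' @param by_study split counts by the held-out subject's study.
#' @return list with `per_config` (p-values and flags per configuration
#'   and comparison) and `summary` (counts and integer percentages of
#'   significant configurations).
#' @export
sensitivity_table <- function(delta_rows, alpha = 0.05, fdr = 0.25,
                              by_study = TRUE) {
  dr <- as.data.table(delta_rows)
  cfg_cols <- c("item", "k", "smote", "learning_rate", "n_trees", "depth")
  grp_cols <- if (by_study) c(cfg_cols, "study") else cfg_cols
  comps <- list(
    BC = function(d) d$mae_base_combined - d$mae_combined,
    BS = function(d) d$mae_base_single - d$mae_single,
    SC = function(d) d$mae_single - d$mae_combined,
    CS = function(d) d$mae_combined - d$mae_single)
  per <- rbindlist(lapply(names(comps), function(cmp) {
    dr[, {
      t <- signed_rank_test(comps[[cmp]](.SD), alternative = "greater",
                            clustered = TRUE, cluster = subject)
      .(comparison = cmp, statistic = t$statistic, p_value = t$p_value,
        n_subjects = t$n)
    }, by = grp_cols]
  }))
  split_cols <- setdiff(grp_cols, cfg_cols)
  per[, significant := p_value < alpha]
  per[, significant_bh := bh_adjust(p_value, fdr),
      by = c("comparison", "item", split_cols)]

  n_cfg <- nrow(unique(per[, ..cfg_cols]))
  summ <- per[, .(n_configs = .N, n_sig = sum(significant),
                  pct_sig = round(100 * sum(significant) / .N),
                  n_sig_bh = sum(significant_bh),
                  pct_sig_bh = round(100 * sum(significant_bh) / .N)),
              by = c("item", split_cols, "comparison")]
  # joint-significance (intersection) columns
  inter <- list(c("BC", "SC"), c("BS", "CS"))
  summ_int <- rbindlist(lapply(inter, function(pair) {
    w <- dcast(per[comparison %in% pair],
               as.formula(paste(paste(grp_cols, collapse = " + "),
                                "~ comparison")),
               value.var = c("significant", "significant_bh"))
    w[, .(n_configs = .N,
          n_sig = sum(get(paste0("significant_", pair[1])) &
                        get(paste0("significant_", pair[2]))),
          pct_sig = round(100 * sum(get(paste0("significant_", pair[1])) &
                                      get(paste0("significant_", pair[2]))) / .N),
          n_sig_bh = sum(get(paste0("significant_bh_", pair[1])) &
                           get(paste0("significant_bh_", pair[2]))),
          pct_sig_bh = round(100 * sum(get(paste0("significant_bh_", pair[1])) &
                                         get(paste0("significant_bh_", pair[2]))) / .N)),
      by = c("item", split_cols)][, comparison := paste(pair, collapse = "&")]
  }))
  setcolorder(summ_int, names(summ))
  list(per_config = per[], summary = rbind(summ, summ_int)[])
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Population-averaged clustered linear regression fitted by iterated
#' generalized least squares with a moment estimate of the exchangeable
#' correlation, reported with robust (sandwich) standard errors.
#'
#' @param x design matrix (including intercept column).
#' @param y response.
#' @param id cluster ids.
#' @param maxit,tol iteration controls.
#' @return list with `coefficients` (data.table term, beta, se, ci_lo,
#'   ci_hi, p), `rho`, `n_clusters`.
#' @export
gee_exchangeable <- function(x, y, id, maxit = 50, tol = 1e-8) {
  x <- as.matrix(x)
  id <- as.character(id)
  clusters <- split(seq_along(y), id)
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  beta <- qr.solve(crossprod(x), crossprod(x, y))
  rho <- 0
  # closed-form inverse of the exchangeable block phi*[(1-rho)I + rho*J]
  vinv_times <- function(m, ni, phi, rho) {
    a <- 1 / (phi * (1 - rho))
    b <- -rho / (phi * (1 - rho) * (1 + (ni - 1) * rho))
    a * m + b * matrix(colSums(m), ni, ncol(m), byrow = TRUE)
  }
  for (it in seq_len(maxit)) {
    e <- y - drop(x %*% beta)
    phi <- mean(e^2)
    num <- 0; den <- 0
    for (ix in clusters) {
      ni <- length(ix)
      if (ni > 1) {
        num <- num + (sum(e[ix])^2 - sum(e[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    rho <- if (den > 0) max(min(num / (den * phi), 0.99), -0.99) else 0
    A <- matrix(0, ncol(x), ncol(x)); b <- numeric(ncol(x))
    for (ix in clusters) {
      ni <- length(ix)
      xi <- x[ix, , drop = FALSE]
      A <- A + crossprod(xi, vinv_times(xi, ni, phi, rho))
      b <- b + crossprod(xi, vinv_times(cbind(y[ix]), ni, phi, rho))
    }
    beta_new <- qr.solve(A, b)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  e <- y - drop(x %*% beta)
  A <- matrix(0, ncol(x), ncol(x)); M <- matrix(0, ncol(x), ncol(x))
  phi <- mean(e^2)
  for (ix in clusters) {
    ni <- length(ix)
    xi <- x[ix, , drop = FALSE]
    A <- A + crossprod(xi, vinv_times(xi, ni, phi, rho))
    u <- crossprod(xi, vinv_times(cbind(e[ix]), ni, phi, rho))
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  vc <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(vc))
  z <- drop(beta) / se
  co <- data.table(term = colnames(x), beta = drop(beta), se = se,
                   ci_lo = drop(beta) - qnorm(0.975) * se,
                   ci_hi = drop(beta) + qnorm(0.975) * se,
                   p = 2 * pnorm(-abs(z)))
  list(coefficients = co, rho = rho, n_clusters = length(clusters))
}

#' Association between the change in Proxy-A distance and in MAE
#'
#' Estimates how dMAE = MAE_single - MAE_combined moves per unit of
#' dPAD = PAD_single - PAD_combined within subjects, controlling for the
#' outcome item and the personalization neighbor count, with two
#' estimators on the identical row set: a population-averaged GEE
#' (exchangeable working correlation, robust SEs) and a random-intercept
#' linear mixed model (cluster = subject, Wald intervals).
#'
#' @param delta_rows rows with `dmae`, `dpad`, `item`, `k`, `subject`
#'   (one per subject x configuration).
#' @return list with `gee` and `lmm` coefficient tables, `n_rows`,
#'   `n_clusters`.
#' @export
pad_mae_association <- function(delta_rows) {
  dr <- as.data.table(delta_rows)
  dr <- dr[complete.cases(dr[, .(dmae, dpad)])]
  if (uniqueN(dr$subject) < 2L) stop("need at least 2 subject clusters")
  dr[, k_label := ifelse(is.finite(k), paste0("k", k), "kall")]
  rhs <- "dpad"
  if (uniqueN(dr$item) > 1L) rhs <- c(rhs, "item")
  if (uniqueN(dr$k_label) > 1L) rhs <- c(rhs, "k_label")
  fml <- as.formula(paste("~", paste(rhs, collapse = " + ")))
  x <- model.matrix(fml, data = dr)
  gee <- gee_exchangeable(x, dr$dmae, dr$subject)
  lf <- as.formula(paste("dmae ~", paste(rhs, collapse = " + "),
                         "+ (1 | subject)"))
  lmm <- lme4::lmer(lf, data = dr, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  fe <- lme4::fixef(lmm)
  se <- sqrt(diag(as.matrix(vcov(lmm))))
  z <- fe / se
  lco <- data.table(term = names(fe), beta = unname(fe), se = unname(se),
                    ci_lo = unname(fe - qnorm(0.975) * se),
                    ci_hi = unname(fe + qnorm(0.975) * se),
                    p = unname(2 * pnorm(-abs(z))))
  list(gee = gee$coefficients, lmm = lco, n_rows = nrow(dr),
       n_clusters = uniqueN(dr$subject), rho = gee$rho)
}
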