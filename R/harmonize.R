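#' Daily and 6-hour epoch features from one day of hourly values
#'
#' Each sensing variable contributes five features per day: one whole-day
#' summary and one per 6-hour epoch (12AM-6AM, 6AM-12PM, 12PM-6PM,
#' 6PM-12AM).  Epochs are half-open \[start, end): a value stamped at
#' exactly 6AM belongs to the 6AM-12PM epoch.  For `"sum"`/`"count"`
#' aggregation, missing hours contribute nothing (no recorded events); for
#' `"mean"`, the summary is the mean of the observed hours and is `NA`
#' when no hour is observed.
#'
#' @param hourly numeric vector of 24 hourly values (hour 0 .. 23),
#'   `NA` = no data that hour.
#' @param aggregation `"sum"`, `"count"` or `"mean"`.
#' @return Named numeric vector of length 5: `daily`, `ep1` .. `ep4`.
#' @export
epoch_features <- function(hourly, aggregation = c("sum", "count", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(hourly) != 24L) stop("hourly must have length 24")
  agg <- function(v) {
    if (aggregation == "mean") {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else {
      sum(v, na.rm = TRUE)
    }
  }
  ep <- vapply(0:3, function(e) agg(hourly[(6 * e + 1):(6 * e + 6)]),
               numeric(1))
  c(daily = agg(hourly), ep1 = ep[1], ep2 = ep[2], ep3 = ep[3], ep4 = ep[4])
}

#' Per subject-day feature table from a long hourly sensing table
#'
#' Computes, for every subject-day, the 43 canonical sensor features
#' (8 epoch-aggregated variables x 5 features + 3 day-level sleep
#' features) and the day's coverage in hours.  Coverage counts distinct
#' hours carrying a non-missing value for any epoch variable.
#'
#' @param sensor long table with columns `subject`, `study`, `date`
#'   (integer day index), `variable`, `hour` (0-23, `NA` for day-level
#'   sleep variables) and `value`.
#' @param aggregation named map variable -> aggregation, defaulting to
#'   [default_aggregation()].
#' @return data.table keyed by (`subject`, `date`) with `study`,
#'   `hours_with_data` and the 43 feature columns ([feature_names()]).
#' @export
compute_day_features <- function(sensor, aggregation = default_aggregation()) {
  sensor <- as.data.table(sensor)
  unknown <- setdiff(unique(sensor$variable), aligned_variables())
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(epoch_variables() %in% names(aggregation))) {
    stop("aggregation map must cover all epoch variables")
  }

  epoch_rows <- sensor[variable %in% epoch_variables()]
  cov <- epoch_rows[!is.na(value),
                    .(hours_with_data = uniqueN(hour)),
                    by = .(subject, study, date)]

  feats <- epoch_rows[, {
    hh <- rep(NA_real_, 24L)
    hh[hour + 1L] <- value
    as.list(epoch_features(hh, aggregation[[variable[1L]]]))
  }, by = .(subject, study, date, variable)]
  wide <- dcast(feats, subject + study + date ~ variable,
                value.var = c("daily", "ep1", "ep2", "ep3", "ep4"))
  # dcast names are <stat>_<variable>; rename to <variable>.<stat>
  for (v in epoch_variables()) {
    for (s in c("daily", "ep1", "ep2", "ep3", "ep4")) {
      old <- paste(s, v, sep = "_")
      if (old %in% names(wide)) setnames(wide, old, paste(v, s, sep = "."))
    }
  }

  sleep <- sensor[variable %in% sleep_variables(),
                  .(value = value[1L]), by = .(subject, study, date, variable)]
  if (nrow(sleep)) {
    sleep_wide <- dcast(sleep, subject + study + date ~ variable,
                        value.var = "value")
    wide <- merge(wide, sleep_wide, by = c("subject", "study", "date"),
                  all.x = TRUE)
  }
  for (v in sleep_variables()) {
    if (!v %in% names(wide)) wide[, (v) := NA_real_]
  }
  out <- merge(wide, cov, by = c("subject", "study", "date"), all.x = TRUE)
  out[is.na(hours_with_data), hours_with_data := 0L]
  missing_cols <- setdiff(feature_names(FALSE), names(out))
  for (cc in missing_cols) out[, (cc) := 0]
  setcolorder(out, c("subject", "study", "date", "hours_with_data",
                     feature_names(FALSE)))
  setkeyv(out, c("subject", "date"))
  out[]
}

#' Drop days with insufficient sensing coverage
#'
#' Days derived from close-to-raw sensing data are retained only when at
#' least `min_hours` of the day carry collected data.  The rule applies
#' only to studies flagged as raw-derived; studies whose public release
#' already contains curated day-level features pass through untouched.
#'
#' @param day_features output of [compute_day_features()].
#' @param min_hours coverage threshold in hours (default 19).
#' @param raw_derived character vector of study ids the rule applies to;
#'   `NULL` applies it to every study.
#' @return Filtered day-feature table.
#' @export
filter_low_coverage_days <- function(day_features, min_hours = 19,
                                     raw_derived = NULL) {
  dt <- as.data.table(day_features)
  if (is.null(raw_derived)) {
    dt[hours_with_data >= min_hours]
  } else {
    dt[!(study %in% raw_derived) | hours_with_data >= min_hours]
  }
}

#' Align EMA responses with trailing-window behavioral features
#'
#' For every EMA response on day t the model inputs are the means of each
#' day-level feature over the available days in \{t-window+1, ..., t\}
#' (window = 3 by default: days 4-6 for an EMA on day 6).  A 44th feature
#' counts the days missing from the window.  Sleep features missing for
#' the whole window are filled with the subject's mean observed sleep
#' feature value.  Responses whose window contains no sensor day at all
#' are dropped with a warning.
#'
#' @param day_features per-day feature table, already coverage-filtered.
#' @param ema normalized EMA table (see [normalize_ema()]) with columns
#'   `subject`, `study`, `date`, `item`, `value`, `severe`.
#' @param window trailing window length in days (>= 1).
#' @param sleep_fill fill all-missing sleep windows with the subject mean.
#' @return data.table of aligned instances: identifiers, `item`,
#'   `outcome`, `severe` and the 44 feature columns.
#' @export
build_aligned_instances <- function(day_features, ema, window = 3,
                                    sleep_fill = TRUE) {
  stopifnot(window >= 1)
  day_features <- as.data.table(day_features)
  ema <- as.data.table(ema)
  fn <- feature_names(FALSE)

  day_split <- split(day_features, by = "subject")
  subj_sleep_mean <- day_features[, lapply(.SD, function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  }), .SDcols = sleep_variables(), by = subject]
  setkey(subj_sleep_mean, subject)
  global_sleep_mean <- vapply(sleep_variables(), function(v) {
    z <- day_features[[v]]
    if (all(is.na(z))) 0 else mean(z, na.rm = TRUE)
  }, numeric(1))

  n_skipped <- 0L
  rows <- vector("list", nrow(ema))
  for (i in seq_len(nrow(ema))) {
    e <- ema[i]
    days <- day_split[[as.character(e$subject)]]
    win <- if (is.null(days)) NULL else
      days[date >= e$date - window + 1L & date <= e$date]
    if (is.null(win) || nrow(win) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_missing <- window - nrow(win)
    f <- vapply(fn, function(cc) {
      z <- win[[cc]]
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    }, numeric(1))
    if (sleep_fill) {
      for (v in sleep_variables()) {
        if (is.na(f[[v]])) {
          fill <- subj_sleep_mean[.(e$subject)][[v]]
          f[[v]] <- if (is.na(fill)) global_sleep_mean[[v]] else fill
        }
      }
    }
    rows[[i]] <- c(list(subject = e$subject, study = e$study, date = e$date,
                        item = e$item, outcome = e$value, severe = e$severe),
                   as.list(f), list(missing_days = n_missing))
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d EMA response(s) skipped: no sensor days in window",
                    n_skipped))
  }
  out <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) return(out)
  setcolorder(out, c("subject", "study", "date", "item", "outcome", "severe",
                     feature_names(TRUE)))
  out[]
}

#' Unlock-duration and sleep day values from phone lock intervals
#'
#' Studies releasing only phone lock events are converted to the aligned
#' schema by (a) crediting each hour with its unlocked minutes and (b)
#' estimating sleep as the longest locked interval intersecting the
#' 9PM-to-noon night window, attributing it to the waking day.  Sleep
#' onset/wake are expressed in hours since midnight of the night-start
#' day, so 11PM is 23 and 7AM the next day is 31; duration is wake minus
#' onset.
#'
#' @param lock_intervals table with columns `subject`, `start`, `end`:
#'   locked intervals in absolute hours since midnight of day 1 (day d
#'   spans \[(d-1) * 24, d * 24)).  Intervals must not overlap within a
#'   subject.
#' @param n_days number of study days to emit.
#' @param study study id stamped on the output.
#' @return Long sensing table (schema of [compute_day_features()]) with
#'   hourly `unlock_duration` (minutes) and day-level sleep variables;
#'   days without a locked interval in the night window carry no sleep
#'   rows.
#' @export
derive_lock_based_streams <- function(lock_intervals, n_days,
                                      study = "studentlife") {
  li <- as.data.table(lock_intervals)
  stopifnot(all(li$end >= li$start))
  setorder(li, subject, start)
  overlap <- li[, any(head(end, -1L) > tail(start, -1L) + 1e-9), by = subject]
  if (any(overlap$V1)) stop("overlapping lock intervals")

  out <- vector("list", 0L)
  for (s in unique(li$subject)) {
    iv <- li[subject == s]
    # hourly unlocked minutes
    locked_in_hour <- function(h0) {
      lo <- pmax(iv$start, h0); hi <- pmin(iv$end, h0 + 1)
      sum(pmax(hi - lo, 0))
    }
    hrs <- data.table(
      subject = s, study = study,
      date = rep(seq_len(n_days), each = 24L),
      variable = "unlock_duration",
      hour = rep(0:23, times = n_days))
    abs_hour <- (hrs$date - 1L) * 24 + hrs$hour
    hrs[, value := 60 * (1 - vapply(abs_hour, locked_in_hour, numeric(1)))]
    out[[length(out) + 1L]] <- hrs

    for (d in seq_len(n_days)) {
      w0 <- (d - 1) * 24 - 3   # 9PM of day d-1
      w1 <- (d - 1) * 24 + 12  # noon of day d
      lo <- pmax(iv$start, w0); hi <- pmin(iv$end, w1)
      olap <- hi - lo
      cand <- which(olap > 0)
      if (!length(cand)) next
      best <- cand[which.max(iv$end[cand] - iv$start[cand])]
      onset <- iv$start[best] - (d - 2) * 24  # hours since midnight, day d-1
      wake <- iv$end[best] - (d - 2) * 24
      out[[length(out) + 1L]] <- data.table(
        subject = s, study = study, date = d,
        variable = sleep_variables(), hour = NA_integer_,
        value = c(onset, wake, wake - onset))
    }
  }
  rbindlist(out)
}
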