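# Small programmatic fixtures shared across test files.

# Long hourly sensing table for one subject-day from a named list of
# 24-vectors (missing variables default to zeros).
toy_sensor_day <- function(subject = "s1", study = "a", date = 1L,
                           values = list()) {
  rows <- lapply(epoch_variables(), function(v) {
    val <- if (v %in% names(values)) values[[v]] else rep(0, 24)
    data.table::data.table(subject = subject, study = study, date = date,
                           variable = v, hour = 0:23, value = val)
  })
  data.table::rbindlist(rows)
}

toy_sleep_day <- function(subject = "s1", study = "a", date = 1L,
                          onset = 23, wake = 31) {
  data.table::data.table(subject = subject, study = study, date = date,
                         variable = sleep_variables(), hour = NA_integer_,
                         value = c(onset, wake, wake - onset))
}

# Random aligned-instance table: n_subjects x n_per instances with iid
# features and outcomes on the 0..3 grid, split over two studies.
toy_instances <- function(n_subjects = 6, n_per = 10, seed = 1,
                          item = "sleep") {
  set.seed(seed)
  fn <- feature_names()
  rows <- lapply(seq_len(n_subjects), function(s) {
    x <- matrix(rnorm(n_per * length(fn), mean = s %% 3), n_per,
                dimnames = list(NULL, fn))
    dt <- data.table::as.data.table(x)
    dt[, `:=`(subject = sprintf("s%02d", s),
              # below 4 subjects a two-study split would leave empty
              # single-study training sets
              study = if (n_subjects < 4) "a" else
                ifelse(s <= n_subjects / 2, "a", "b"),
              date = seq_len(n_per), item = item,
              outcome = sample(0:3, n_per, replace = TRUE))]
    dt[, severe := as.integer(outcome <= 1)]
    dt
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("subject", "study", "date", "item",
                                 "outcome", "severe", fn))
  out
}

# Small fast study config for generator tests.
tiny_config <- function(study_id = "a", n_subjects = 3, n_days = 30,
                        seed = 1, ...) {
  study_config(study_id, n_subjects = n_subjects, n_days = n_days,
               seed = seed, n_cal = 300, ...)
}
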