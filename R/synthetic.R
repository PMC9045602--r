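#' Specify the behavior-to-symptom link of a synthetic study
#'
#' Synthetic EMA outcomes are produced by applying a link to each
#' subject's noiseless 3-day trailing mean of the daily behavioral
#' summaries: a weighted sum of standardized summaries is passed through
#' the link form, a subject-level intercept and Gaussian noise are added,
#' and the latent value is discretized onto the outcome grid so that the
#' study's marginal category frequencies match `category_prior`.
#'
#' No public generative model exists for these data; every distributional
#' choice here is a documented stand-in with the qualitative structure
#' the analysis assumes (heavy-tailed non-negative features, ordinal 0-3
#' outcomes with under-represented severe categories).
#'
#' @param weights named numeric vector of per-variable weights (names
#'   must be aligned variables; unnamed variables get weight 0).
#' @param noise_sd Gaussian noise scale on the latent (>= 0).
#' @param form link form applied to the weighted sum: `"linear"`,
#'   `"threshold"` (sign step) or `"saturating"` (tanh).
#' @param grid ordered outcome categories on the 0-3 scale.
#' @param category_prior target marginal probability of each grid
#'   category; sums to 1.
#' @param intercept latent intercept; with zero weights and zero noise
#'   every outcome is the grid value nearest the intercept.
#' @return A `link_spec` object.
#' @export
link_spec <- function(weights = numeric(0), noise_sd = 0.8,
                      form = c("linear", "threshold", "saturating"),
                      grid = 0:3, category_prior = rep(1 / length(grid),
                                                       length(grid)),
                      intercept = 1.5) {
  form <- match.arg(form)
  if (length(weights) && (is.null(names(weights)) ||
                          !all(names(weights) %in% aligned_variables()))) {
    stop("weights must be named by aligned variables")
  }
  if (!all(is.finite(weights))) stop("weights must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0 | grid > 3)) {
    stop("grid must be strictly ascending within [0, 3]")
  }
  if (length(category_prior) != length(grid) ||
      abs(sum(category_prior) - 1) > 1e-8 || any(category_prior < 0)) {
    stop("category_prior must be a probability vector over the grid")
  }
  structure(list(weights = weights, noise_sd = noise_sd, form = form,
                 grid = grid, category_prior = category_prior,
                 intercept = intercept),
            class = "link_spec")
}

#' Specify how a second study's marginals differ from the first
#'
#' @param location per-variable additive shift of the daily summary
#'   (scalar recycled, or named vector); applied as `location / 24` per
#'   hourly value so the daily sum shifts by `location`.
#' @param scale multiplicative scale (> 0), scalar or named vector.
#' @param missing_rate probability that a subject-day of sensing data is
#'   dropped entirely.
#' @param schedule EMA delivery schedule: either
#'   `list(type = "fixed", days = c(1, 3, 5), jitter = p)` (calendar
#'   cadence, e.g. Mon/Wed/Fri, each prompt skipped with probability
#'   `jitter`) or `list(type = "bernoulli", period = d)` (each day is an
#'   EMA day with probability `1 / period` - an irregular schedule).
#' @return A `shift_spec` object.
#' @export
shift_spec <- function(location = 0, scale = 1, missing_rate = 0.1,
                       schedule = list(type = "fixed", days = c(1, 3, 5),
                                       jitter = 0.1)) {
  if (any(scale <= 0)) stop("scale must be > 0")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]")
  if (!schedule$type %in% c("fixed", "bernoulli")) {
    stop("schedule type must be 'fixed' or 'bernoulli'")
  }
  structure(list(location = location, scale = scale,
                 missing_rate = missing_rate, schedule = schedule),
            class = "shift_spec")
}

#' Default marginal families of the sensing variables
#'
#' Durations and distances are log-normal (non-negative, heavy-tailed);
#' event counts are negative-binomial (overdispersed).  Parameters are
#' per-hour at the peak of the diurnal profile.
#'
#' @return Named list of family descriptors.
#' @export
default_families <- function() {
  ln <- function(meanlog, sdlog) list(family = "lognormal",
                                      meanlog = meanlog, sdlog = sdlog)
  nb <- function(mu, size) list(family = "nbinom", mu = mu, size = size)
  list(activity_on_foot = ln(0.8, 0.9),       # minutes on foot / hour
       activity_still = ln(2.8, 0.5),
       activity_unknown = ln(0.2, 0.8),
       conversation_duration = ln(1.0, 1.0),
       conversation_count = nb(0.5, 1.2),
       location_distance = ln(-0.5, 1.3),     # km / hour
       unlock_duration = ln(1.4, 0.8),
       unique_locations = nb(0.3, 1.5))
}

#' Default behavior-to-symptom links for the two modeled items
#'
#' Sleep quality loads positively on sleep duration and conversational
#' activity and negatively on nighttime phone use; stress loads
#' positively on phone use and negatively on social behavior.  Category
#' priors put roughly a fifth to a quarter of responses in the severe
#' half (poor sleep 0-1, high stress 2-3), matching the imbalance the
#' oversampling stage targets.
#'
#' @return Named list of [link_spec()] objects for `sleep` and `stress`.
#' @export
default_links <- function() {
  list(
    sleep = link_spec(
      weights = c(sleep_duration = 0.7, conversation_duration = 0.3,
                  unlock_duration = -0.4, activity_on_foot = 0.3),
      noise_sd = 0.8, form = "linear", grid = 0:3,
      category_prior = c(0.07, 0.15, 0.45, 0.33)),
    stress = link_spec(
      weights = c(unlock_duration = 0.5, conversation_count = -0.4,
                  activity_on_foot = -0.3, sleep_duration = -0.3),
      noise_sd = 0.8, form = "linear", grid = 0:3,
      category_prior = c(0.35, 0.42, 0.15, 0.08)))
}

#' Configure one synthetic study
#'
#' @param study_id study label.
#' @param n_subjects,n_days positive integers.
#' @param links named list of [link_spec()], one per EMA item.
#' @param shift a [shift_spec()].
#' @param seed master seed; expanded into independent per-subject
#'   substreams so subject s's data do not change when `n_subjects` does.
#' @param variables sensing variables; must cover the full aligned set.
#' @param families marginal families per epoch variable.
#' @param subject_sd SD of the log-normal subject-level multiplier on
#'   each variable (between-subject behavioral heterogeneity).
#' @param subject_intercept_sd SD of the subject-level latent intercept
#'   (within-subject outcome correlation).
#' @param mappings named list of [ema_mapping()] used to express the
#'   generated outcomes on the study's raw response scale; defaults to
#'   the identity 0-3 scale per item.
#' @param raw_derived flag marking the study as derived from raw sensing
#'   (subject to the 19-hour coverage rule downstream).
#' @param n_cal Monte-Carlo sample size used to calibrate the link's
#'   standardization moments and grid cutpoints (larger = category
#'   frequencies closer to `category_prior`).
#' @return A `study_config` object.
#' @export
study_config <- function(study_id, n_subjects, n_days,
                         links = default_links(), shift = shift_spec(),
                         seed = 1, variables = aligned_variables(),
                         families = default_families(), subject_sd = 0.35,
                         subject_intercept_sd = 0.3, mappings = NULL,
                         raw_derived = FALSE, n_cal = 1500) {
  if (n_subjects <= 0 || n_days <= 0) {
    stop("n_subjects and n_days must be positive")
  }
  if (!all(aligned_variables() %in% variables)) {
    stop("variables must cover the full aligned set")
  }
  if (is.null(mappings)) {
    mappings <- lapply(setNames(names(links), names(links)), mapping_crosscheck)
  }
  structure(list(study_id = study_id, n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), links = links, shift = shift,
                 seed = as.integer(seed), variables = variables,
                 families = families, subject_sd = subject_sd,
                 subject_intercept_sd = subject_intercept_sd,
                 mappings = mappings, raw_derived = raw_derived,
                 n_cal = as.integer(n_cal)),
            class = "study_config")
}

# ---- internal simulation helpers -------------------------------------

# diurnal weight per hour (low overnight, peaked midday/evening)
diurnal_profile <- function() {
  c(rep(0.15, 6), rep(1.0, 6), rep(1.1, 6), rep(0.9, 6))
}

# n_days x 24 matrix of hourly values for one subject and variable
sim_hourly <- function(fam, n_days, mult) {
  w <- diurnal_profile()
  n <- n_days * 24L
  wv <- rep(w, times = n_days)
  v <- switch(fam$family,
    lognormal = wv * mult * rlnorm(n, fam$meanlog, fam$sdlog),
    nbinom = rnbinom(n, mu = pmax(wv * mult * fam$mu, 1e-8), size = fam$size),
    stop("unknown family"))
  matrix(v, nrow = n_days, ncol = 24L, byrow = TRUE)
}

shift_value <- function(spec_field, variable, default) {
  if (is.null(names(spec_field))) spec_field[1L]
  else if (variable %in% names(spec_field)) spec_field[[variable]]
  else default
}

# daily summaries (n_days x n_vars) for one subject, shift applied
sim_subject_days <- function(config, subj_mult, sleep_base) {
  nd <- config$n_days
  ep <- epoch_variables()
  hourly <- vector("list", length(ep))
  names(hourly) <- ep
  daily <- matrix(0, nd, length(ep), dimnames = list(NULL, ep))
  for (v in ep) {
    h <- sim_hourly(config$families[[v]], nd, subj_mult[[v]])
    sc <- shift_value(config$shift$scale, v, 1)
    loc <- shift_value(config$shift$location, v, 0)
    h <- pmax(h * sc + loc / 24, 0)
    hourly[[v]] <- h
    daily[, v] <- rowSums(h)
  }
  onset <- sleep_base["onset"] + rnorm(nd, 0, 0.7)
  dur <- pmax(sleep_base["duration"] + rnorm(nd, 0, 0.8), 2)
  sleep <- cbind(sleep_onset = onset, sleep_wake = onset + dur,
                 sleep_duration = dur)
  for (v in sleep_variables()) {
    sc <- shift_value(config$shift$scale, v, 1)
    loc <- shift_value(config$shift$location, v, 0)
    sleep[, v] <- sleep[, v] * sc + loc
  }
  list(hourly = hourly, daily = cbind(daily, sleep))
}

draw_subject_effects <- function(config) {
  ep <- epoch_variables()
  mult <- setNames(exp(rnorm(length(ep), 0, config$subject_sd)), ep)
  sleep_base <- c(onset = 23.5 + rnorm(1, 0, 0.5),
                  duration = 7.5 + rnorm(1, 0, 0.5))
  u <- rnorm(1, 0, config$subject_intercept_sd)
  list(mult = mult, sleep_base = sleep_base, u = u)
}

# trailing window-mean matrix of daily summaries (noiseless "truth")
trailing_mean <- function(daily, window = 3L) {
  nd <- nrow(daily)
  out <- matrix(NA_real_, nd, ncol(daily), dimnames = dimnames(daily))
  for (d in seq_len(nd)) {
    rows <- max(1L, d - window + 1L):d
    out[d, ] <- colMeans(daily[rows, , drop = FALSE])
  }
  out
}

link_signal <- function(link, z) {
  vars <- names(link$weights)
  s <- if (length(vars)) drop(z[, vars, drop = FALSE] %*% link$weights) else
    rep(0, nrow(z))
  switch(link$form,
         linear = s,
         threshold = ifelse(s > 0, 1, -1),
         saturating = tanh(s))
}

# Monte-Carlo calibration of standardization moments and grid cutpoints,
# run on its own RNG substream so the cutpoints depend only on
# (config, seed), not on the realized subjects.
calibrate_links <- function(config, calib_seed,
                            n_cal = config$n_cal %||% 1500L) {
  set.seed(calib_seed)
  vars <- c(epoch_variables(), sleep_variables())
  m3 <- matrix(NA_real_, n_cal, length(vars), dimnames = list(NULL, vars))
  u <- numeric(n_cal)
  for (i in seq_len(n_cal)) {
    eff <- draw_subject_effects(config)
    cfg3 <- config
    cfg3$n_days <- 3L
    sim <- sim_subject_days(cfg3, eff$mult, eff$sleep_base)
    m3[i, ] <- colMeans(sim$daily)
    u[i] <- eff$u
  }
  center <- colMeans(m3)
  scale <- apply(m3, 2, sd)
  scale[scale < 1e-12] <- 1
  z <- sweep(sweep(m3, 2, center), 2, scale, "/")
  cuts <- lapply(config$links, function(link) {
    latent <- link$intercept + link_signal(link, z) + u +
      rnorm(n_cal, 0, link$noise_sd)
    if (sd(latent) < 1e-8) {
      list(degenerate = TRUE, cutpoints = NULL)
    } else {
      pr <- cumsum(link$category_prior)
      list(degenerate = FALSE,
           cutpoints = unname(quantile(latent, pr[-length(pr)])))
    }
  })
  list(center = center, scale = scale, cuts = cuts)
}

discretize_latent <- function(latent, link, cut) {
  if (cut$degenerate) {
    grid <- link$grid
    idx <- vapply(pmin(pmax(latent, 0), 3),
                  function(x) which.min(abs(grid - x)), integer(1))
  } else {
    idx <- findInterval(latent, cut$cutpoints) + 1L
  }
  link$grid[idx]
}

ema_days <- function(schedule, n_days) {
  if (schedule$type == "fixed") {
    dow <- ((seq_len(n_days) - 1L) %% 7L) + 1L
    days <- which(dow %in% schedule$days)
    jit <- if (is.null(schedule$jitter)) 0 else schedule$jitter
    if (jit > 0) days <- days[runif(length(days)) >= jit]
    days
  } else {
    p <- 1 / schedule$period
    which(runif(n_days) < p)
  }
}

raw_from_normalized <- function(value, mapping) {
  vapply(value, function(v) {
    hit <- which(mapping$normalized == v)
    if (!length(hit)) stop("generated value off the mapping grid")
    as.character(mapping$raw[hit[1L]])
  }, character(1))
}

# ---- public generator ------------------------------------------------

#' Generate one synthetic study
#'
#' Produces the long hourly sensing table and the raw EMA response table
#' for a configured study.  Outcomes are driven by the noiseless 3-day
#' trailing mean of the daily summaries (so harmonization can in
#' principle recover the signal exactly), and sensing missingness is
#' injected afterwards.  Reproducible: identical `(config, seed)` give
#' identical datasets.
#'
#' @param config a [study_config()].
#' @param include_sensor assemble the (large) hourly sensing table; set
#'   `FALSE` to generate outcomes only, e.g. for Monte-Carlo checks of
#'   the EMA marginals.  The EMA stream is identical either way.
#' @param calibration optionally, a link calibration (standardization
#'   moments and grid cutpoints) taken from another study.  When two
#'   studies share a link, the second study must reuse the first study's
#'   calibration so that the feature-to-symptom conditional is identical
#'   on the raw feature scale; its own category priors then emerge from
#'   its shifted features instead of being imposed.
#' @return A `study_dataset`: list with `sensor` (long hourly table),
#'   `ema` (subject, study, date, item, raw_value), `study_id`, `config`.
#' @export
generate_study <- function(config, include_sensor = TRUE,
                           calibration = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  calib_seed <- sample.int(2147483646L, 1)
  subj_seeds <- sample.int(2147483646L, config$n_subjects)
  calib <- if (is.null(calibration)) calibrate_links(config, calib_seed)
           else calibration

  ep <- epoch_variables()
  sensor_list <- vector("list", config$n_subjects)
  ema_list <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(subj_seeds[s])
    sid <- sprintf("%s_%02d", config$study_id, s)
    eff <- draw_subject_effects(config)
    sim <- sim_subject_days(config, eff$mult, eff$sleep_base)

    if (include_sensor) {
      hr <- rbindlist(lapply(ep, function(v) {
        data.table(subject = sid, study = config$study_id,
                   date = rep(seq_len(config$n_days), times = 24L),
                   variable = v,
                   hour = rep(0:23, each = config$n_days),
                   value = as.vector(sim$hourly[[v]]))
      }))
      sl <- data.table(subject = sid, study = config$study_id,
                       date = rep(seq_len(config$n_days), times = 3L),
                       variable = rep(sleep_variables(),
                                      each = config$n_days),
                       hour = NA_integer_,
                       value = as.vector(sim$daily[, sleep_variables()]))
      sensor_list[[s]] <- rbind(hr, sl)
    }

    m3 <- trailing_mean(sim$daily)
    z <- sweep(sweep(m3, 2, calib$center), 2, calib$scale, "/")
    days <- ema_days(config$shift$schedule, config$n_days)
    if (length(days)) {
      ema_list[[s]] <- rbindlist(lapply(names(config$links), function(it) {
        link <- config$links[[it]]
        latent <- link$intercept + link_signal(link, z[days, , drop = FALSE]) +
          eff$u + rnorm(length(days), 0, link$noise_sd)
        val <- discretize_latent(latent, link, calib$cuts[[it]])
        data.table(subject = sid, study = config$study_id, date = days,
                   item = it,
                   raw_value = raw_from_normalized(val, config$mappings[[it]]))
      }))
    }
  }
  ds <- structure(list(sensor = rbindlist(sensor_list),
                       ema = rbindlist(ema_list),
                       study_id = config$study_id, config = config),
                  class = "study_dataset")
  if (include_sensor && config$shift$missing_rate > 0) {
    ds <- inject_missingness(ds, config$shift$missing_rate,
                             seed = derive_seed(config$seed, 77L))
  }
  ds
}

#' Generate a pair of linked synthetic studies
#'
#' Study B's sensing features are drawn from study A's marginal families
#' transformed by B's [shift_spec()] (so the configured shift is the only
#' systematic feature difference).  With `shared_link = TRUE` both
#' studies share A's behavior-to-symptom links; otherwise B keeps its own
#' links, which may be opposed to A's (a negative-transfer scenario).
#'
#' @param config_a,config_b [study_config()] objects with identical
#'   variable lists.
#' @param shared_link copy A's links *and* A's link calibration into B,
#'   making the raw-feature-to-symptom conditional identical across the
#'   two studies (B's outcome marginals then follow from its feature
#'   shift).  With `FALSE` each study calibrates its own links, which may
#'   be opposed (a negative-transfer scenario).
#' @return List with elements `a` and `b` (two `study_dataset`s).
#' @export
generate_paired_studies <- function(config_a, config_b, shared_link = TRUE) {
  if (!setequal(config_a$variables, config_b$variables)) {
    stop("incompatible variable lists")
  }
  config_b$families <- config_a$families
  ds_a <- generate_study(config_a)
  if (shared_link) {
    config_b$links <- config_a$links
    set.seed(config_a$seed)
    calib_seed_a <- sample.int(2147483646L, 1)
    calib_a <- calibrate_links(config_a, calib_seed_a)
    ds_b <- generate_study(config_b, calibration = calib_a)
  } else {
    ds_b <- generate_study(config_b)
  }
  list(a = ds_a, b = ds_b)
}

#' Drop whole subject-days of sensing data at random
#'
#' Each subject-day is dropped independently with probability
#' `day_rate`; EMA responses are untouched.
#'
#' @param dataset a `study_dataset` or a long sensing table.
#' @param day_rate drop probability in \[0, 1\].
#' @param seed RNG seed.
#' @return Same type as `dataset` with sensor days removed.
#' @export
inject_missingness <- function(dataset, day_rate, seed = 1) {
  if (day_rate < 0 || day_rate > 1) stop("day_rate must be in [0, 1]")
  is_ds <- inherits(dataset, "study_dataset")
  sensor <- if (is_ds) dataset$sensor else as.data.table(dataset)
  if (day_rate > 0) {
    set.seed(seed)
    days <- unique(sensor[, .(subject, date)])
    days[, drop := runif(.N) < day_rate]
    sensor <- merge(sensor, days, by = c("subject", "date"))
    sensor <- sensor[drop == FALSE][, drop := NULL]
  }
  if (is_ds) {
    dataset$sensor <- sensor
    dataset
  } else {
    sensor
  }
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset '%s': %d subjects, %d sensor rows, %d EMA rows>\n",
              x$study_id, length(unique(x$sensor$subject)),
              nrow(x$sensor), nrow(x$ema)))
  invisible(x)
}
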