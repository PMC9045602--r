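#' Experiment configuration with the canonical analysis constants
#'
#' Bundles the two study configurations, the outcome items, the
#' hyperparameter grid and the analysis constants: significance level
#' 0.05, Benjamini-Hochberg FDR 0.25, 3-day trailing window, 19-hour
#' coverage rule, >= 30 EMA validation rule.
#'
#' @param config_a,config_b [study_config()]s for the two studies.
#' @param items outcome items to model.
#' @param grid hyperparameter configurations ([hyper_grid()]).
#' @param modes training modes.
#' @param shared_link share study A's links with study B.
#' @param alpha,fdr,window,min_coverage,min_ema analysis constants.
#' @param seed master seed.
#' @param out_dir optional directory for report artifacts.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(config_a = NULL, config_b = NULL,
                              items = c("sleep", "stress"),
                              grid = hyper_grid(),
                              modes = c("single", "combined"),
                              shared_link = TRUE,
                              alpha = 0.05, fdr = 0.25, window = 3,
                              min_coverage = 19, min_ema = 30, seed = 1,
                              out_dir = NULL) {
  if (is.null(config_a)) {
    config_a <- study_config("crosscheck", n_subjects = 61, n_days = 365,
                             seed = derive_seed(seed, 1L))
  }
  if (is.null(config_b)) {
    config_b <- study_config(
      "studentlife", n_subjects = 48, n_days = 70,
      seed = derive_seed(seed, 2L),
      shift = shift_spec(location = 20, scale = 1.4, missing_rate = 0.15,
                         schedule = list(type = "bernoulli", period = 2.5)),
      mappings = list(sleep = mapping_studentlife_sleep("sleep"),
                      stress = mapping_studentlife_stress("stress")),
      raw_derived = TRUE)
  }
  stopifnot(alpha > 0, fdr > 0, window >= 1, min_coverage > 0, min_ema > 0)
  structure(list(config_a = config_a, config_b = config_b, items = items,
                 grid = grid, modes = modes, shared_link = shared_link,
                 alpha = alpha, fdr = fdr, window = window,
                 min_coverage = min_coverage, min_ema = min_ema,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Harmonize one study dataset into aligned instances
#'
#' Normalizes the raw EMA responses through the study's item mappings,
#' computes day-level epoch features, applies the coverage rule (only to
#' raw-derived studies) and aligns every response with its
#' trailing-window features.
#'
#' @param dataset a `study_dataset` (or list with `sensor`, `ema`).
#' @param mappings item mappings; defaults to the dataset config's.
#' @param window trailing window (days).
#' @param min_coverage coverage threshold in hours.
#' @param raw_derived apply the coverage rule; defaults to the config
#'   flag.
#' @return Aligned instance table (see [build_aligned_instances()]).
#' @export
harmonize_study <- function(dataset, mappings = NULL, window = 3,
                            min_coverage = 19, raw_derived = NULL) {
  if (is.null(mappings)) mappings <- dataset$config$mappings
  if (is.null(raw_derived)) {
    raw_derived <- isTRUE(dataset$config$raw_derived)
  }
  ema <- normalize_ema(dataset$ema, mappings)
  days <- compute_day_features(dataset$sensor)
  if (raw_derived) {
    days <- filter_low_coverage_days(days, min_hours = min_coverage)
  }
  build_aligned_instances(days, ema, window = window)
}

config_fingerprint <- function(config) {
  json <- jsonlite::serializeJSON(config)
  v <- utf8ToInt(json)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

#' Run the full cross-study experiment
#'
#' Generates (or accepts) the paired studies, harmonizes them, runs the
#' LOSO grid per outcome item, computes the Proxy-A distance table, the
#' paired delta rows, the sensitivity summary, the PAD-MAE association
#' and the severity metrics, and - when `out_dir` is set - writes every
#' table as delimited text along with a JSON run manifest.  Idempotent
#' for a fixed configuration and seed.
#'
#' @param config an [experiment_config()].
#' @param datasets optional pre-generated list(a =, b =) of
#'   `study_dataset`s (bypasses generation).
#' @return list with `instances`, `predictions`, `pads`, `delta_rows`,
#'   `sensitivity`, `association`, `severity`, `manifest` (invisible).
#' @export
run_experiment <- function(config, datasets = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(datasets)) {
    datasets <- generate_paired_studies(config$config_a, config$config_b,
                                        shared_link = config$shared_link)
  }
  inst <- rbind(
    harmonize_study(datasets$a, window = config$window,
                    min_coverage = config$min_coverage),
    harmonize_study(datasets$b, window = config$window,
                    min_coverage = config$min_coverage))

  preds <- list(); pads <- list()
  for (it in config$items) {
    preds[[it]] <- run_loso_grid(inst, it, grid = config$grid,
                                 modes = config$modes, seed = config$seed,
                                 min_ema = config$min_ema)
    pads[[it]] <- pad_table(inst, it, ks = sort(unique(config$grid$k)),
                            modes = config$modes, seed = config$seed,
                            min_ema = config$min_ema)
  }
  preds <- rbindlist(preds)
  pads <- rbindlist(pads)

  delta <- paired_delta_rows(preds, pads)
  sens <- sensitivity_table(delta, alpha = config$alpha, fdr = config$fdr)
  assoc <- if ("dpad" %in% names(delta) &&
               sum(complete.cases(delta[, .(dmae, dpad)])) > 2) {
    # degenerate layouts (e.g. one configuration per subject) cannot
    # support the mixed model; report no association rather than abort
    tryCatch(pad_mae_association(delta), error = function(e) {
      message("PAD-MAE association skipped: ", conditionMessage(e))
      NULL
    })
  } else NULL

  sev <- rbindlist(lapply(config$items, function(it) {
    direction <- if (grepl("sleep", it)) "higher_better" else "higher_worse"
    p <- preds[item == it]
    p[, {
      m <- severity_metrics(.SD, direction = direction)
      as.list(m)
    }, by = .(item, mode, k, smote, learning_rate, n_trees, depth)]
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossgen")),
    seed = config$seed,
    config_hash = config_fingerprint(config),
    n_grid = nrow(config$grid),
    items = config$items, modes = config$modes,
    n_instances = nrow(inst), n_predictions = nrow(preds),
    alpha = config$alpha, fdr = config$fdr, window = config$window,
    min_coverage = config$min_coverage, min_ema = config$min_ema)

  out <- list(instances = inst, predictions = preds, pads = pads,
              delta_rows = delta, sensitivity = sens, association = assoc,
              severity = sev, manifest = manifest)
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  invisible(out)
}

#' Write experiment artifacts as delimited text plus a JSON manifest
#'
#' @param result output of [run_experiment()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(result$instances, file.path(dir, "instances.csv"))
  fwrite(result$predictions, file.path(dir, "predictions.csv"))
  fwrite(result$pads, file.path(dir, "pad.csv"))
  fwrite(result$delta_rows, file.path(dir, "delta_rows.csv"))
  fwrite(result$sensitivity$summary, file.path(dir, "sensitivity_summary.csv"))
  fwrite(result$sensitivity$per_config,
         file.path(dir, "sensitivity_per_config.csv"))
  fwrite(result$severity, file.path(dir, "severity_metrics.csv"))
  if (!is.null(result$association)) {
    fwrite(result$association$gee, file.path(dir, "association_gee.csv"))
    fwrite(result$association$lmm, file.path(dir, "association_lmm.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write / read a study dataset in the canonical delimited-text schema
#'
#' Two files per study: `sensing.csv` (subject, study, date, variable,
#' hour, value) and `ema.csv` (subject, study, date, item, raw_value).
#'
#' @param dataset a `study_dataset`.
#' @param dir target directory.
#' @return `dir` (write) or a list with `sensor` and `ema` (read).
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(dataset$sensor, file.path(dir, "sensing.csv"))
  fwrite(dataset$ema, file.path(dir, "ema.csv"))
  invisible(dir)
}

#' @param dir directory holding `sensing.csv` and `ema.csv`.
#' @rdname write_study_dataset
#' @export
read_study_dataset <- function(dir) {
  list(sensor = fread(file.path(dir, "sensing.csv")),
       ema = fread(file.path(dir, "ema.csv"),
                   colClasses = list(character = "raw_value")))
}
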