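#' Read an experiment configuration from structured text (JSON)
#'
#' The file mirrors [experiment_config()]: two study blocks (each a
#' [study_config()] in JSON form), the outcome items, an optional
#' reduced grid, and the analysis constants.  Omitted fields fall back
#' to the package defaults.
#'
#' @param path path to a JSON configuration file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_link <- function(l) {
    link_spec(weights = unlist(l$weights) %||% numeric(0),
              noise_sd = l$noise_sd %||% 0.8,
              form = l$form %||% "linear",
              grid = l$grid %||% 0:3,
              category_prior = l$category_prior %||%
                rep(1 / length(l$grid %||% 0:3), length(l$grid %||% 0:3)),
              intercept = l$intercept %||% 1.5)
  }
  parse_shift <- function(s) {
    if (is.null(s)) return(shift_spec())
    shift_spec(location = unlist(s$location) %||% 0,
               scale = unlist(s$scale) %||% 1,
               missing_rate = s$missing_rate %||% 0.1,
               schedule = s$schedule %||% list(type = "fixed",
                                               days = c(1, 3, 5),
                                               jitter = 0.1))
  }
  parse_study <- function(s, default_seed) {
    if (is.null(s)) return(NULL)
    links <- if (is.null(s$links)) default_links() else
      lapply(s$links, parse_link)
    mappings <- NULL
    if (!is.null(s$mappings)) {
      builders <- list(crosscheck = mapping_crosscheck,
                       studentlife_sleep = mapping_studentlife_sleep,
                       studentlife_stress = mapping_studentlife_stress)
      mappings <- lapply(setNames(names(s$mappings), names(s$mappings)),
                         function(it) builders[[s$mappings[[it]]]](it))
    }
    study_config(s$study_id, n_subjects = s$n_subjects, n_days = s$n_days,
                 links = links, shift = parse_shift(s$shift),
                 seed = s$seed %||% default_seed,
                 subject_sd = s$subject_sd %||% 0.35,
                 subject_intercept_sd = s$subject_intercept_sd %||% 0.3,
                 mappings = mappings,
                 raw_derived = isTRUE(s$raw_derived),
                 n_cal = s$n_cal %||% 1500)
  }
  seed <- raw$seed %||% 1
  grid <- if (is.null(raw$grid)) hyper_grid() else {
    g <- raw$grid
    k <- g$k %||% c(5, 10, 50, 100, 500, Inf)
    k[k == "all"] <- Inf
    hyper_grid(learning_rate = g$learning_rate %||% c(0.001, 0.01, 0.1, 1),
               n_trees = g$n_trees %||% c(20, 100, 1000),
               depth = g$depth %||% c(3, 7, 10),
               smote = g$smote %||% c(TRUE, FALSE),
               k = as.numeric(k))
  }
  experiment_config(
    config_a = parse_study(raw$study_a, derive_seed(seed, 1L)),
    config_b = parse_study(raw$study_b, derive_seed(seed, 2L)),
    items = raw$items %||% c("sleep", "stress"),
    grid = grid,
    modes = raw$modes %||% c("single", "combined"),
    shared_link = raw$shared_link %||% TRUE,
    alpha = raw$alpha %||% 0.05, fdr = raw$fdr %||% 0.25,
    window = raw$window %||% 3, min_coverage = raw$min_coverage %||% 19,
    min_ema = raw$min_ema %||% 30, seed = seed,
    out_dir = raw$out_dir)
}
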