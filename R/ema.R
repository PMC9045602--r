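#' Declare how a raw EMA item maps onto the common 0-3 severity scale
#'
#' Each study's ecological momentary assessment (EMA) items are answered
#' on their own raw scale.  For cross-study modeling every item is mapped
#' onto a common 0-3 scale with a consistent severity direction: for sleep
#' quality 0 is the poorest and 3 the best sleep; for stress 0 is the
#' least and 3 the most stressed.  The two categories at the severe end of
#' each scale (sleep 0-1, stress 2-3) define the binary "severe" label.
#'
#' @param item item name.
#' @param raw ordered vector of admissible raw values (numeric codes or
#'   category labels), ordered so that `normalized` is its image.
#' @param normalized numeric vector of the same length with values in
#'   \[0, 3\]; must be monotone in severity after the `raw` ordering.
#' @param direction `"higher_better"` (e.g. sleep quality) or
#'   `"higher_worse"` (e.g. stress); fixes which end of the normalized
#'   scale is severe.
#' @return An `ema_mapping` object.
#' @export
ema_mapping <- function(item, raw, normalized,
                        direction = c("higher_worse", "higher_better")) {
  direction <- match.arg(direction)
  if (length(raw) != length(normalized)) stop("raw/normalized length mismatch")
  if (any(normalized < 0 | normalized > 3)) {
    stop("normalized values must lie in [0, 3]")
  }
  grid <- sort(unique(normalized))
  severe <- severe_set(grid, direction)
  if (length(severe) != 2L) stop("severe set must contain exactly 2 categories")
  structure(list(item = item, raw = raw, normalized = normalized,
                 direction = direction, grid = grid, severe = severe),
            class = "ema_mapping")
}

# The two categories at the severe end of a normalized grid.
severe_set <- function(grid, direction) {
  grid <- sort(grid)
  if (direction == "higher_worse") tail(grid, 2L) else head(grid, 2L)
}

#' The ten EMA items administered in a CrossCheck-style study
#'
#' All ten items are answered on a native 0 (not at all) to 3 (extremely)
#' scale every Monday/Wednesday/Friday.
#'
#' @return Character vector of 10 item names.
#' @export
crosscheck_ema_items <- function() {
  c("calm", "social", "voices", "seeing_things", "stressed", "harm",
    "sleeping", "think", "depressed", "hopeful")
}

#' Built-in item mappings
#'
#' `mapping_crosscheck()` is the identity on the native 0-3 scale.
#' `mapping_studentlife_sleep()` maps the 4-category sleep-quality item
#' (1 = very good ... 4 = very bad) through `x -> 4 - x`, so higher
#' normalized values mean better sleep.  `mapping_studentlife_stress()`
#' reorders the five stress labels by severity and maps them affinely onto
#' \[0, 3\], snapped to the integer grid.
#'
#' @param item item name; `direction` is inferred for the two modeled
#'   symptoms (`"sleep*"` higher-is-better, otherwise higher-is-worse).
#' @return An [ema_mapping()].
#' @export
mapping_crosscheck <- function(item) {
  direction <- if (grepl("sleep", item)) "higher_better" else "higher_worse"
  ema_mapping(item, raw = 0:3, normalized = 0:3, direction = direction)
}

#' @rdname mapping_crosscheck
#' @export
mapping_studentlife_sleep <- function(item = "sleep") {
  # 1 "Very good" .. 4 "Very bad"  ->  3 .. 0
  ema_mapping(item, raw = 1:4, normalized = 4 - (1:4),
              direction = "higher_better")
}

#' @rdname mapping_crosscheck
#' @export
mapping_studentlife_stress <- function(item = "stress") {
  labels <- c("Feeling great", "Feeling good", "A little stressed",
              "Definitely stressed", "Stressed out")
  # unique severity-monotone order, then affine onto [0,3], rounded to grid
  ema_mapping(item, raw = labels, normalized = round(3 * (0:4) / 4),
              direction = "higher_worse")
}

#' Normalize raw EMA responses onto the common 0-3 scale
#'
#' @param ema data.table/data.frame with columns `subject`, `study`,
#'   `date`, `item`, `raw_value`.
#' @param mappings named list of [ema_mapping()] objects, one per item
#'   present in `ema`.
#' @return data.table with added columns `value` (normalized, in \[0,3\])
#'   and `severe` (0/1).
#' @export
normalize_ema <- function(ema, mappings) {
  ema <- as.data.table(ema)
  if (!all(ema$item %in% names(mappings))) {
    missing_items <- setdiff(unique(ema$item), names(mappings))
    stop("no mapping for item(s): ", paste(missing_items, collapse = ", "))
  }
  out <- vector("list", length(unique(ema$item)))
  for (it in unique(ema$item)) {
    map <- mappings[[it]]
    rows <- ema[item == it]
    idx <- match(as.character(rows$raw_value), as.character(map$raw))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf("raw value '%s' outside domain of item '%s' (subject %s)",
                   rows$raw_value[bad], it, rows$subject[bad]))
    }
    rows[, value := map$normalized[idx]]
    rows[, severe := label_severity(value, map)]
    out[[which(unique(ema$item) == it)]] <- rows
  }
  rbindlist(out)
}

#' Binary severe-symptom label
#'
#' A normalized value is severe when it falls in the two categories at the
#' severe end of the scale: values 0-1 for higher-is-better items (poor
#' sleep), values 2-3 for higher-is-worse items (high stress).
#'
#' @param value normalized value(s) in \[0, 3\].
#' @param mapping an [ema_mapping()] (only its direction is used).
#' @return Integer 0/1 vector.
#' @export
label_severity <- function(value, mapping) {
  stopifnot(all(value >= 0 & value <= 3))
  if (mapping$direction == "higher_better") {
    as.integer(value <= max(head(mapping$grid, 2L)))
  } else {
    as.integer(value >= min(tail(mapping$grid, 2L)))
  }
}

#' Subjects eligible as validation data
#'
#' A subject enters the leave-one-subject-out validation set for an
#' outcome item only with at least `min_ema` aligned responses for that
#' item; all subjects remain usable as training data regardless.
#'
#' @param instances aligned instance table (see
#'   [build_aligned_instances()]).
#' @param item outcome item; `NULL` uses all rows.
#' @param min_ema minimum responses (default 30).
#' @return Character vector of subject ids.
#' @export
select_validation_subjects <- function(instances, item = NULL, min_ema = 30) {
  dt <- as.data.table(instances)
  if (!is.null(item)) dt <- dt[dt$item == item]
  if (nrow(dt) == 0L) return(character(0))
  counts <- dt[, .N, by = subject]
  sort(as.character(counts[N >= min_ema]$subject))
}
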