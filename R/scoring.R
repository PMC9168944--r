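#' Linearly normalize a raw domain score onto the 0-100 best-health scale
#'
#' A raw score is mapped linearly between its achievable bounds so that 100
#' is the best condition and 0 the worst; scales where a higher raw value
#' means worse health are reflected. The mapping is affine and preserves
#' ordering, so variable properties are unchanged. Output is clamped to
#' \[0, 100\] only against floating-point round-off; a raw value outside its
#' bounds is an error, never silently clamped.
#'
#' @param raw Raw-scale value.
#' @param bounds Numeric length-2, achievable raw `c(min, max)`.
#' @param orientation `"higher-raw-is-better"` or `"higher-raw-is-worse"`.
#' @return Points on the 0-100 scale (100 = best health).
#' @examples
#' normalize_score(22, c(10, 50), "higher-raw-is-worse") # FAS total 22 -> 70
#' @export
normalize_score <- function(raw, bounds, orientation) {
  orientation <- match.arg(orientation,
                           c("higher-raw-is-better", "higher-raw-is-worse"))
  lo <- bounds[[1L]]; hi <- bounds[[2L]]
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  if (raw < lo - eps || raw > hi + eps)
    rc_range_error(sprintf("raw score %g outside achievable bounds [%g, %g]",
                           raw, lo, hi))
  x <- 100 * (raw - lo) / (hi - lo)
  if (orientation == "higher-raw-is-worse") x <- 100 - x
  min(100, max(0, x))
}

#' Score one functional domain of one response record
#'
#' Aggregates the answered member items under the instrument's scoring rule,
#' prorates over missing items, and normalizes onto the 0-100 best-health
#' scale. A domain is unscorable (`missing = TRUE`) when fewer than
#' `proration_floor` of its items are answered, or, for the grade-rescale
#' decision tree, when the answers do not resolve a grade. Impairment is a
#' normalized score strictly below the threshold (default 100: any departure
#' from full health counts as an unmet need).
#'
#' @param record A record validated with [validate_responses()].
#' @param definition The matching `rc_instrument`.
#' @param domain_id Domain to score.
#' @param proration_floor Minimum answered fraction for prorated scoring
#'   (default 0.5, the common PROM half-items convention).
#' @param impairment_threshold Normalized score below which the domain is
#'   flagged impaired (default 100).
#' @return One-row data frame: `respondent_id`, `timepoint`,
#'   `timepoint_index`, `instrument_id`, `domain_id`, `raw`, `normalized`,
#'   `n_answered`, `n_total`, `impaired`, `missing`.
#' @export
score_domain <- function(record, definition, domain_id,
                         proration_floor = 0.5, impairment_threshold = 100) {
  rule <- domain_rule(definition, domain_id)
  member_ids <- definition$domain_items[[domain_id]]
  n_total <- length(member_ids)
  codes <- record$answers[member_ids]           # absent items come back NA
  names(codes) <- member_ids
  answered <- !is.na(codes)
  n_answered <- sum(answered)

  # Domain orientation: when every member item points the same way, use it
  # directly (covers e.g. a best-high rating inside a worst-high instrument).
  # With mixed item orientations, reflect the minority onto the instrument's
  # direction across each item's own level range.
  orients <- vapply(definition$items[member_ids], function(it)
    item_orientation(definition, it), "")
  if (length(unique(orients)) == 1L) {
    orientation <- orients[[1L]]
  } else {
    orientation <- definition$orientation
    for (id in member_ids[answered]) {
      it <- definition$items[[id]]
      if (!identical(item_orientation(definition, it), orientation))
        codes[[id]] <- min(it$codes) + max(it$codes) - codes[[id]]
    }
  }

  raw <- NA_real_; normalized <- NA_real_; missing <- TRUE
  bounds <- definition$raw_bounds[[domain_id]]

  if (rule == "grade-rescale") {
    g <- resolve_grade(codes, definition)
    if (!is.na(g)) { raw <- g; missing <- FALSE }
  } else if (n_total > 0L && n_answered / n_total >= proration_floor &&
             n_answered > 0L) {
    m <- mean(codes[answered])
    raw <- switch(rule,
      "mean-rescale" = m,
      "sum-rescale" = m * n_total,              # prorated sum
      "per-dimension-rescale" = m,
      "passthrough-0-100" = m)
    missing <- FALSE
  }
  if (!missing) normalized <- normalize_score(raw, bounds, orientation)
  data.frame(
    respondent_id = record$respondent_id, timepoint = record$timepoint,
    timepoint_index = record$timepoint_index,
    instrument_id = definition$instrument_id, domain_id = domain_id,
    raw = raw, normalized = normalized,
    n_answered = n_answered, n_total = n_total,
    impaired = if (missing) NA else normalized < impairment_threshold,
    missing = missing, stringsAsFactors = FALSE)
}

# Yes/no decision tree, severest question first: the first "yes" fixes the
# grade (5 down to 1); all "no" resolves to grade 0. A missing answer before
# any "yes" leaves the grade unresolved (fail-safe: missing, never a guess).
resolve_grade <- function(codes, definition) {
  order <- definition$grade_order
  grades <- seq.int(length(order), 1L)          # 5,4,3,2,1 for five items
  for (k in seq_along(order)) {
    a <- codes[[order[[k]]]]
    if (is.na(a)) return(NA_real_)
    if (a == 1L) return(as.numeric(grades[[k]]))
  }
  0
}

#' Score every domain of an instrument
#'
#' @inheritParams score_domain
#' @param validate Validate the record first (default `TRUE`).
#' @return Data frame with one row per domain, in definition order; columns
#'   as in [score_domain()].
#' @export
score_instrument <- function(record, definition, proration_floor = 0.5,
                             impairment_threshold = 100, validate = TRUE) {
  if (validate) validate_responses(record, definition)
  do.call(rbind, lapply(definition$domains$domain_id, function(d)
    score_domain(record, definition, d, proration_floor = proration_floor,
                 impairment_threshold = impairment_threshold)))
}

#' Score a set of response records against a catalog
#'
#' The workhorse of the pipeline: validates and scores every record, one row
#' per (respondent, timepoint, instrument, domain).
#'
#' @param records List of `rc_record`.
#' @param catalog An `rc_catalog` from [load_instrument_catalog()].
#' @inheritParams score_domain
#' @param impairment_thresholds Optional named numeric vector of per-domain
#'   overrides, names `"instrument_id:domain_id"`.
#' @return Data frame of domain scores.
#' @export
score_records <- function(records, catalog, proration_floor = 0.5,
                          impairment_thresholds = NULL) {
  out <- lapply(records, function(r) {
    def <- catalog_instrument(catalog, r$instrument_id)
    validate_responses(r, def)
    do.call(rbind, lapply(def$domains$domain_id, function(d) {
      thr <- impairment_thresholds[[paste0(r$instrument_id, ":", d)]] %||% 100
      score_domain(r, def, d, proration_floor = proration_floor,
                   impairment_threshold = thr)
    }))
  })
  do.call(rbind, out)
}

SCORE_COLUMNS <- c("respondent_id", "timepoint", "instrument_id", "domain_id",
                   "raw", "normalized", "n_answered", "n_total",
                   "impaired", "missing")

#' Write domain scores to CSV
#'
#' Column layout:
#' `respondent_id,timepoint,instrument_id,domain_id,raw,normalized,n_answered,n_total,impaired,missing`.
#' @param scores Data frame from [score_records()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores[, SCORE_COLUMNS], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write domain scores to JSON
#' @inheritParams write_scores_csv
#' @return `path`, invisibly.
#' @export
write_scores_json <- function(scores, path) {
  jsonlite::write_json(scores[, SCORE_COLUMNS], path, auto_unbox = FALSE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}
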