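# Shared fixtures: catalog/mapping are loaded once per test run.

the_catalog <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_instrument_catalog()
    cached
  }
})

the_mapping <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_area_mapping(catalog = the_catalog())
    cached
  }
})

item_best_code <- function(def, item) {
  orient <- item$orientation
  if (is.null(orient)) orient <- def$orientation
  if (orient == "higher-raw-is-better") max(item$codes) else min(item$codes)
}

item_worst_code <- function(def, item) {
  orient <- item$orientation
  if (is.null(orient)) orient <- def$orientation
  if (orient == "higher-raw-is-better") min(item$codes) else max(item$codes)
}

all_best_record <- function(def, respondent = "r1", timepoint = "t1",
                            tp_index = 1L) {
  codes <- vapply(def$items, function(it) item_best_code(def, it), 0L)
  if (def$scoring_rule == "grade-rescale")
    codes[] <- 0L                       # best = "no" to every tree question
  response_record(respondent, timepoint, def$instrument_id,
                  stats::setNames(codes, names(def$items)),
                  timepoint_index = tp_index)
}

all_worst_record <- function(def, respondent = "r1", timepoint = "t1",
                             tp_index = 1L) {
  codes <- vapply(def$items, function(it) item_worst_code(def, it), 0L)
  if (def$scoring_rule == "grade-rescale")
    codes[] <- 1L                       # "yes" at the severest question
  response_record(respondent, timepoint, def$instrument_id,
                  stats::setNames(codes, names(def$items)),
                  timepoint_index = tp_index)
}

random_record <- function(def, respondent = "r1", timepoint = "t1",
                          tp_index = 1L) {
  codes <- vapply(def$items, function(it)
    it$codes[sample.int(length(it$codes), 1L)], 0L)
  response_record(respondent, timepoint, def$instrument_id,
                  stats::setNames(codes, names(def$items)),
                  timepoint_index = tp_index)
}

# Random scored cohort: one snapshot per respondent built through the real
# pipeline on random records.
random_snapshot <- function(respondent = "r1", timepoint = "t1",
                            tp_index = 1L) {
  catalog <- the_catalog()
  recs <- lapply(catalog, random_record, respondent = respondent,
                 timepoint = timepoint, tp_index = tp_index)
  scores <- score_records(unname(recs), catalog)
  assemble_compass(scores, the_mapping())
}
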