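#' Construct a response record
#'
#' One respondent's item-level answers for one instrument at one time point.
#' Unanswered items are carried as explicit `NA` (never 0 or blank-as-0:
#' 0 is a valid HADS/EAT-10 code).
#'
#' @param respondent_id Opaque respondent identifier.
#' @param timepoint Time-point label (e.g. `"3-month"`).
#' @param instrument_id Instrument the answers belong to.
#' @param answers Named integer vector, `item_id -> response code`, `NA` for
#'   explicitly missing.
#' @param timepoint_index Ordinal position of the time point (1 = earliest).
#' @param completed_on Optional completion `Date`.
#' @return A list of class `rc_record`.
#' @export
response_record <- function(respondent_id, timepoint, instrument_id, answers,
                            timepoint_index = 1L, completed_on = NULL) {
  if (length(answers) && is.null(names(answers)))
    rc_validation_error("answers must be named by item id")
  structure(list(
    respondent_id = as.character(respondent_id),
    timepoint = as.character(timepoint),
    timepoint_index = as.integer(timepoint_index),
    instrument_id = as.character(instrument_id),
    answers = stats::setNames(as.integer(answers), names(answers)),
    completed_on = completed_on
  ), class = "rc_record")
}

#' Validate a response record against its instrument definition
#'
#' Checks every answered item id against the instrument's item bank and every
#' response code against the item's admissible levels. Explicit-missing
#' answers pass through unchanged.
#'
#' @param record An [response_record()].
#' @param definition The matching `rc_instrument`.
#' @return The record, unchanged, invisibly classed as validated.
#' @export
validate_responses <- function(record, definition) {
  stopifnot(inherits(record, "rc_record"), inherits(definition, "rc_instrument"))
  if (record$instrument_id != definition$instrument_id)
    rc_validation_error(sprintf(
      "record is for instrument '%s', definition is '%s'",
      record$instrument_id, definition$instrument_id))
  ids <- names(record$answers)
  if (anyDuplicated(ids))
    rc_validation_error(sprintf(
      "respondent '%s': duplicate entries for item '%s'",
      record$respondent_id, ids[duplicated(ids)][1L]))
  unknown <- setdiff(ids, names(definition$items))
  if (length(unknown))
    rc_validation_error(sprintf(
      "respondent '%s': unknown item id '%s' for instrument '%s'",
      record$respondent_id, unknown[1L], definition$instrument_id))
  for (id in ids) {
    code <- record$answers[[id]]
    if (is.na(code)) next
    adm <- definition$items[[id]]$codes
    if (!(code %in% adm))
      rc_range_error(sprintf(
        "respondent '%s', item '%s': code %d not admissible (levels: %s)",
        record$respondent_id, id, code,
        paste(range(adm), collapse = "-")))
  }
  record$validated <- TRUE
  invisible(record)
}

# ---------------------------------------------------------------------------
# Long-format CSV / JSON interchange:
#   respondent_id,timepoint,instrument_id,item_id,value   (blank value = NA)

#' Write response records to long-format CSV
#'
#' @param records List of `rc_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(records, path) {
  rows <- lapply(records, function(r) data.frame(
    respondent_id = r$respondent_id, timepoint = r$timepoint,
    instrument_id = r$instrument_id,
    item_id = names(r$answers),
    value = ifelse(is.na(r$answers), "", as.character(r$answers)),
    stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read response records from long-format CSV
#'
#' Expects the header `respondent_id,timepoint,instrument_id,item_id,value`;
#' a blank `value` is an explicit-missing answer. One record is assembled per
#' (respondent, timepoint, instrument) group.
#'
#' @param path CSV file.
#' @param timepoints Optional named integer vector mapping time-point labels
#'   to ordinal indices; defaults to order of first appearance in the file.
#' @return List of `rc_record`.
#' @export
read_responses_csv <- function(path, timepoints = NULL) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8"),
    error = function(e) rc_validation_error(
      sprintf("file '%s': cannot read CSV (%s)", path, conditionMessage(e))))
  need <- c("respondent_id", "timepoint", "instrument_id", "item_id", "value")
  if (!all(need %in% names(df)))
    rc_validation_error(sprintf(
      "file '%s': CSV header must contain %s", path,
      paste(need, collapse = ",")))
  records_from_long(df, timepoints)
}

records_from_long <- function(df, timepoints = NULL) {
  if (is.null(timepoints)) {
    labs <- unique(df$timepoint)
    timepoints <- stats::setNames(seq_along(labs), labs)
  }
  unknown_tp <- setdiff(unique(df$timepoint), names(timepoints))
  if (length(unknown_tp))
    rc_validation_error(sprintf("unknown time point label '%s'", unknown_tp[1L]))
  val <- trimws(df$value)
  bad <- which(val != "" & is.na(suppressWarnings(as.integer(val))))
  if (length(bad))
    rc_validation_error(sprintf(
      "row %d (respondent '%s', item '%s'): non-integer value '%s'",
      bad[1L] + 1L, df$respondent_id[bad[1L]], df$item_id[bad[1L]],
      df$value[bad[1L]]))
  df$code <- ifelse(val == "", NA_integer_, suppressWarnings(as.integer(val)))
  key <- paste(df$respondent_id, df$timepoint, df$instrument_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    response_record(
      respondent_id = g$respondent_id[1L], timepoint = g$timepoint[1L],
      instrument_id = g$instrument_id[1L],
      answers = stats::setNames(g$code, g$item_id),
      timepoint_index = timepoints[[g$timepoint[1L]]])
  }) |> unname()
}

#' Read response records from the equivalent JSON document
#'
#' The JSON form is an array of objects with the same five fields as the CSV
#' columns (a `null` or absent `value` is explicit-missing).
#' @inheritParams read_responses_csv
#' @return List of `rc_record`.
#' @export
read_responses_json <- function(path, timepoints = NULL) {
  doc <- jsonlite::read_json(path)
  df <- do.call(rbind, lapply(doc, function(r) data.frame(
    respondent_id = as.character(r$respondent_id),
    timepoint = as.character(r$timepoint),
    instrument_id = as.character(r$instrument_id),
    item_id = as.character(r$item_id),
    value = if (is.null(r$value)) "" else as.character(r$value),
    stringsAsFactors = FALSE)))
  if (is.null(df)) rc_validation_error(sprintf("file '%s': empty document", path))
  records_from_long(df, timepoints)
}
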