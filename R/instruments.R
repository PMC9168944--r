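#' Construct an item definition
#'
#' An item is one ordinal question: an identifier, a display prompt, the
#' ordered set of admissible integer response codes with labels, and the
#' domain it belongs to. Compact 0-100 rating items can be given as a
#' `levels_range` instead of enumerating 101 levels.
#'
#' @param item_id Unique (within the instrument) item identifier.
#' @param domain_id Identifier of the owning domain.
#' @param codes Strictly increasing integer vector of admissible response
#'   codes (at least 2).
#' @param labels Character vector of level labels, recycled from codes when
#'   omitted.
#' @param prompt Display prompt. Placeholder text by default: questionnaire
#'   wording is licensed and is deliberately not reproduced.
#' @param orientation Optional per-item override, `"higher-raw-is-better"` or
#'   `"higher-raw-is-worse"`; defaults to the instrument's orientation.
#' @return A list of class `rc_item`.
#' @export
item_definition <- function(item_id, domain_id, codes, labels = NULL,
                            prompt = NULL, orientation = NULL) {
  codes <- as.integer(codes)
  if (length(codes) < 2L)
    rc_validation_error(sprintf("item '%s': needs >= 2 levels", item_id))
  if (any(diff(codes) <= 0L))
    rc_validation_error(sprintf(
      "item '%s': level codes must be strictly increasing", item_id))
  if (!is.null(orientation))
    orientation <- match.arg(orientation,
                             c("higher-raw-is-better", "higher-raw-is-worse"))
  structure(list(
    item_id = as.character(item_id),
    prompt = prompt %||% paste0("Item ", item_id),
    domain_id = as.character(domain_id),
    codes = codes,
    labels = as.character(labels %||% paste0("level ", codes)),
    orientation = orientation
  ), class = "rc_item")
}

SCORING_RULES <- c("mean-rescale", "sum-rescale", "grade-rescale",
                   "per-dimension-rescale", "passthrough-0-100")

#' Construct an instrument definition
#'
#' Declarative description of one patient-reported outcome measure: its item
#' bank, the partition of items into functional domains, the scoring rule
#' that aggregates item codes to a raw domain score, and the orientation that
#' fixes which pole of the raw scale is good health. Enforced invariants:
#' unique item ids, every item in exactly one declared domain, every domain
#' non-empty, achievable raw bounds with min < max.
#'
#' @param instrument_id Short identifier (e.g. `"fas"`).
#' @param name Display name.
#' @param items List of [item_definition()] objects.
#' @param domains Data frame with columns `domain_id`, `name` and optionally
#'   `scoring_rule` (per-domain override of the instrument rule).
#' @param scoring_rule Instrument-level rule, one of
#'   `r paste0('\x60', SCORING_RULES, '\x60', collapse = ", ")`.
#' @param orientation `"higher-raw-is-better"` or `"higher-raw-is-worse"`
#'   (instrument default; items may override).
#' @param grade_order For `grade-rescale` instruments: item ids in
#'   severest-first decision-tree order.
#' @return A list of class `rc_instrument`, with per-domain `raw_bounds`
#'   derived from the rule and the item level sets.
#' @export
instrument_definition <- function(instrument_id, name, items, domains,
                                  scoring_rule, orientation,
                                  grade_order = NULL) {
  scoring_rule <- match.arg(scoring_rule, SCORING_RULES)
  orientation <- match.arg(orientation,
                           c("higher-raw-is-better", "higher-raw-is-worse"))
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids))
    rc_validation_error(sprintf("instrument '%s': duplicate item id '%s'",
                                instrument_id, ids[duplicated(ids)][1L]))
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  if (!all(c("domain_id", "name") %in% names(domains)))
    rc_config_error(sprintf(
      "instrument '%s': domains need 'domain_id' and 'name' fields",
      instrument_id))
  if (anyDuplicated(domains$domain_id))
    rc_validation_error(sprintf("instrument '%s': duplicate domain id",
                                instrument_id))
  if (is.null(domains$scoring_rule)) domains$scoring_rule <- NA_character_
  domains$scoring_rule <- ifelse(is.na(domains$scoring_rule), scoring_rule,
                                 domains$scoring_rule)
  bad_rule <- setdiff(unique(domains$scoring_rule), SCORING_RULES)
  if (length(bad_rule))
    rc_config_error(sprintf("instrument '%s': unknown scoring rule '%s'",
                            instrument_id, bad_rule[1L]))

  item_domain <- vapply(items, `[[`, "", "domain_id")
  unknown <- setdiff(item_domain, domains$domain_id)
  if (length(unknown))
    rc_validation_error(sprintf(
      "instrument '%s': item assigned to undeclared domain '%s'",
      instrument_id, unknown[1L]))
  empty <- setdiff(domains$domain_id, item_domain)
  if (length(empty))
    rc_validation_error(sprintf("instrument '%s': domain '%s' has no items",
                                instrument_id, empty[1L]))

  names(items) <- ids
  domain_items <- split(ids, factor(item_domain, levels = domains$domain_id))

  def <- structure(list(
    instrument_id = as.character(instrument_id),
    name = as.character(name),
    orientation = orientation,
    scoring_rule = scoring_rule,
    domains = domains,
    items = items,
    domain_items = domain_items,
    grade_order = grade_order
  ), class = "rc_instrument")
  def$raw_bounds <- lapply(stats::setNames(domains$domain_id, domains$domain_id),
                           function(d) derive_raw_bounds(def, d))
  for (d in domains$domain_id) {
    b <- def$raw_bounds[[d]]
    if (!(b[1L] < b[2L]))
      rc_validation_error(sprintf(
        "instrument '%s': domain '%s' raw bounds are degenerate",
        instrument_id, d))
  }
  if (scoring_rule == "grade-rescale") {
    go <- grade_order %||% unname(unlist(domain_items))
    if (!setequal(go, ids))
      rc_config_error(sprintf(
        "instrument '%s': grade_order must list every item exactly once",
        instrument_id))
    def$grade_order <- go
  }
  def
}

# Achievable raw min/max for one domain under its scoring rule.
derive_raw_bounds <- function(def, domain_id) {
  rule <- domain_rule(def, domain_id)
  its <- def$items[def$domain_items[[domain_id]]]
  lo <- vapply(its, function(i) min(i$codes), 0)
  hi <- vapply(its, function(i) max(i$codes), 0)
  switch(rule,
    "mean-rescale" = c(mean(lo), mean(hi)),
    "sum-rescale" = c(sum(lo), sum(hi)),
    "grade-rescale" = c(0, 5),
    "per-dimension-rescale" = {
      if (length(its) != 1L)
        rc_config_error(sprintf(
          "domain '%s': per-dimension-rescale requires exactly one item",
          domain_id))
      c(lo, hi)
    },
    "passthrough-0-100" = {
      if (length(its) != 1L)
        rc_config_error(sprintf(
          "domain '%s': passthrough-0-100 requires exactly one item",
          domain_id))
      c(lo, hi)
    })
}

domain_rule <- function(def, domain_id) {
  i <- match(domain_id, def$domains$domain_id)
  if (is.na(i))
    rc_validation_error(sprintf("instrument '%s' has no domain '%s'",
                                def$instrument_id, domain_id))
  def$domains$scoring_rule[i]
}

item_orientation <- function(def, item) {
  item$orientation %||% def$orientation
}

#' @export
print.rc_instrument <- function(x, ...) {
  cat(sprintf("<instrument %s: %s>\n", x$instrument_id, x$name))
  cat(sprintf("  %d items, %d domains, rule %s, %s\n",
              length(x$items), nrow(x$domains), x$scoring_rule, x$orientation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON document loading

parse_instrument_document <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) rc_config_error(sprintf(
      "file '%s': not parseable as JSON (%s)", path, conditionMessage(e))))
  for (f in c("instrument_id", "name", "orientation", "scoring_rule",
              "domains", "items")) {
    if (is.null(doc[[f]]))
      rc_config_error(sprintf(
        "file '%s': missing required field '%s'", path, f))
  }
  items <- lapply(doc$items, function(it) {
    if (is.null(it$item_id))
      rc_config_error(sprintf("file '%s': item without 'item_id'", path))
    if (is.null(it$levels) && is.null(it$levels_range))
      rc_config_error(sprintf(
        "file '%s', item '%s': field 'levels' (or 'levels_range') is required",
        path, it$item_id))
    if (!is.null(it$levels_range)) {
      codes <- seq.int(it$levels_range[[1L]], it$levels_range[[2L]])
      labels <- as.character(codes)
    } else {
      codes <- vapply(it$levels, function(l) as.integer(l$code), 0L)
      labels <- vapply(it$levels, function(l) as.character(l$label %||% l$code), "")
    }
    tryCatch(
      item_definition(it$item_id, it$domain_id, codes, labels,
                      prompt = it$prompt, orientation = it$orientation),
      error = function(e) rc_config_error(sprintf(
        "file '%s', item '%s': %s", path, it$item_id, conditionMessage(e))))
  })
  domains <- do.call(rbind, lapply(doc$domains, function(d) data.frame(
    domain_id = d$domain_id, name = d$name,
    scoring_rule = d$scoring_rule %||% NA_character_,
    stringsAsFactors = FALSE)))
  grade_order <- NULL
  for (d in doc$domains)
    if (!is.null(d$grade_order)) grade_order <- unlist(d$grade_order)
  tryCatch(
    instrument_definition(doc$instrument_id, doc$name, items, domains,
                          doc$scoring_rule, doc$orientation,
                          grade_order = grade_order),
    rc_config_error = function(e) stop(e),
    error = function(e) rc_config_error(
      sprintf("file '%s': %s", path, conditionMessage(e))))
}

#' Load a catalog of instrument definitions
#'
#' Reads one JSON document per instrument, validates it, and returns a named
#' catalog. Duplicate instrument ids across files are rejected.
#'
#' @param files Character vector of JSON file paths. Defaults to the packaged
#'   six-instrument set (SIS 3.0, SIS+ additional questions, HADS, FAS,
#'   smRSq, EQ-5D-3L, EAT-10).
#' @return Named list of `rc_instrument`, class `rc_catalog`.
#' @examples
#' cat <- load_instrument_catalog()
#' names(cat)
#' @export
load_instrument_catalog <- function(files = default_instrument_files()) {
  defs <- lapply(files, parse_instrument_document)
  ids <- vapply(defs, `[[`, "", "instrument_id")
  if (anyDuplicated(ids))
    rc_abort(sprintf("duplicate instrument id '%s' across definition files",
                     ids[duplicated(ids)][1L]),
             class = "rc_conflict_error")
  structure(stats::setNames(defs, ids), class = "rc_catalog")
}

#' @export
`[.rc_catalog` <- function(x, i) {
  structure(NextMethod(), class = "rc_catalog")
}

#' Paths of the packaged default instrument definitions
#' @return Character vector of JSON file paths shipped with the package.
#' @export
default_instrument_files <- function() {
  dir <- system.file("extdata", "instruments", package = "rehabcompass")
  f <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  f[order(f, method = "radix")]   # byte order: stable across locales
}

catalog_instrument <- function(catalog, instrument_id) {
  def <- catalog[[instrument_id]]
  if (is.null(def))
    rc_validation_error(sprintf("catalog has no instrument '%s'",
                                instrument_id))
  def
}
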