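#' Triage color scale
#'
#' Scores are triaged on a general scale: worst health 0-30 in red, best
#' health 70-100 in green, values in between in orange; unscorable domains
#' render in a neutral color. Boundary convention: red = \[0, 30\],
#' orange = (30, 70), green = \[70, 100\] (the printed ranges are closed).
#'
#' @param red_upper Upper bound of the red band (default 30).
#' @param green_lower Lower bound of the green band (default 70).
#' @return List of class `rc_color_scale`.
#' @export
color_scale <- function(red_upper = 30, green_lower = 70) {
  if (!(0 <= red_upper && red_upper < green_lower && green_lower <= 100))
    rc_config_error("color scale requires 0 <= red bound < green bound <= 100")
  structure(list(red_upper = red_upper, green_lower = green_lower,
                 bands = c("red", "orange", "green")),
            class = "rc_color_scale")
}

#' Assign a score to its color band
#'
#' @param score Points on the 0-100 scale (vectorized); `NA` maps to
#'   `"missing"`.
#' @param scale A [color_scale()].
#' @return Character vector of band labels.
#' @examples
#' band(c(0, 30, 50, 70, 100))
#' @export
band <- function(score, scale = color_scale()) {
  if (any(score < 0 | score > 100, na.rm = TRUE))
    rc_range_error("score outside [0, 100]")
  out <- ifelse(is.na(score), "missing",
         ifelse(score <= scale$red_upper, "red",
         ifelse(score < scale$green_lower, "orange", "green")))
  as.character(out)
}

#' Load a seven-area mapping
#'
#' The mapping assigns scored (instrument, domain) pairs to the seven
#' functional areas commonly affected after stroke — life, cognition,
#' emotion, fatigue, sexuality and continence, sensory function, motor
#' function — in the angular order the compass draws them. It is data, not
#' code: the packaged default is a reconstruction and deployments may
#' replace it.
#'
#' @param path JSON mapping document; defaults to the packaged mapping.
#' @param catalog Optional `rc_catalog`; when given, every member domain is
#'   checked to exist.
#' @return List of class `rc_area_mapping`: ordered `areas` data frame and a
#'   `members` data frame (`area_id`, `instrument_id`, `domain_id`).
#' @export
load_area_mapping <- function(path = default_mapping_file(), catalog = NULL) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$areas))
    rc_config_error(sprintf("file '%s': missing 'areas'", path))
  areas <- do.call(rbind, lapply(doc$areas, function(a) data.frame(
    area_id = a$area_id, name = a$name, stringsAsFactors = FALSE)))
  members <- do.call(rbind, lapply(doc$areas, function(a)
    do.call(rbind, lapply(a$members, function(m) data.frame(
      area_id = a$area_id, instrument_id = m[[1L]], domain_id = m[[2L]],
      stringsAsFactors = FALSE)))))
  area_mapping(areas, members, catalog = catalog)
}

REQUIRED_AREAS <- c("life", "cognition", "emotion", "fatigue",
                    "sexuality_continence", "sensory", "motor")

#' Construct an area mapping from data frames
#' @param areas Data frame `area_id`, `name`, in angular order.
#' @param members Data frame `area_id`, `instrument_id`, `domain_id`.
#' @param catalog Optional catalog for existence checks.
#' @return `rc_area_mapping`.
#' @export
area_mapping <- function(areas, members, catalog = NULL) {
  if (nrow(areas) != 7L || !setequal(areas$area_id, REQUIRED_AREAS))
    rc_config_error(sprintf(
      "mapping must have exactly the 7 areas {%s}",
      paste(REQUIRED_AREAS, collapse = ", ")))
  key <- paste(members$instrument_id, members$domain_id, sep = ":")
  if (anyDuplicated(key))
    rc_config_error(sprintf("domain '%s' mapped to more than one area",
                            key[duplicated(key)][1L]))
  if (!all(members$area_id %in% areas$area_id))
    rc_config_error("mapping member references an undeclared area")
  if (!is.null(catalog)) {
    for (i in seq_len(nrow(members))) {
      def <- catalog_instrument(catalog, members$instrument_id[i])
      if (!(members$domain_id[i] %in% def$domains$domain_id))
        rc_config_error(sprintf(
          "mapping member %s:%s not found in catalog",
          members$instrument_id[i], members$domain_id[i]))
    }
  }
  structure(list(areas = areas, members = members),
            class = "rc_area_mapping")
}

#' Path of the packaged default area-mapping document
#' @return File path.
#' @export
default_mapping_file <- function() {
  system.file("extdata", "mapping", "default_areas.json",
              package = "rehabcompass")
}

#' Flag a scored domain as impaired
#'
#' A normalized value below 100 is an unmet rehabilitation need; the
#' threshold can be lowered per deployment. Missingness must be handled by
#' the caller: an unscorable domain has no impairment status.
#'
#' @param score One-row domain-score data frame (or a list with `normalized`
#'   and `missing`).
#' @param threshold Impairment threshold (default 100; impaired iff
#'   normalized < threshold).
#' @return `TRUE` or `FALSE`.
#' @export
flag_impairment <- function(score, threshold = 100) {
  if (isTRUE(as.logical(score$missing)) || is.na(score$normalized))
    rc_validation_error("cannot flag impairment on a missing domain score")
  score$normalized < threshold
}

#' Assemble the seven-area compass snapshot
#'
#' Groups one respondent's domain scores at one time point into the seven
#' functional areas. Each area is colored by the arithmetic mean of its
#' non-missing member domains (equal weights) and carries an inner-edge
#' marker colored by the lowest member value, so a single severely disturbed
#' function is not averaged away. Areas whose members are all missing render
#' neutral.
#'
#' @param domain_scores Data frame of scores (one respondent, one time
#'   point) from [score_records()].
#' @param mapping An `rc_area_mapping`.
#' @param scale A [color_scale()].
#' @return List of class `rc_snapshot`: `respondent_id`, `timepoint`,
#'   `timepoint_index`, `areas` data frame (`area_id`, `area_score`,
#'   `min_score`, `area_band`, `min_band`, `n_members`, `n_scored`,
#'   `missing`) and `domains` bar data (`area_id`, `instrument_id`,
#'   `domain_id`, `normalized`, `band`, `impaired`, `missing`).
#' @export
assemble_compass <- function(domain_scores, mapping, scale = color_scale()) {
  stopifnot(inherits(mapping, "rc_area_mapping"))
  if (length(unique(domain_scores$respondent_id)) != 1L ||
      length(unique(domain_scores$timepoint)) != 1L)
    rc_validation_error(
      "assemble_compass expects scores of exactly one respondent and time point")
  key <- function(i, d) paste(i, d, sep = ":")
  have <- key(domain_scores$instrument_id, domain_scores$domain_id)
  want <- key(mapping$members$instrument_id, mapping$members$domain_id)
  absent <- setdiff(want, have)
  if (length(absent))
    rc_validation_error(sprintf(
      "mapped domain '%s' absent from input (score it or mark it missing)",
      absent[1L]))

  idx <- match(want, have)
  domains <- data.frame(
    area_id = mapping$members$area_id,
    instrument_id = mapping$members$instrument_id,
    domain_id = mapping$members$domain_id,
    normalized = domain_scores$normalized[idx],
    impaired = domain_scores$impaired[idx],
    missing = domain_scores$missing[idx],
    stringsAsFactors = FALSE)
  domains$band <- band(ifelse(domains$missing, NA, domains$normalized), scale)

  grp <- factor(domains$area_id, levels = mapping$areas$area_id)
  ok <- !domains$missing
  n_scored <- as.integer(table(grp[ok]))
  sums <- as.numeric(tapply(domains$normalized[ok], grp[ok], sum,
                            default = NA_real_))
  mins <- as.numeric(tapply(domains$normalized[ok], grp[ok], min,
                            default = NA_real_))
  area_score <- sums / ifelse(n_scored > 0L, n_scored, NA_integer_)
  areas <- data.frame(
    area_id = mapping$areas$area_id, name = mapping$areas$name,
    area_score = area_score, min_score = mins,
    area_band = band(area_score, scale), min_band = band(mins, scale),
    n_members = as.integer(table(grp)), n_scored = n_scored,
    missing = n_scored == 0L, stringsAsFactors = FALSE)

  structure(list(
    respondent_id = domain_scores$respondent_id[1L],
    timepoint = domain_scores$timepoint[1L],
    timepoint_index = domain_scores$timepoint_index[1L] %||% NA_integer_,
    areas = areas, domains = domains, scale = scale,
    mapping_signature = paste(want, collapse = ";")
  ), class = "rc_snapshot")
}

#' @export
print.rc_snapshot <- function(x, ...) {
  cat(sprintf("<compass snapshot: respondent %s @ %s>\n",
              x$respondent_id, x$timepoint))
  print(x$areas[, c("area_id", "area_score", "min_score",
                    "area_band", "min_band")], row.names = FALSE)
  invisible(x)
}

#' Compare two compass snapshots over time
#'
#' Longitudinal follow-up is read directly off color changes: the delta
#' carries, per domain and per area, the signed score change
#' (later - earlier) and the band transition (e.g. `"red->green"`). Domains
#' missing at either end are flagged (`newly_missing` / `newly_scored`)
#' rather than differenced.
#'
#' @param earlier,later `rc_snapshot`s of the same respondent under the same
#'   mapping, with `earlier` at the earlier time point.
#' @return List of class `rc_delta` with `domains` and `areas` data frames.
#' @export
compare_snapshots <- function(earlier, later) {
  stopifnot(inherits(earlier, "rc_snapshot"), inherits(later, "rc_snapshot"))
  if (earlier$respondent_id != later$respondent_id)
    rc_validation_error("snapshots belong to different respondents")
  if (!identical(earlier$mapping_signature, later$mapping_signature))
    rc_validation_error("snapshots were assembled under different mappings")

  diff_frame <- function(e, l, id_cols, score_col, band_col, miss_col) {
    was <- !as.logical(e[[miss_col]]); is_ <- !as.logical(l[[miss_col]])
    both <- was & is_
    chg <- ifelse(both, l[[score_col]] - e[[score_col]], NA_real_)
    trans <- ifelse(both & e[[band_col]] != l[[band_col]],
                    paste0(e[[band_col]], "->", l[[band_col]]), NA_character_)
    out <- e[, id_cols, drop = FALSE]
    out$earlier <- ifelse(was, e[[score_col]], NA_real_)
    out$later <- ifelse(is_, l[[score_col]], NA_real_)
    out$change <- chg
    out$band_earlier <- e[[band_col]]; out$band_later <- l[[band_col]]
    out$transition <- trans
    out$newly_missing <- was & !is_
    out$newly_scored <- !was & is_
    out
  }
  structure(list(
    respondent_id = earlier$respondent_id,
    timepoints = c(earlier$timepoint, later$timepoint),
    domains = diff_frame(earlier$domains, later$domains,
                         c("area_id", "instrument_id", "domain_id"),
                         "normalized", "band", "missing"),
    areas = diff_frame(earlier$areas, later$areas, c("area_id"),
                       "area_score", "area_band", "missing")
  ), class = "rc_delta")
}

#' Export a snapshot (or delta) as a JSON document
#'
#' Stable field names for downstream report tooling.
#' @param x An `rc_snapshot` or `rc_delta`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_compass_json <- function(x, path) {
  stopifnot(inherits(x, "rc_snapshot") || inherits(x, "rc_delta"))
  doc <- unclass(x)
  doc$scale <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
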