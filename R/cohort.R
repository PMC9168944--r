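#' Summarize a cohort of compass snapshots
#'
#' Group-level view of unmet rehabilitation needs: for every mapped domain,
#' the median and 25-75% interquartile range of the normalized scores over
#' the cohort, plus the impairment count and frequency. Statistics use
#' available cases only: respondents whose domain is unscorable are excluded
#' from that domain's denominator, and `n_scored` is reported alongside so
#' the denominator is never hidden.
#'
#' @param snapshots List of `rc_snapshot`, one per respondent (filter to one
#'   time point before calling). All snapshots must share one area mapping.
#' @param impairment_threshold Normalized score below which a respondent
#'   counts as impaired in a domain (default 100).
#' @param quantile_type Percentile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between closest ranks).
#' @return Data frame of class `rc_cohort_summary`, one row per
#'   (instrument, domain): `area_id`, `instrument_id`, `domain_id`,
#'   `n_scored`, `median`, `q25`, `q75`, `impaired_n`, `frequency`,
#'   `percent` (nearest integer, half away from zero). Attribute
#'   `cohort_size` is the number of snapshots.
#' @export
summarize_cohort <- function(snapshots, impairment_threshold = 100,
                             quantile_type = 7) {
  if (length(snapshots) == 0L)
    rc_validation_error("empty snapshot set")
  stopifnot(all(vapply(snapshots, inherits, TRUE, "rc_snapshot")))
  sigs <- vapply(snapshots, `[[`, "", "mapping_signature")
  if (length(unique(sigs)) != 1L)
    rc_validation_error("snapshots use mixed area mappings")
  ids <- vapply(snapshots, `[[`, "", "respondent_id")
  if (anyDuplicated(ids))
    rc_validation_error(sprintf(
      "more than one snapshot for respondent '%s' (filter by time point first)",
      ids[duplicated(ids)][1L]))

  all_domains <- do.call(rbind, lapply(snapshots, `[[`, "domains"))
  key <- paste(all_domains$instrument_id, all_domains$domain_id, sep = ":")
  template <- snapshots[[1L]]$domains
  out <- do.call(rbind, lapply(seq_len(nrow(template)), function(i) {
    k <- paste(template$instrument_id[i], template$domain_id[i], sep = ":")
    rows <- all_domains[key == k & !all_domains$missing, ]
    x <- rows$normalized
    n <- length(x)
    imp <- sum(x < impairment_threshold)
    qs <- if (n) stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                                 names = FALSE) else rep(NA_real_, 3L)
    data.frame(
      area_id = template$area_id[i],
      instrument_id = template$instrument_id[i],
      domain_id = template$domain_id[i],
      n_scored = n, median = qs[2L], q25 = qs[1L], q75 = qs[3L],
      impaired_n = if (n) imp else NA_integer_,
      frequency = if (n) imp / n else NA_real_,
      percent = if (n) round_half_up(100 * imp / n) else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  structure(out, class = c("rc_cohort_summary", "data.frame"),
            cohort_size = length(snapshots))
}

# Nearest integer, half away from zero (base round() rounds half to even,
# which would print 20/24 as 83 either way but disagrees at exact halves).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Order a cohort summary worst-median first
#'
#' Report rows for an extent/frequency chart: stable ascending sort by
#' median (most severe problem first), ties broken by impairment frequency
#' descending, then domain id lexicographically.
#'
#' @param summary An `rc_cohort_summary`.
#' @return The summary rows in report order, with a `label` column.
#' @export
extent_frequency_table <- function(summary) {
  if (is.null(summary) || nrow(summary) == 0L)
    rc_validation_error("empty cohort summary")
  s <- summary[!is.na(summary$median), , drop = FALSE]
  ord <- order(s$median, -s$frequency, s$domain_id, method = "radix")
  s <- s[ord, , drop = FALSE]
  s$label <- paste(s$instrument_id, s$domain_id, sep = ":")
  rownames(s) <- NULL
  s
}

#' Write a cohort summary to CSV (one row per domain)
#' @param summary An `rc_cohort_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  df <- as.data.frame(summary)
  df$cohort_size <- attr(summary, "cohort_size")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a cohort summary to JSON
#' @inheritParams write_summary_csv
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  doc <- list(cohort_size = attr(summary, "cohort_size"),
              domains = as.data.frame(summary))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
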