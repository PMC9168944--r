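#' Define a synthetic cohort profile
#'
#' Stated world for the generator: a post-stroke outpatient cohort
#' (default size 24, as in a typical follow-up clinic study month) answering
#' every instrument at one or more follow-up time points. Impairment is
#' planted per domain: a respondent targeted as unimpaired answers the best
#' level of every member item; an impaired respondent draws item levels from
#' a binomially shifted ordinal distribution whose worseness parameter is
#' `severity`, with at least one item guaranteed off the best level so the
#' domain scores below 100.
#'
#' @param size Number of respondents (default 24).
#' @param prevalence Named numeric vector of per-domain target impairment
#'   prevalences, names `"instrument_id:domain_id"`, values in \[0, 1\].
#' @param default_prevalence Prevalence for domains not named (default 0.5,
#'   a mid-range burden typical of 12-month post-stroke cohorts).
#' @param severity Worseness parameter in (0, 1\]: expected fractional shift
#'   of an impaired answer toward the worst level (default 0.3, mild-to-
#'   moderate impairment).
#' @param mode `"exact-count"` (deterministic allocation of
#'   `round(prevalence * size)` impaired respondents; for worked-example
#'   counts) or `"probabilistic"` (independent Bernoulli per respondent).
#' @param timepoints Data frame `label`, `index` of time points to emit
#'   (default 3-month and 12-month).
#' @param improvement_drift Fraction by which severity shrinks per
#'   time-point step (default 0.25): planted impairments persist but soften
#'   at later follow-ups.
#' @param seed Integer seed; fixes the generated records byte-for-byte.
#' @return List of class `rc_cohort_profile`.
#' @export
cohort_profile <- function(size = 24, prevalence = NULL,
                           default_prevalence = 0.5, severity = 0.3,
                           mode = c("exact-count", "probabilistic"),
                           timepoints = data.frame(
                             label = c("3-month", "12-month"),
                             index = c(1L, 2L)),
                           improvement_drift = 0.25, seed = 20240101L) {
  mode <- match.arg(mode)
  if (size < 1L) rc_config_error("cohort size must be >= 1")
  if (!is.null(prevalence) &&
      (is.null(names(prevalence)) || any(prevalence < 0 | prevalence > 1)))
    rc_config_error("prevalence must be named and within [0, 1]")
  if (default_prevalence < 0 || default_prevalence > 1)
    rc_config_error("default_prevalence must be within [0, 1]")
  if (severity <= 0 || severity > 1)
    rc_config_error("severity must be in (0, 1]")
  if (improvement_drift < 0 || improvement_drift >= 1)
    rc_config_error("improvement_drift must be in [0, 1)")
  structure(list(
    size = as.integer(size), prevalence = prevalence,
    default_prevalence = default_prevalence, severity = severity,
    mode = mode, timepoints = timepoints,
    improvement_drift = improvement_drift, seed = as.integer(seed)
  ), class = "rc_cohort_profile")
}

#' Read a cohort profile from a JSON document
#' @param path JSON file; defaults to the packaged Fig-5-style profile
#'   (fatigue 20/24, sleep 18/24, QoL and strength 17/24, anxiety 16/24).
#' @return `rc_cohort_profile`.
#' @export
load_cohort_profile <- function(path = default_profile_file()) {
  doc <- jsonlite::read_json(path)
  tps <- if (is.null(doc$timepoints)) NULL else do.call(rbind, lapply(
    doc$timepoints, function(t) data.frame(label = t$label,
                                           index = as.integer(t$index),
                                           stringsAsFactors = FALSE)))
  cohort_profile(
    size = doc$size %||% 24,
    prevalence = if (!is.null(doc$prevalence)) unlist(doc$prevalence),
    default_prevalence = doc$default_prevalence %||% 0.5,
    severity = doc$default_severity %||% doc$severity %||% 0.3,
    mode = doc$mode %||% "exact-count",
    timepoints = tps %||% data.frame(label = c("3-month", "12-month"),
                                     index = c(1L, 2L)),
    improvement_drift = doc$improvement_drift %||% 0.25,
    seed = doc$seed %||% 20240101L)
}

#' Path of the packaged default cohort profile
#' @return File path.
#' @export
default_profile_file <- function() {
  system.file("extdata", "profiles", "default_cohort.json",
              package = "rehabcompass")
}

# Run fn under a seeded private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

best_index <- function(def, item) {
  if (item_orientation(def, item) == "higher-raw-is-better")
    length(item$codes) else 1L
}

# Shift an item from its best level toward the worst by `shift` level steps.
shifted_code <- function(def, item, shift) {
  n <- length(item$codes)
  b <- best_index(def, item)
  idx <- if (b == n) n - min(shift, n - 1L) else 1L + min(shift, n - 1L)
  item$codes[idx]
}

#' Generate item-level synthetic response records
#'
#' Emits one record per respondent, instrument, and time point, reproducible
#' byte-for-byte under the profile's seed. Domains targeted as unimpaired
#' are answered at the best level throughout; impaired domains draw each
#' item's shift from `Binomial(steps, severity)` (severity decays by the
#' improvement drift at later time points) with one member item forced off
#' the best level, so the planted impairment counts are recovered exactly by
#' the scoring pipeline.
#'
#' @param profile A [cohort_profile()].
#' @param catalog An `rc_catalog`; every instrument is administered.
#' @param mapping Optional `rc_area_mapping` (checked against the catalog).
#' @return List of `rc_record`.
#' @export
generate_cohort <- function(profile, catalog, mapping = NULL) {
  stopifnot(inherits(profile, "rc_cohort_profile"),
            inherits(catalog, "rc_catalog"))
  all_keys <- unlist(lapply(catalog, function(def)
    paste(def$instrument_id, def$domains$domain_id, sep = ":")))
  unknown <- setdiff(names(profile$prevalence), all_keys)
  if (length(unknown))
    rc_config_error(sprintf("prevalence given for unknown domain '%s'",
                            unknown[1L]))
  if (!is.null(mapping)) area_mapping(mapping$areas, mapping$members, catalog)

  size <- profile$size
  resp_ids <- sprintf("R%03d", seq_len(size))

  with_private_seed(profile$seed, function() {
    # Plant the impaired set once per domain; it persists across time points.
    impaired <- lapply(stats::setNames(all_keys, all_keys), function(k) {
      p <- if (k %in% names(profile$prevalence)) profile$prevalence[[k]]
           else profile$default_prevalence
      if (profile$mode == "exact-count") {
        n_imp <- round_half_up(p * size)
        seq_len(size) %in% sample.int(size, n_imp)
      } else {
        stats::runif(size) < p
      }
    })

    records <- list()
    for (t in seq_len(nrow(profile$timepoints))) {
      tp_label <- profile$timepoints$label[t]
      tp_index <- profile$timepoints$index[t]
      sev <- profile$severity *
        (1 - profile$improvement_drift)^(tp_index - 1L)
      for (r in seq_len(size)) {
        for (def in catalog) {
          answers <- integer(0)
          for (d in def$domains$domain_id) {
            k <- paste(def$instrument_id, d, sep = ":")
            member_ids <- def$domain_items[[d]]
            is_imp <- impaired[[k]][r]
            if (domain_rule(def, d) == "grade-rescale") {
              g <- if (is_imp) 1L + stats::rbinom(1L, 4L, sev) else 0L
              ord <- def$grade_order
              vals <- integer(length(ord))
              if (g > 0L) vals[length(ord) - g + 1L] <- 1L
              answers[ord] <- vals
            } else if (!is_imp) {
              for (id in member_ids) {
                it <- def$items[[id]]
                answers[[id]] <- it$codes[best_index(def, it)]
              }
            } else {
              steps <- vapply(def$items[member_ids],
                              function(it) length(it$codes) - 1L, 0L)
              shifts <- stats::rbinom(length(member_ids), steps, sev)
              if (all(shifts == 0L)) {
                j <- if (length(member_ids) == 1L) 1L
                     else sample.int(length(member_ids), 1L)
                shifts[j] <- 1L + stats::rbinom(1L, steps[j] - 1L, sev)
              }
              for (j in seq_along(member_ids)) {
                it <- def$items[[member_ids[j]]]
                answers[[member_ids[j]]] <- shifted_code(def, it, shifts[j])
              }
            }
          }
          records[[length(records) + 1L]] <- response_record(
            respondent_id = resp_ids[r], timepoint = tp_label,
            instrument_id = def$instrument_id,
            answers = answers[names(def$items)],
            timepoint_index = tp_index)
        }
      }
    }
    records
  })
}

#' Inject item-level missingness into response records
#'
#' Each answer is independently blanked (explicit `NA`) with the given
#' probability; respondent, time-point, and instrument identifiers are never
#' touched. Deterministic under `seed`.
#'
#' @param records List of `rc_record`.
#' @param rate Per-item missingness probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The records with some answers set to `NA`.
#' @export
inject_missingness <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate > 1)
    rc_range_error("missingness rate must be within [0, 1]")
  if (rate == 0) return(records)
  with_private_seed(seed, function() {
    lapply(records, function(r) {
      drop <- stats::runif(length(r$answers)) < rate
      r$answers[drop] <- NA_integer_
      r
    })
  })
}
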