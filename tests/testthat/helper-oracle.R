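# Independent brute-force scorer used as the oracle against score_domain().
#
# Different computational route on purpose: instead of aggregate-then-rescale,
# each answered item is mapped on its own onto 0-100 toward best health via
# its level index, and the domain score is the plain average of the per-item
# values. For every packaged rule (all items of a domain share one level
# range) this is algebraically the same quantity, reached by different code.

oracle_item_points <- function(def, item, code) {
  pos <- match(code, item$codes)
  u <- 100 * (pos - 1) / (length(item$codes) - 1)
  orient <- item$orientation
  if (is.null(orient)) orient <- def$orientation
  if (orient == "higher-raw-is-worse") u <- 100 - u
  u
}

oracle_grade <- function(def, answers) {
  ord <- def$grade_order
  for (k in seq_along(ord)) {
    v <- answers[[ord[k]]]
    if (is.na(v)) return(NA_real_)
    if (v == 1L) return(length(ord) - k + 1)
  }
  0
}

oracle_score_domain <- function(def, answers, domain_id, floor = 0.5) {
  member_ids <- def$domain_items[[domain_id]]
  a <- answers[member_ids]
  names(a) <- member_ids
  rule <- def$domains$scoring_rule[match(domain_id, def$domains$domain_id)]

  if (rule == "grade-rescale") {
    g <- oracle_grade(def, a)
    if (is.na(g)) return(list(raw = NA_real_, normalized = NA_real_,
                              missing = TRUE))
    return(list(raw = g, normalized = 100 * (5 - g) / 5, missing = FALSE))
  }
  answered <- !is.na(a)
  if (sum(answered) == 0L || sum(answered) / length(a) < floor)
    return(list(raw = NA_real_, normalized = NA_real_, missing = TRUE))
  pts <- vapply(member_ids[answered], function(id)
    oracle_item_points(def, def$items[[id]], a[[id]]), 0)
  raw <- switch(rule,
    "mean-rescale" = mean(a[answered]),
    "sum-rescale" = mean(a[answered]) * length(a),
    "per-dimension-rescale" = mean(a[answered]),
    "passthrough-0-100" = mean(a[answered]))
  list(raw = raw, normalized = mean(pts), missing = FALSE)
}

# Enumerate every response vector of a domain (used where <= 5 items).
enumerate_response_vectors <- function(def, domain_id) {
  member_ids <- def$domain_items[[domain_id]]
  grids <- lapply(def$items[member_ids], `[[`, "codes")
  names(grids) <- member_ids
  as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
}
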