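test_that("packaged catalog holds exactly the default instruments", {
  catalog <- the_catalog()
  expect_setequal(names(catalog),
                  c("sis3", "sis_plus", "hads", "fas", "smrsq", "eq5d3l",
                    "eat10"))
  # stated item-bank structure
  expect_length(the_catalog()$sis3$items, 60L)  # 59 ordinal + recovery rating
  expect_equal(nrow(the_catalog()$sis3$domains), 9L)
  expect_length(the_catalog()$hads$items, 14L)
  expect_length(the_catalog()$fas$items, 10L)
  expect_length(the_catalog()$smrsq$items, 5L)
  expect_length(the_catalog()$eq5d3l$items, 6L)
  expect_length(the_catalog()$eat10$items, 10L)
  sis_sizes <- vapply(the_catalog()$sis3$domain_items, length, 0L)
  expect_equal(unname(sis_sizes[c("strength", "memory", "emotion",
                                  "communication", "adl", "mobility",
                                  "hand", "participation")]),
               c(4L, 7L, 9L, 7L, 10L, 9L, 5L, 8L))
})

test_that("catalog loading rejects bad documents and duplicate ids", {
  expect_length(load_instrument_catalog(character(0)), 0L)
  f <- default_instrument_files()
  expect_error(load_instrument_catalog(c(f, f[1L])),
               class = "rc_conflict_error")

  # an item pointing at an undeclared domain is a validation failure that
  # names the offending construct
  bad <- tempfile(fileext = ".json")
  doc <- jsonlite::read_json(system.file("extdata", "instruments", "fas.json",
                                         package = "rehabcompass"))
  doc$items[[1L]]$domain_id <- "somewhere_else"
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(load_instrument_catalog(bad), "somewhere_else",
               class = "rc_config_error")

  # missing required field names the file and the field
  doc2 <- jsonlite::read_json(f[1L]); doc2$scoring_rule <- NULL
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc2, bad2, auto_unbox = TRUE)
  expect_error(load_instrument_catalog(bad2), "scoring_rule",
               class = "rc_config_error")
})

test_that("instrument invariants are enforced at construction", {
  items <- list(item_definition("a", "d1", 1:3), item_definition("b", "d1", 1:3))
  doms <- data.frame(domain_id = "d1", name = "D1")
  expect_s3_class(instrument_definition("x", "X", items, doms,
                                        "mean-rescale", "higher-raw-is-better"),
                  "rc_instrument")
  expect_error(item_definition("a", "d", 1L), "levels")
  expect_error(item_definition("a", "d", c(1L, 1L, 2L)), "increasing")
  expect_error(
    instrument_definition("x", "X", c(items, items[1L]), doms,
                          "mean-rescale", "higher-raw-is-better"),
    "duplicate item", class = "rc_validation_error")
  expect_error(
    instrument_definition("x", "X", items,
                          rbind(doms, data.frame(domain_id = "d2", name = "D2")),
                          "mean-rescale", "higher-raw-is-better"),
    "no items", class = "rc_validation_error")
})

test_that("response validation pinpoints unknown items and bad codes", {
  hads <- the_catalog()$hads
  ok <- response_record("p1", "3-month", "hads",
                        stats::setNames(rep(2L, 14), names(hads$items)))
  expect_silent(validate_responses(ok, hads))

  fas <- the_catalog()$fas
  bad <- response_record("p1", "3-month", "fas",
                         stats::setNames(c(7L, rep(3L, 9)), names(fas$items)))
  err <- expect_error(validate_responses(bad, fas), class = "rc_range_error")
  expect_match(conditionMessage(err), "fas_01")
  expect_match(conditionMessage(err), "7")
  expect_match(conditionMessage(err), "1-5")

  sis <- the_catalog()$sis3
  expect_error(
    validate_responses(response_record("p1", "t", "sis3", c(sis9z = 3L)), sis),
    "sis9z", class = "rc_validation_error")
  expect_error(
    validate_responses(
      response_record("p1", "t", "fas",
                      stats::setNames(c(1L, 1L), c("fas_01", "fas_01"))), fas),
    "duplicate", class = "rc_validation_error")
  # explicit-missing passes through untouched
  part <- response_record("p1", "t", "fas",
                          stats::setNames(c(NA, rep(2L, 9)), names(fas$items)))
  expect_silent(validate_responses(part, fas))
})

test_that("normalize_score is an anchored linear map and rejects out-of-bounds", {
  expect_equal(normalize_score(50, c(10, 50), "higher-raw-is-worse"), 0)
  expect_equal(normalize_score(10, c(10, 50), "higher-raw-is-worse"), 100)
  expect_equal(normalize_score(30, c(10, 50), "higher-raw-is-worse"), 50)
  expect_equal(normalize_score(5, c(1, 5), "higher-raw-is-better"), 100)
  expect_equal(normalize_score(3, c(1, 5), "higher-raw-is-better"), 50)
  expect_error(normalize_score(51, c(10, 50), "higher-raw-is-worse"),
               class = "rc_range_error")
  expect_error(normalize_score(0.9, c(1, 5), "higher-raw-is-better"),
               class = "rc_range_error")
})

test_that("worked scoring examples hit the published rescales", {
  catalog <- the_catalog()
  # SIS strength all at the best level -> 100
  sis <- catalog$sis3
  best <- all_best_record(sis)
  expect_equal(score_domain(best, sis, "strength")$normalized, 100)
  # FAS all-worst: raw sum 50 -> 0
  fas <- catalog$fas
  worst <- all_worst_record(fas)
  sc <- score_domain(worst, fas, "fatigue")
  expect_equal(sc$raw, 50)
  expect_equal(sc$normalized, 0)
  # FAS total 22 -> 70 (frozen from the independent oracle's rescale)
  answers <- stats::setNames(c(3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 1L),
                             names(fas$items))
  expect_equal(sum(answers), 22)
  rec <- response_record("p", "t", "fas", answers)
  sc22 <- score_domain(rec, fas, "fatigue")
  expect_equal(sc22$raw, 22)
  expect_equal(sc22$normalized, 70)
  orc <- oracle_score_domain(fas, rec$answers, "fatigue")
  expect_equal(sc22$normalized, orc$normalized)
  # HADS subscale: sum s -> 100*(21-s)/21
  hads <- catalog$hads
  h <- response_record("p", "t", "hads",
                       stats::setNames(rep(1L, 14), names(hads$items)))
  expect_equal(score_domain(h, hads, "anxiety")$raw, 7)
  expect_equal(score_domain(h, hads, "anxiety")$normalized, 100 * 14 / 21)
  # EQ-5D VAS passes through unchanged
  eq <- catalog$eq5d3l
  e <- response_record("p", "t", "eq5d3l",
                       c(eq_mobility = 1L, eq_selfcare = 1L, eq_usual = 2L,
                         eq_pain_discomfort = 2L, eq_anxiety_depression = 3L,
                         eq_vas = 78L))
  es <- score_instrument(e, eq)
  expect_equal(es$normalized[es$domain_id == "vas"], 78)
  expect_equal(es$normalized[es$domain_id == "usual"], 50)
  expect_equal(es$normalized[es$domain_id == "anxiety_depression"], 0)
})

test_that("smRSq decision tree resolves grades severest-first, fail-safe", {
  smrsq <- the_catalog()$smrsq
  ids <- smrsq$grade_order
  grade_of <- function(answers) {
    rec <- response_record("p", "t", "smrsq", answers)
    score_domain(rec, smrsq, "grade")
  }
  all_no <- stats::setNames(rep(0L, 5), ids)
  expect_equal(grade_of(all_no)$raw, 0)
  expect_equal(grade_of(all_no)$normalized, 100)
  for (g in 1:5) {
    a <- all_no
    a[[ids[5L - g + 1L]]] <- 1L
    expect_equal(grade_of(a)$raw, g)
    expect_equal(grade_of(a)$normalized, 100 * (5 - g) / 5)
  }
  # a yes above a yes: the severer one wins (tree order)
  two <- all_no; two[[ids[2L]]] <- 1L; two[[ids[4L]]] <- 1L
  expect_equal(grade_of(two)$raw, 4)
  # unanswered question before the first yes -> unresolvable, never a guess
  amb <- all_no; amb[[ids[1L]]] <- NA_integer_
  expect_true(grade_of(amb)$missing)
  amb2 <- all_no; amb2[[ids[3L]]] <- NA_integer_; amb2[[ids[4L]]] <- 1L
  expect_true(grade_of(amb2)$missing)
  # missing after the resolving yes is irrelevant
  res <- all_no; res[[ids[1L]]] <- 1L; res[is.na(res)] <- 0L
  res[[ids[5L]]] <- NA_integer_
  expect_equal(grade_of(res)$raw, 5)
})

test_that("proration scores a half-answered domain and floors below it", {
  fas <- the_catalog()$fas
  ids <- names(fas$items)
  # 5 of 10 answered at code 3 -> prorated sum 30 -> 50 points
  a <- stats::setNames(c(rep(3L, 5), rep(NA_integer_, 5)), ids)
  sc <- score_domain(response_record("p", "t", "fas", a), fas, "fatigue")
  expect_false(sc$missing)
  expect_equal(sc$raw, 30)
  expect_equal(sc$normalized, 50)
  expect_equal(sc$n_answered, 5L)
  # 4 of 10 -> below the 0.5 floor -> unscorable
  a4 <- stats::setNames(c(rep(3L, 4), rep(NA_integer_, 6)), ids)
  sc4 <- score_domain(response_record("p", "t", "fas", a4), fas, "fatigue")
  expect_true(sc4$missing)
  expect_true(is.na(sc4$normalized))
  # floor is a knob
  sc_low <- score_domain(response_record("p", "t", "fas", a4), fas, "fatigue",
                         proration_floor = 0.3)
  expect_false(sc_low$missing)
  # fully-answered domain: prorated and plain scoring coincide
  full <- stats::setNames(rep(3L, 10), ids)
  expect_equal(
    score_domain(response_record("p", "t", "fas", full), fas, "fatigue")$raw,
    sum(full))
})

test_that("score_instrument covers every domain in definition order", {
  catalog <- the_catalog()
  sis <- catalog$sis3
  all_sc <- score_instrument(all_best_record(sis), sis)
  expect_equal(all_sc$domain_id, sis$domains$domain_id)
  expect_true(all(all_sc$normalized == 100))
  expect_error(score_domain(all_best_record(sis), sis, "nope"),
               class = "rc_validation_error")
  # empty answers -> every domain missing
  empty <- response_record("p", "t", "sis3", integer(0))
  esc <- score_instrument(empty, sis)
  expect_true(all(esc$missing))
  expect_true(all(is.na(esc$normalized)))
})

test_that("anchoring holds for every instrument and domain", {
  for (def in the_catalog()) {
    best <- score_instrument(all_best_record(def), def)
    worst <- score_instrument(all_worst_record(def), def)
    expect_true(all(best$normalized == 100), label = def$instrument_id)
    expect_true(all(worst$normalized == 0), label = def$instrument_id)
  }
})

test_that("single-item worsening never raises a domain score", {
  set.seed(42)
  catalog <- the_catalog()
  for (i in 1:40) {
    def <- catalog[[sample.int(length(catalog), 1L)]]
    if (def$scoring_rule == "grade-rescale") next  # tree handled separately
    rec <- random_record(def)
    id <- sample(names(def$items), 1L)
    it <- def$items[[id]]
    pos <- match(rec$answers[[id]], it$codes)
    worse_dir <- if (item_best_code(def, it) == max(it$codes)) -1L else 1L
    npos <- pos + worse_dir
    if (npos < 1L || npos > length(it$codes)) next
    rec2 <- rec; rec2$answers[[id]] <- it$codes[npos]
    s1 <- score_instrument(rec, def); s2 <- score_instrument(rec2, def)
    expect_true(all(s2$normalized <= s1$normalized + 1e-12),
                label = paste(def$instrument_id, id))
  }
})

test_that("random records match the independent oracle domain by domain", {
  set.seed(7)
  catalog <- the_catalog()
  for (i in 1:25) {
    def <- catalog[[sample.int(length(catalog), 1L)]]
    rec <- random_record(def)
    # knock out a few answers to exercise proration
    k <- sample.int(length(rec$answers), size = sample(0:2, 1L))
    rec$answers[k] <- NA_integer_
    for (d in def$domains$domain_id) {
      got <- score_domain(rec, def, d)
      want <- oracle_score_domain(def, rec$answers, d)
      expect_equal(got$missing, want$missing,
                   label = paste(def$instrument_id, d))
      if (!want$missing) {
        expect_equal(got$raw, want$raw)
        expect_equal(got$normalized, want$normalized, tolerance = 1e-12)
        expect_gte(got$normalized, 0)
        expect_lte(got$normalized, 100)
      }
    }
  }
})

test_that("per-item orientation overrides reflect within one instrument", {
  items <- list(item_definition("good", "d", 1:5),
                item_definition("badly", "d", 1:5,
                                orientation = "higher-raw-is-worse"))
  def <- instrument_definition("mix", "Mixed", items,
                               data.frame(domain_id = "d", name = "D"),
                               "mean-rescale", "higher-raw-is-better")
  rec <- response_record("p", "t", "mix", c(good = 5L, badly = 1L))
  expect_equal(score_domain(rec, def, "d")$normalized, 100)
  rec2 <- response_record("p", "t", "mix", c(good = 5L, badly = 5L))
  expect_equal(score_domain(rec2, def, "d")$normalized, 50)
})
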