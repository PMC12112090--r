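# Closed-vocabulary FTR classification: normalization, marker matching,
# the class schema with modal dominance, participant scoring, and
# validation metrics.

eng <- default_lexicon("english")
nld <- default_lexicon("dutch")

test_that("normalization lowercases, expands contractions and strips parentheticals", {
  expect_equal(normalize_text("It'll rain tomorrow.", eng),
               c("it", "will", "rain", "tomorrow"))
  expect_equal(normalize_text("Morgen regent het.", nld),
               c("morgen", "regent", "het"))
  expect_equal(normalize_text("It rains (I'm very sure)", eng),
               c("it", "rains"))
  expect_equal(normalize_text("He won't leave", eng),
               c("he", "will", "not", "leave"))
  expect_equal(normalize_text("It's gonna rain", eng),
               c("it", "s", "going", "to", "rain"))
  expect_equal(normalize_text("   ", eng), character(0))
})

test_that("marker matching handles single tokens and contiguous subsequences", {
  expect_true(contains_marker(c("it", "is", "going", "to", "rain"),
                              "going to"))
  expect_false(contains_marker(c("the", "bears", "win"), "will"))
  expect_true(contains_marker(c("het", "zal", "regenen"), "zal"))
  expect_true(contains_marker(
    c("hij", "staat", "op", "het", "punt", "te", "vertrekken"),
    "staat op het punt"))
  # non-contiguous tokens do not match a multiword marker
  expect_false(contains_marker(c("going", "there", "to", "win"),
                               "going to"))
  expect_false(contains_marker(character(0), "will"))
})

test_that("the class schema scores future, present, and modal dominance", {
  item <- list(language = "english", present_forms = "rains")
  expect_equal(classify_response("It will rain tomorrow", item, eng),
               c(future = 1L, present = 0L))
  expect_equal(classify_response("It will possibly rain tomorrow", item, eng),
               c(future = 0L, present = 0L))
  expect_equal(classify_response("It rains tomorrow", item, eng),
               c(future = 0L, present = 1L))
  expect_equal(classify_response("Rain tomorrow is possible", item, eng),
               c(future = 0L, present = 0L))
  # negated predictions remain future tense
  expect_equal(classify_response("It won't rain tomorrow", item, eng),
               c(future = 1L, present = 0L))
  expect_equal(classify_response("She is going to win",
                                 list(language = "english",
                                      present_forms = "wins"), eng),
               c(future = 1L, present = 0L))
  item_nl <- list(language = "dutch", present_forms = "regent")
  expect_equal(classify_response("Morgen regent het", item_nl, nld),
               c(future = 0L, present = 1L))
  expect_equal(classify_response("Het zal morgen regenen", item_nl, nld),
               c(future = 1L, present = 0L))
  expect_equal(classify_response("Het zal morgen zeker regenen", item_nl, nld),
               c(future = 0L, present = 0L))
  # a response in neither class scores (0, 0)
  expect_equal(classify_response("Rain is expected", item, eng),
               c(future = 0L, present = 0L))
})

test_that("language mismatches and excluded items are rejected", {
  expect_error(
    classify_response("Morgen regent het",
                      list(language = "dutch", present_forms = "regent"),
                      eng),
    "does not match")
  expect_error(
    classify_response("x", list(language = "english",
                                present_forms = "rains",
                                excluded = TRUE), eng),
    "excluded")
})

test_that("any modal marker suppresses both classes (modal dominance)", {
  base <- list(
    list(text = "It will rain tomorrow", forms = "rains"),
    list(text = "It rains tomorrow", forms = "rains"),
    list(text = "She is going to win the race", forms = "wins")
  )
  for (case in base) {
    item <- list(language = "english", present_forms = case$forms)
    expect_equal(sum(classify_response(case$text, item, eng)), 1)
    for (modal in c("might", "may", "possibly", "definitely", "certainly")) {
      injected <- paste(case$text, modal)
      expect_equal(unname(classify_response(injected, item, eng)),
                   c(0L, 0L), label = injected)
    }
  }
})

test_that("classification is deterministic and mutually exclusive", {
  item <- list(language = "english", present_forms = "rains")
  texts <- c("It will rain tomorrow", "It rains", "Maybe it rains",
             "It is going to rain", "No idea")
  for (tx in texts) {
    s1 <- classify_response(tx, item, eng)
    s2 <- classify_response(tx, item, eng)
    expect_identical(s1, s2)
    expect_lte(sum(s1), 1)
  }
})

test_that("participant proportions count scorable responses only", {
  items <- tiny_items(10)
  texts <- c(
    rep("it will rain tomorrow", 6), # future
    rep("it rains tomorrow", 2),     # present (forms recycled, see below)
    rep("it might rain tomorrow", 2) # modal-dominated
  )
  # use each item's own present form for the present-tense answers
  texts[7:8] <- paste("it", items$present_forms[7:8], "tomorrow")
  responses <- tibble::tibble(participant_id = "p1",
                              item_id = items$item_id, text = texts)
  out <- score_participants(responses, items, eng)
  expect_equal(out$fut_proportion, 0.6)
  expect_equal(out$pres_proportion, 0.2)
  expect_equal(out$n_scored, 10L)
  expect_lte(out$fut_proportion + out$pres_proportion, 1)

  # permuting responses leaves the participant summary unchanged
  perm <- responses[sample.int(10), ]
  expect_equal(score_participants(perm, items, eng)[, -1], out[, -1])
})

test_that("excluded items contribute nothing and can empty a participant", {
  items <- tiny_items(4, excluded = c(FALSE, FALSE, TRUE, TRUE))
  responses <- tibble::tibble(
    participant_id = c("p1", "p1", "p2", "p2"),
    item_id = items$item_id[c(1, 2, 3, 4)],
    text = "it will rain tomorrow"
  )
  out <- score_participants(responses, items, eng)
  expect_equal(out$participant_id, "p1") # p2 is missing, not zero
  expect_equal(out$n_scored, 2L)
  expect_equal(out$fut_proportion, 1)
  expect_equal(out$pres_proportion, 0)
  expect_error(
    score_participants(responses[3:4, ], items, eng), "scorable")
  dup <- responses[c(1, 1), ]
  expect_error(score_participants(dup, items, eng), "duplicate")
})

test_that("validation metrics come from the per-class confusion matrix", {
  grid <- expand.grid(participant_id = sprintf("p%02d", 1:10),
                      item_id = sprintf("i%02d", 1:10),
                      stringsAsFactors = FALSE)
  set.seed(11)
  gold <- tibble::tibble(grid,
                         future = rbinom(100, 1, 0.5))
  gold$present <- ifelse(gold$future == 1, 0L, rbinom(100, 1, 0.5))
  perfect <- validate_against_labels(gold, gold)
  expect_equal(perfect$accuracy, c(1, 1))
  expect_equal(perfect$recall, c(1, 1))

  flipped <- gold
  flipped$future <- 0L
  rec0 <- validate_against_labels(flipped, gold)
  expect_equal(rec0$recall[rec0$class == "future"], 0)

  off4 <- gold
  off4$future[1:4] <- 1L - off4$future[1:4]
  acc <- validate_against_labels(off4, gold)
  expect_equal(acc$accuracy[acc$class == "future"], 0.96)

  misaligned <- gold[-1, ]
  expect_error(validate_against_labels(misaligned, gold), "aligned")
})
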