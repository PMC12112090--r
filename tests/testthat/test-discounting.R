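# Hyperbolic discounting: delay conversion, value function, indifference
# points, candidate enumeration and best-match fitting.

test_that("verbal delays convert to weeks under the declared convention", {
  expect_equal(delay_in_weeks("one week"), 1.0)
  expect_equal(delay_in_weeks("one day"), 1 / 7)
  expect_equal(delay_in_weeks("two days"), 2 / 7)
  expect_equal(delay_in_weeks("one month"), 365.25 / 12 / 7)
  expect_equal(delay_in_weeks("two years"), 2 * 365.25 / 7)
  expect_equal(delay_in_weeks("4½ months"), 4.5 * 365.25 / 12 / 7)
  expect_equal(delay_in_weeks("4½ months"), 19.5670, tolerance = 1e-4)
  expect_equal(delay_in_weeks(c("1 month", "2 weeks")),
               c(365.25 / 84, 2))
  expect_error(delay_in_weeks("next fortnight"), "fortnight")
  expect_error(delay_in_weeks("one lightyear"), "lightyear")
})

test_that("hyperbolic value matches closed form and is strictly decreasing", {
  expect_equal(hyperbolic_value(10, 0, 104), 10)
  expect_equal(hyperbolic_value(10, 0.1, 10), 5)
  expect_equal(hyperbolic_value(10, 1 / 6, 2), 7.5)
  expect_error(hyperbolic_value(-1, 0.1, 1), "positive")
  expect_error(hyperbolic_value(10, -0.1, 1), "nonnegative")
  # monotonicity in k and in D
  ks <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(hyperbolic_value(10, ks, 5)) < 0))
  Ds <- seq(0.1, 120, length.out = 50)
  expect_true(all(diff(hyperbolic_value(10, 0.3, Ds)) < 0))
})

test_that("indifference k inverts the value function", {
  expect_equal(indifference_k(7.50, 10, 2), 1 / 6)
  expect_equal(indifference_k(10, 10, 5), 0)
  expect_equal(indifference_k(9.25, 10, 19.5670), 0.0041439,
               tolerance = 1e-4)
  # the LLR discounted at the indifference rate equals the SSR exactly
  k <- indifference_k(7.50, 10, 2)
  expect_equal(hyperbolic_value(10, k, 2), 7.50)
  expect_error(indifference_k(11, 10, 2), "exceed")
  expect_error(indifference_k(5, 10, 0), "positive")
})

test_that("candidate enumeration covers the crossed battery", {
  # one indifference point per item before de-duplication
  b1 <- study1_battery()
  b2 <- study2_battery()
  expect_length(indifference_k(b1$ssr_amount, b1$llr_amount,
                               b1$delay_weeks), 84)
  expect_length(indifference_k(b2$ssr_amount, b2$llr_amount,
                               b2$delay_weeks), 64)
  # crossed grids share some indifference points, so the unique candidate
  # set is no larger and strictly increasing
  expect_lte(length(candidate_ks(b1)), 84)
  expect_lte(length(candidate_ks(b2)), 64)
  expect_true(all(diff(candidate_ks(b2)) > 1e-12))
  single <- tiny_battery()[2, ]
  expect_equal(candidate_ks(single), 0.25)
})

test_that("near-identical indifference points collapse under the tolerance", {
  battery <- tibble::tibble(
    item_id = c("x", "y", "z"),
    ssr_amount = c(5, 8, 9),
    llr_amount = 10,
    delay_label = c("two weeks", "one week", "one week"),
    delay_weeks = c(2, 0.5, 1)
  )
  # x: 1/2, y: 0.25/0.5 = 1/2, z: 1/9
  expect_length(candidate_ks(battery), 2)
})

test_that("choice prediction uses a strict threshold with LLR at ties", {
  item <- list(ssr_amount = 7.50, llr_amount = 10, delay_weeks = 2)
  expect_equal(predict_choice(item, 0), "LLR")
  expect_equal(predict_choice(item, 1 / 6), "LLR") # exact indifference
  expect_equal(predict_choice(item, 1 / 6 + 1e-9), "SSR")
  far <- list(ssr_amount = 9.50, llr_amount = 10, delay_weeks = 104.357)
  expect_equal(predict_choice(far, 0.01), "SSR")
  # SSR-preference region is upward-closed in k
  for (row in seq_len(nrow(study2_battery()))) {
    it <- study2_battery()[row, ]
    ik <- indifference_k(it$ssr_amount, it$llr_amount, it$delay_weeks)
    expect_equal(predict_choice(it, ik - 1e-9), "LLR")
    expect_equal(predict_choice(it, ik + 1e-9), "SSR")
  }
})

test_that("an all-LLR responder fits to the smallest candidate exactly", {
  battery <- study2_battery()
  obs <- tibble::tibble(participant_id = "p1", item_id = battery$item_id,
                        choice = "LLR")
  fit <- fit_k(obs, battery)
  expect_equal(fit$k, min(candidate_ks(battery)))
  expect_equal(fit$match_proportion, 1.0)
  expect_equal(fit$n_tied, 1L)
  expect_equal(fit$log_k, log(fit$k))
})

test_that("noise-free choices from a candidate rate refit perfectly", {
  battery <- study1_battery()
  cands <- candidate_ks(battery)
  for (k_star in cands[c(1, 20, 42, length(cands))]) {
    fit <- fit_k(hyperbolic_choices(k_star, battery), battery)
    expect_equal(fit$match_proportion, 1.0)
    expect_gte(fit$k, min(cands))
    expect_lte(fit$k, max(cands))
  }
})

test_that("tied candidates resolve to their geometric mean", {
  battery <- tiny_battery() # indifference points 1, 1/4, 1/9
  obs <- tibble::tibble(
    participant_id = "p1",
    item_id = c("C", "A"),
    choice = c("SSR", "LLR")
  )
  fit <- fit_k(obs, battery)
  # candidates 1/4 and 1 both predict both observed choices
  expect_equal(fit$n_tied, 2L)
  expect_equal(fit$k, sqrt(0.25 * 1))
  expect_equal(fit$match_proportion, 1.0)
})

test_that("fit_k validates its inputs", {
  battery <- tiny_battery()
  expect_error(fit_k(tibble::tibble(participant_id = character(),
                                    item_id = character(),
                                    choice = character()), battery),
               "at least one")
  dup <- tibble::tibble(participant_id = "p1", item_id = c("A", "A"),
                        choice = c("SSR", "LLR"))
  expect_error(fit_k(dup, battery), "duplicate")
  unknown <- tibble::tibble(participant_id = "p1", item_id = "nope",
                            choice = "SSR")
  expect_error(fit_k(unknown, battery), "not in battery")
  bad <- tibble::tibble(participant_id = "p1", item_id = "A",
                        choice = "YES")
  expect_error(fit_k(bad, battery), "SSR")
  two <- tibble::tibble(participant_id = c("p1", "p2"),
                        item_id = c("A", "B"), choice = "LLR")
  expect_error(fit_k(two, battery), "single participant")
})

test_that("cohort fitting pools the match proportion over participants", {
  battery <- study2_battery()
  cands <- candidate_ks(battery)
  obs <- dplyr::bind_rows(
    hyperbolic_choices(cands[10], battery, "pA"),
    hyperbolic_choices(cands[40], battery, "pB")
  )
  fit <- cohort_fit(obs, battery)
  expect_equal(nrow(fit$fits), 2)
  expect_equal(fit$overall_match_proportion, 1.0)

  # flip 8 of pB's 64 choices: pooled proportion can only meet or exceed
  # the generating rate's agreement
  flipped <- obs
  idx <- which(flipped$participant_id == "pB")[1:8]
  flipped$choice[idx] <- ifelse(flipped$choice[idx] == "SSR", "LLR", "SSR")
  noisy <- cohort_fit(flipped, battery)
  expect_gte(noisy$overall_match_proportion, (64 + 56) / 128)
  expect_lte(noisy$overall_match_proportion, 1)

  single <- cohort_fit(hyperbolic_choices(cands[5], battery, "solo"),
                       battery)
  expect_equal(nrow(single$fits), 1)
  expect_equal(single$overall_match_proportion,
               single$fits$match_proportion)
  # participant identity is attached to propagated errors
  bad <- tibble::tibble(participant_id = c("ok", "bad", "bad"),
                        item_id = battery$item_id[c(1, 2, 2)],
                        choice = "LLR")
  expect_error(cohort_fit(bad, battery), "bad")
})
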