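# Shared in-code fixtures for the suite.

# A three-item battery with well-separated indifference points
# (1/9, 1/4, 1) used for tie-breaking and inversion checks.
tiny_battery <- function() {
  tibble::tibble(
    item_id = c("A", "B", "C"),
    ssr_amount = c(5, 8, 9),
    llr_amount = 10,
    delay_label = "one week",
    delay_weeks = 1
  )
}

# Noise-free choices a hyperbolic discounter with rate k makes on a battery.
hyperbolic_choices <- function(k, battery, participant_id = "p1") {
  ik <- indifference_k(battery$ssr_amount, battery$llr_amount,
                       battery$delay_weeks)
  tibble::tibble(
    participant_id = participant_id,
    item_id = battery$item_id,
    choice = ifelse(k > ik, "SSR", "LLR")
  )
}

# A minimal English item list for classifier tests.
tiny_items <- function(n = 3, excluded = rep(FALSE, n)) {
  bank <- list(
    c("rain", "rains"), c("win", "wins"), c("play", "plays"),
    c("crash", "crashes"), c("leave", "leaves")
  )
  idx <- rep_len(seq_along(bank), n)
  tibble::tibble(
    item_id = sprintf("it%02d", seq_len(n)),
    language = "english",
    present_forms = vapply(idx, function(i) bank[[i]][2], character(1)),
    target_verb_lemma = vapply(idx, function(i) bank[[i]][1], character(1)),
    excluded = excluded
  )
}
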