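# Deterministic closed-vocabulary classification of elicited FTR sentences.
#
# Class schema: a response is future tense iff it contains a future marker
# and no modal marker; it is present tense iff it is not future, contains
# no modal marker, and conjugates the item's target verb in one of its
# present-tense forms. Any modal word (high- or low-certainty) dominates
# and suppresses both classes.

#' Normalize a response to a token sequence
#'
#' Parenthetical material is removed before tokenization (participants are
#' instructed to omit it, so parenthetical echoes of the prompt are not
#' scored), the text is lowercased, the lexicon's contraction rules are
#' applied in order ("it'll" becomes "it will", "gonna" becomes
#' "going to"), and the result is split into word tokens on
#' non-alphanumeric characters.
#'
#' @param text A single character string.
#' @param lexicon An [ftr_lexicon()] supplying the contraction map.
#' @return Character vector of tokens (possibly empty).
#' @export
normalize_text <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\([^)]*\\)", " ", text)
  s <- tolower(s)
  cm <- lexicon$contraction_map
  for (i in seq_along(cm)) {
    s <- gsub(names(cm)[i], paste0(" ", cm[[i]], " "), s, fixed = TRUE)
  }
  tokens <- strsplit(gsub("[^[:alnum:]]+", " ", s), " ", fixed = TRUE)[[1]]
  tokens[nzchar(tokens)]
}

#' Does a token sequence contain any marker?
#'
#' Single-token markers match on token equality; multiword markers (e.g.
#' "going to", "staat op het punt") must occur as a contiguous
#' subsequence.
#'
#' @param tokens Character vector of tokens.
#' @param markers List of marker token sequences (as stored in an
#'   [ftr_lexicon()], e.g. `lexicon$future_tokens`) or a character vector
#'   of phrases.
#' @return `TRUE` or `FALSE`.
#' @export
contains_marker <- function(tokens, markers) {
  if (is.character(markers)) {
    markers <- strsplit(tolower(markers), " ", fixed = TRUE)
  }
  n <- length(tokens)
  for (m in markers) {
    len <- length(m)
    if (len == 0 || len > n) next
    if (len == 1) {
      if (m %in% tokens) return(TRUE)
    } else {
      starts <- which(tokens == m[1])
      starts <- starts[starts + len - 1 <= n]
      for (s in starts) {
        if (all(tokens[s:(s + len - 1)] == m)) return(TRUE)
      }
    }
  }
  FALSE
}

.present_forms_vector <- function(present_forms) {
  if (is.list(present_forms)) present_forms <- present_forms[[1]]
  if (length(present_forms) == 1 && grepl(";", present_forms)) {
    present_forms <- strsplit(present_forms, ";", fixed = TRUE)[[1]]
  }
  tolower(trimws(present_forms))
}

#' Classify one elicited response
#'
#' Applies the future/present class schema with modal dominance. The item
#' supplies the admissible present-tense surface forms of its target verb,
#' so present-tense detection is item-driven rather than a general
#' morphological parse.
#'
#' @param text The participant's free-text response.
#' @param item A single-row list/tibble with at least `language`,
#'   `present_forms` (character vector, list column, or
#'   semicolon-separated string) and optionally `excluded`.
#' @param lexicon The [ftr_lexicon()] for the item's language.
#' @return Named integer vector `c(future = 0/1, present = 0/1)`; the two
#'   classes are mutually exclusive and both are 0 whenever a modal marker
#'   occurs.
#' @export
classify_response <- function(text, item, lexicon) {
  if (isTRUE(item$excluded)) {
    stop("cannot classify a response to an excluded item", call. = FALSE)
  }
  if (!identical(tolower(item$language[[1]]), lexicon$language)) {
    stop("item language '", item$language[[1]],
         "' does not match lexicon language '", lexicon$language, "'",
         call. = FALSE)
  }
  tokens <- normalize_text(text, lexicon)
  has_modal <- contains_marker(tokens, lexicon$modal_tokens)
  has_future <- contains_marker(tokens, lexicon$future_tokens)
  future <- as.integer(has_future && !has_modal)
  present <- 0L
  if (!has_modal && future == 0L) {
    forms <- .present_forms_vector(item$present_forms)
    present <- as.integer(any(forms %in% tokens))
  }
  c(future = future, present = present)
}

.check_items <- function(items) {
  required <- c("item_id", "language", "present_forms", "excluded")
  missing <- setdiff(required, names(items))
  if (length(missing) > 0) {
    stop("items table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("items table has duplicated item_id values", call. = FALSE)
  }
  invisible(items)
}

#' Classify a table of responses
#'
#' @param responses Tibble with `participant_id`, `item_id`, `text`.
#' @param items Item metadata tibble (see [default_elicitation_items()]);
#'   excluded items are dropped before scoring.
#' @param lexicon The [ftr_lexicon()] matching the items' language.
#' @return Tibble `participant_id`, `item_id`, `future`, `present`, one
#'   row per scorable response.
#' @export
classify_responses <- function(responses, items, lexicon) {
  .check_items(items)
  required <- c("participant_id", "item_id", "text")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0) {
    stop("responses missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(responses$item_id, items$item_id)
  if (length(unknown) > 0) {
    stop("response item(s) not in items table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(responses$participant_id, responses$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, item_id) responses", call. = FALSE)
  }
  idx <- match(responses$item_id, items$item_id)
  keep <- !items$excluded[idx]
  responses <- responses[keep, , drop = FALSE]
  idx <- idx[keep]
  scores <- t(vapply(seq_len(nrow(responses)), function(i) {
    classify_response(responses$text[i], items[idx[i], , drop = FALSE],
                      lexicon)
  }, c(future = 0L, present = 0L)))
  tibble::tibble(
    participant_id = responses$participant_id,
    item_id = responses$item_id,
    future = scores[, "future"],
    present = scores[, "present"]
  )
}

#' Per-participant future- and present-tense proportions
#'
#' Scores every non-excluded response and aggregates to the participant
#' level: the proportion of scorable responses classed future tense and
#' present tense. Participants whose responses are all to excluded items
#' have no scorable data and are absent from the result (missing, not
#' zero).
#'
#' @inheritParams classify_responses
#' @return Tibble `participant_id`, `fut_proportion`, `pres_proportion`,
#'   `n_scored`.
#' @export
score_participants <- function(responses, items, lexicon) {
  scored <- classify_responses(responses, items, lexicon)
  if (nrow(scored) == 0) {
    stop("no scorable responses (all items excluded?)", call. = FALSE)
  }
  pieces <- split(seq_len(nrow(scored)),
                  factor(scored$participant_id,
                         levels = unique(scored$participant_id)))
  tibble::tibble(
    participant_id = names(pieces),
    fut_proportion = vapply(pieces, function(i) mean(scored$future[i]),
                            numeric(1), USE.NAMES = FALSE),
    pres_proportion = vapply(pieces, function(i) mean(scored$present[i]),
                             numeric(1), USE.NAMES = FALSE),
    n_scored = vapply(pieces, length, integer(1), USE.NAMES = FALSE)
  )
}

#' Compare predicted scores against gold labels
#'
#' Computes per-class accuracy, precision and recall from the confusion
#' matrix of predicted vs. gold binary scores, aligned on
#' (participant_id, item_id).
#'
#' @param predicted,gold Tibbles with `participant_id`, `item_id`,
#'   `future`, `present`. The two key sets must coincide.
#' @return Tibble with one row per class (`future`, `present`) and columns
#'   `accuracy`, `precision`, `recall` (precision/recall are `NaN` when
#'   undefined).
#' @export
validate_against_labels <- function(predicted, gold) {
  kp <- paste(predicted$participant_id, predicted$item_id, sep = "\r")
  kg <- paste(gold$participant_id, gold$item_id, sep = "\r")
  if (anyDuplicated(kp) || anyDuplicated(kg)) {
    stop("duplicated (participant_id, item_id) keys", call. = FALSE)
  }
  if (length(kp) != length(kg) || !setequal(kp, kg)) {
    stop("predicted and gold labels are not aligned on the same ",
         "(participant_id, item_id) keys", call. = FALSE)
  }
  gold <- gold[match(kp, kg), , drop = FALSE]
  one_class <- function(p, g) {
    tp <- sum(p == 1 & g == 1)
    fp <- sum(p == 1 & g == 0)
    fn <- sum(p == 0 & g == 1)
    c(accuracy = mean(p == g), precision = tp / (tp + fp),
      recall = tp / (tp + fn))
  }
  fut <- one_class(predicted$future, gold$future)
  pres <- one_class(predicted$present, gold$present)
  tibble::tibble(
    class = c("future", "present"),
    accuracy = c(fut[["accuracy"]], pres[["accuracy"]]),
    precision = c(fut[["precision"]], pres[["precision"]]),
    recall = c(fut[["recall"]], pres[["recall"]])
  )
}
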