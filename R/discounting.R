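# Hyperbolic discounting: candidate enumeration and best-match k fitting.

#' Hyperbolic present value of a delayed reward
#'
#' The subjective value of an amount `A` delivered after delay `D` under a
#' hyperbolic discount rate `k` is `V = A / (1 + k * D)`. Larger `k` means
#' steeper devaluation of delayed rewards.
#'
#' @param A Amount (currency units), positive.
#' @param k Per-week discount rate, nonnegative.
#' @param D Delay in weeks, nonnegative.
#' @return Discounted value, same length as the longest argument.
#' @examples
#' hyperbolic_value(10, 0.1, 10) # 5
#' @export
hyperbolic_value <- function(A, k, D) {
  stopifnot(is.numeric(A), is.numeric(k), is.numeric(D))
  if (any(A <= 0)) stop("A must be positive", call. = FALSE)
  if (any(k < 0)) stop("k must be nonnegative", call. = FALSE)
  if (any(D < 0)) stop("D must be nonnegative", call. = FALSE)
  A / (1 + k * D)
}

#' Indifference discount rate for one choice item
#'
#' The unique rate `k` at which the hyperbolic value of the larger-later
#' reward equals the smaller-sooner reward: `k = (llr/ssr - 1) / D`. The
#' amount ratio is unitless, so the currency cancels.
#'
#' @param ssr Smaller-sooner amount, `0 < ssr <= llr`.
#' @param llr Larger-later amount.
#' @param D Delay in weeks, positive.
#' @return Per-week indifference rate (0 when `ssr == llr`).
#' @export
indifference_k <- function(ssr, llr, D) {
  stopifnot(is.numeric(ssr), is.numeric(llr), is.numeric(D))
  if (any(ssr <= 0)) stop("ssr must be positive", call. = FALSE)
  if (any(ssr > llr)) stop("ssr must not exceed llr", call. = FALSE)
  if (any(D <= 0)) stop("D must be positive", call. = FALSE)
  (llr / ssr - 1) / D
}

#' Candidate discount rates of a battery
#'
#' One indifference rate per item, de-duplicated within an absolute
#' tolerance (crossed batteries can produce numerically identical
#' indifference points) and returned in ascending order. Within a duplicate
#' group the smallest member is kept.
#'
#' @param battery A battery tibble (see [choice_battery()]).
#' @param tol Absolute de-duplication tolerance. Default `1e-12`.
#' @return Sorted numeric vector of unique candidate rates.
#' @export
candidate_ks <- function(battery, tol = 1e-12) {
  .check_battery(battery)
  ks <- sort(indifference_k(battery$ssr_amount, battery$llr_amount,
                            battery$delay_weeks))
  ks[c(TRUE, diff(ks) > tol)]
}

#' Predict the choice a hyperbolic discounter makes on an item
#'
#' The smaller-sooner reward is chosen when it strictly exceeds the
#' discounted larger-later reward; exact indifference yields the
#' larger-later reward.
#'
#' @param item One battery row (list or single-row data frame with
#'   `ssr_amount`, `llr_amount`, `delay_weeks`).
#' @param k Per-week discount rate, nonnegative (vectorised).
#' @return Character vector of `"SSR"`/`"LLR"`.
#' @export
predict_choice <- function(item, k) {
  stopifnot(is.numeric(k))
  if (any(k < 0)) stop("k must be nonnegative", call. = FALSE)
  v <- hyperbolic_value(item$llr_amount, k, item$delay_weeks)
  ifelse(item$ssr_amount > v, "SSR", "LLR")
}

.check_observations <- function(observations, battery,
                                check_duplicates = TRUE) {
  required <- c("participant_id", "item_id", "choice")
  missing <- setdiff(required, names(observations))
  if (length(missing) > 0) {
    stop("observations missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(observations) == 0) {
    stop("at least one choice observation is required", call. = FALSE)
  }
  bad <- setdiff(unique(observations$choice), c("SSR", "LLR"))
  if (length(bad) > 0) {
    stop("choice values must be 'SSR' or 'LLR'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(observations$item_id, battery$item_id)
  if (length(unknown) > 0) {
    stop("observation item(s) not in battery: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (check_duplicates) {
    key <- paste(observations$participant_id, observations$item_id,
                 sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (participant_id, item_id) observations",
           call. = FALSE)
    }
  }
  invisible(observations)
}

#' Fit a participant's discount rate by enumeration and matching
#'
#' Every candidate rate of the battery (each item's indifference point) is
#' scored by the proportion of the participant's observed choices it
#' predicts under the hyperbolic rule; the best-matching set is retained and
#' its geometric mean reported as `k`. Because predictions depend on `k`
#' only through its position relative to each item's indifference point,
#' the candidate grid is exhaustive for this battery.
#'
#' @param observations Tibble with `participant_id`, `item_id`, `choice`
#'   (`"SSR"`/`"LLR"`), one participant only.
#' @param battery The battery the observations were collected on.
#' @param tol Candidate de-duplication tolerance passed to [candidate_ks()].
#' @return One-row tibble: `participant_id`, `k`, `log_k`,
#'   `match_proportion`, `n_tied`, `n_choices`.
#' @export
fit_k <- function(observations, battery, tol = 1e-12) {
  .check_battery(battery)
  .check_observations(observations, battery)
  pid <- unique(observations$participant_id)
  if (length(pid) != 1) {
    stop("fit_k expects observations from a single participant; got ",
         length(pid), call. = FALSE)
  }
  cands <- candidate_ks(battery, tol)
  idx <- match(observations$item_id, battery$item_id)
  ik_obs <- indifference_k(battery$ssr_amount[idx], battery$llr_amount[idx],
                           battery$delay_weeks[idx])
  obs_ssr <- observations$choice == "SSR"
  # predicted SSR iff candidate k strictly exceeds the item's indifference k
  pred_ssr <- outer(cands, ik_obs, `>`)
  match_count <- rowSums(pred_ssr == matrix(obs_ssr, nrow = length(cands),
                                            ncol = length(obs_ssr),
                                            byrow = TRUE))
  best <- which(match_count == max(match_count))
  k <- if (length(best) == 1) cands[best] else exp(mean(log(cands[best])))
  tibble::tibble(
    participant_id = pid,
    k = k,
    log_k = log(k),
    match_proportion = max(match_count) / length(obs_ssr),
    n_tied = length(best),
    n_choices = length(obs_ssr)
  )
}

#' Fit discount rates for a whole cohort
#'
#' Applies [fit_k()] to each participant and pools the proportion of
#' observed choices the fitted rates reproduce.
#'
#' @param observations Tibble of choice observations for one or more
#'   participants.
#' @param battery The battery the observations were collected on.
#' @param tol Candidate de-duplication tolerance.
#' @return An object of class `cohort_fit`: a list with `fits` (one row per
#'   participant, see [fit_k()]) and `overall_match_proportion` (pooled
#'   matched choices / total choices).
#' @export
cohort_fit <- function(observations, battery, tol = 1e-12) {
  .check_battery(battery)
  # duplicate detection is left to fit_k so the error names the participant
  .check_observations(observations, battery, check_duplicates = FALSE)
  pieces <- split(seq_len(nrow(observations)),
                  factor(observations$participant_id,
                         levels = unique(observations$participant_id)))
  fits <- lapply(names(pieces), function(pid) {
    rows <- observations[pieces[[pid]], , drop = FALSE]
    tryCatch(fit_k(rows, battery, tol), error = function(e) {
      stop("participant '", pid, "': ", conditionMessage(e), call. = FALSE)
    })
  })
  fits <- dplyr::bind_rows(fits)
  overall <- sum(fits$match_proportion * fits$n_choices) / sum(fits$n_choices)
  structure(
    list(fits = fits, overall_match_proportion = overall),
    class = "cohort_fit"
  )
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("Hyperbolic k fits for", nrow(x$fits), "participants\n")
  cat(sprintf("Overall match proportion: %.4f (%d choices)\n",
              x$overall_match_proportion, sum(x$fits$n_choices)))
  print(x$fits, ...)
  invisible(x)
}
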