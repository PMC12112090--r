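# Synthetic two-language cohorts with the path structure the analysis
# assumes: standardized future-tense use depends on language, log discount
# rate depends on language, future-tense use and their interaction; choices
# are near-hyperbolic with a symmetric flip noise; elicited text is built
# from a small within-vocabulary template grammar so the classifier can be
# round-tripped against generator ground truth.

# Published marginal means of the future-tense proportion per language,
# used to anchor the Gaussian back-transform from the standardized scale.
.fut_means <- list(
  study1 = c(english = 0.59, dutch = 0.33),
  study2 = c(english = 0.59, dutch = 0.20)
)

#' Construct generator parameters
#'
#' Holds the full parameterization of a synthetic cohort: group sizes, the
#' mediator-equation coefficients (`lambda1`, `alpha`) and residual scale
#' `sigma1` on the standardized future-tense scale, the outcome-equation
#' coefficients (`lambda2`, `tau_prime`, `beta1`, `beta2`) and residual
#' scale `sigma2` on the log-k scale, the Gaussian back-transform mapping
#' standardized future-tense use to a proportion, the choice-flip noise
#' rate, the battery, and the elicitation settings.
#'
#' @param n_english,n_dutch Cohort sizes (at least 2 each).
#' @param lambda1,alpha,sigma1 Mediator-equation intercept, language path
#'   and residual scale (standardized units); `sigma1 > 0`.
#' @param lambda2,tau_prime,beta1,beta2,sigma2 Outcome-equation intercept,
#'   direct effect, mediator slope, interaction, residual scale (log-k
#'   units); `sigma2 > 0`.
#' @param fut_grand_mean,fut_grand_sd Back-transform:
#'   `fut_proportion = clip(fut_grand_mean + fut_z * fut_grand_sd, 0, 1)`;
#'   `fut_grand_sd > 0`.
#' @param choice_noise Independent flip probability for each generated
#'   choice, in `[0, 0.5)`. Default 0.06.
#' @param battery `"study1"` or `"study2"`.
#' @param n_elicitation_items Number of elicitation items per language.
#' @param modal_injection_rate Probability a generated response carries a
#'   modal marker (and therefore scores in neither class), in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `generator_params` (a validated list).
#' @export
generator_params <- function(n_english, n_dutch, lambda1, alpha, sigma1,
                             lambda2, tau_prime, beta1, beta2, sigma2,
                             fut_grand_mean, fut_grand_sd,
                             choice_noise = 0.06, battery = "study1",
                             n_elicitation_items = 26,
                             modal_injection_rate = 0.3, seed = 1) {
  p <- list(
    n_english = as.integer(n_english), n_dutch = as.integer(n_dutch),
    lambda1 = lambda1, alpha = alpha, sigma1 = sigma1,
    lambda2 = lambda2, tau_prime = tau_prime, beta1 = beta1,
    beta2 = beta2, sigma2 = sigma2,
    fut_grand_mean = fut_grand_mean, fut_grand_sd = fut_grand_sd,
    choice_noise = choice_noise, battery = battery,
    n_elicitation_items = as.integer(n_elicitation_items),
    modal_injection_rate = modal_injection_rate, seed = as.integer(seed)
  )
  stopifnot(
    p$n_english >= 2, p$n_dutch >= 2,
    p$sigma1 > 0, p$sigma2 > 0, p$fut_grand_sd > 0,
    p$choice_noise >= 0, p$choice_noise < 0.5,
    p$modal_injection_rate >= 0, p$modal_injection_rate <= 1,
    p$n_elicitation_items >= 1
  )
  .battery_by_name(p$battery) # validates the label
  structure(p, class = "generator_params")
}

#' Default generator parameterizations for the two study designs
#'
#' Group sizes and path coefficients are the published posterior-mean
#' estimates for each study; the residual scales are calibrated once so
#' the synthetic marginal SDs approximate the published descriptive
#' statistics (see `scripts/calibrate_generator.R` in the source
#' repository), and the back-transform is solved from the per-language
#' future-tense means and the language path: `fut_grand_sd =
#' (mean_english - mean_dutch) / alpha`, `fut_grand_mean = mean_dutch -
#' lambda1 * fut_grand_sd`.
#'
#' @param study `"study1"` or `"study2"`.
#' @param seed Integer seed stored in the parameters. Default 1.
#' @return A [generator_params()] object.
#' @examples
#' default_params("study1")$alpha # 1.36
#' @export
default_params <- function(study = c("study1", "study2"), seed = 1) {
  study <- match.arg(study)
  m <- .fut_means[[study]]
  if (study == "study1") {
    lambda1 <- -0.65; alpha <- 1.36
    gs <- (m[["english"]] - m[["dutch"]]) / alpha
    generator_params(
      n_english = 113, n_dutch = 122,
      lambda1 = lambda1, alpha = alpha, sigma1 = 0.75,
      lambda2 = -3.00, tau_prime = 0.30, beta1 = 0.26, beta2 = -0.90,
      sigma2 = 1.9,
      fut_grand_mean = m[["dutch"]] - lambda1 * gs, fut_grand_sd = gs,
      battery = "study1", n_elicitation_items = 26, seed = seed
    )
  } else {
    lambda1 <- -0.75; alpha <- 1.51
    gs <- (m[["english"]] - m[["dutch"]]) / alpha
    generator_params(
      n_english = 301, n_dutch = 305,
      lambda1 = lambda1, alpha = alpha, sigma1 = 0.66,
      lambda2 = -3.82, tau_prime = 1.10, beta1 = -0.07, beta2 = -0.26,
      sigma2 = 1.38,
      fut_grand_mean = m[["dutch"]] - lambda1 * gs, fut_grand_sd = gs,
      battery = "study2", n_elicitation_items = 24, seed = seed
    )
  }
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic-cohort parameters (battery ", x$battery, "): ",
      x$n_english, " English + ", x$n_dutch, " Dutch\n", sep = "")
  cat(sprintf("  mediator: lambda1=%.2f alpha=%.2f sigma1=%.2f\n",
              x$lambda1, x$alpha, x$sigma1))
  cat(sprintf("  outcome:  lambda2=%.2f tau'=%.2f beta1=%.2f beta2=%.2f sigma2=%.2f\n",
              x$lambda2, x$tau_prime, x$beta1, x$beta2, x$sigma2))
  cat(sprintf("  back-transform: mean=%.4f sd=%.4f; choice noise=%.2f; modal rate=%.2f; seed=%d\n",
              x$fut_grand_mean, x$fut_grand_sd, x$choice_noise,
              x$modal_injection_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic two-language cohort
#'
#' Latent standardized future-tense use is drawn from
#' `N(lambda1 + alpha * lang, sigma1)` and latent log k from
#' `N(lambda2 + tau' * lang + beta1 * fut_z + beta2 * fut_z * lang,
#' sigma2)`. The future-tense proportion is the Gaussian back-transform
#' clipped to `[0, 1]`; the clip rate is attached as an attribute (and at
#' the default parameters stays below 1%).
#'
#' @param params A [generator_params()] object.
#' @return Tibble with `participant_id`, `language`, `language_indicator`,
#'   `fut_z_latent`, `fut_proportion`, `log_k_latent`, `k_latent`; the
#'   proportion clip rate is in `attr(, "clip_rate")`.
#' @export
gen_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n_english + params$n_dutch
  lang <- rep(c(1, 0), c(params$n_english, params$n_dutch))
  fut_z <- stats::rnorm(n, params$lambda1 + params$alpha * lang,
                        params$sigma1)
  log_k <- stats::rnorm(
    n,
    params$lambda2 + params$tau_prime * lang + params$beta1 * fut_z +
      params$beta2 * fut_z * lang,
    params$sigma2
  )
  raw_prop <- params$fut_grand_mean + fut_z * params$fut_grand_sd
  clipped <- raw_prop < 0 | raw_prop > 1
  out <- tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    language = ifelse(lang == 1, "english", "dutch"),
    language_indicator = lang,
    fut_z_latent = fut_z,
    fut_proportion = pmin(pmax(raw_prop, 0), 1),
    log_k_latent = log_k,
    k_latent = exp(log_k)
  )
  attr(out, "clip_rate") <- mean(clipped)
  out
}

#' Generate near-hyperbolic choice observations for a cohort
#'
#' Each participant's choice on each battery item is the hyperbolic
#' prediction at their latent `k`, flipped independently with probability
#' `choice_noise`.
#'
#' @param cohort A [gen_cohort()] tibble (or any tibble with
#'   `participant_id` and `k_latent`).
#' @param battery A battery tibble.
#' @param choice_noise Flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Tibble `participant_id`, `item_id`, `choice`.
#' @export
gen_choices <- function(cohort, battery, choice_noise = 0.06, seed = 1) {
  .check_battery(battery)
  stopifnot(all(cohort$k_latent > 0), choice_noise >= 0, choice_noise < 0.5)
  set.seed(seed)
  ik <- indifference_k(battery$ssr_amount, battery$llr_amount,
                       battery$delay_weeks)
  n_p <- nrow(cohort)
  n_i <- nrow(battery)
  # predicted SSR iff k strictly exceeds the item's indifference point
  pred_ssr <- outer(cohort$k_latent, ik, `>`)
  flip <- matrix(stats::runif(n_p * n_i) < choice_noise, n_p, n_i)
  ssr <- xor(pred_ssr, flip)
  tibble::tibble(
    participant_id = rep(cohort$participant_id, each = n_i),
    item_id = rep(battery$item_id, times = n_p),
    choice = ifelse(as.vector(t(ssr)), "SSR", "LLR")
  )
}

# Template verb banks. Each row: subject, infinitive, third-person-singular
# present form, and a tail adverbial. Dutch future-tense templates place
# the infinitive clause-finally ("ze zal de wedstrijd winnen").
.verb_bank <- list(
  english = data.frame(
    subject = c("it", "it", "she", "he", "the team", "the market",
                "she", "he", "the shop", "she", "the family", "the show",
                "he"),
    infinitive = c("rain", "snow", "win", "drive", "play", "crash",
                   "arrive", "leave", "open", "call", "move", "start",
                   "finish"),
    present = c("rains", "snows", "wins", "drives", "plays", "crashes",
                "arrives", "leaves", "opens", "calls", "moves", "starts",
                "finishes"),
    tail = c("tomorrow", "next week", "the race", "to the store",
             "on sunday", "within two years", "in one year",
             "in six months", "in ten years", "later today", "next year",
             "in two years", "the project soon"),
    stringsAsFactors = FALSE
  ),
  dutch = data.frame(
    subject = c("het", "het", "ze", "hij", "het team", "de markt", "ze",
                "hij", "de winkel", "ze", "de familie", "de show", "hij"),
    infinitive = c("regenen", "sneeuwen", "winnen", "rijden", "spelen",
                   "dalen", "komen", "vertrekken", "openen", "bellen",
                   "verhuizen", "beginnen", "stoppen"),
    present = c("regent", "sneeuwt", "wint", "rijdt", "speelt", "daalt",
                "komt", "vertrekt", "opent", "belt", "verhuist", "begint",
                "stopt"),
    tail = c("morgen", "volgende week", "de wedstrijd", "naar de winkel",
             "op zondag", "binnen twee jaar", "over een jaar",
             "over zes maanden", "over tien jaar", "later vandaag",
             "volgend jaar", "over twee jaar", "binnenkort"),
    stringsAsFactors = FALSE
  )
)

.modal_adverbs <- list(
  english = c("maybe", "possibly", "probably", "perhaps"),
  dutch = c("misschien", "mogelijk", "waarschijnlijk", "zeker")
)

.distance_levels <- c("later today", "tomorrow", "one week", "six months",
                      "one year", "two years", "ten years", "25+ years",
                      "indeterminate", "ongoing")
.modality_levels <- c("high-certainty", "low-certainty", "neutral")
.mode_levels <- c("prediction", "intention")

#' Built-in elicitation items for a language
#'
#' Items are drawn (with recycling) from a small bank of target verbs,
#' each with its third-person-singular present form; the within-subjects
#' factor levels (distance, modality condition, FTR mode) are carried as
#' metadata and assigned cyclically. They do not modulate generation.
#'
#' @param language `"english"` or `"dutch"`.
#' @param n Number of items.
#' @return Tibble of item metadata: `item_id`, `language`,
#'   `context_text`, `target_verb_lemma`, `present_forms`
#'   (semicolon-separated), `distance_category`, `modality_condition`,
#'   `ftr_mode`, `excluded`, plus the template columns `subject`,
#'   `infinitive`, `tail` used by [gen_elicitation()].
#' @export
default_elicitation_items <- function(language = c("english", "dutch"),
                                      n = 26) {
  language <- match.arg(language)
  stopifnot(n >= 1)
  bank <- .verb_bank[[language]]
  idx <- rep_len(seq_len(nrow(bank)), n)
  tibble::tibble(
    item_id = sprintf("%s_item%02d", substr(language, 1, 3), seq_len(n)),
    language = language,
    context_text = sprintf("Context %d: a future event involving '%s'.",
                           seq_len(n), bank$infinitive[idx]),
    target_verb_lemma = bank$infinitive[idx],
    present_forms = bank$present[idx],
    distance_category = rep_len(.distance_levels, n),
    modality_condition = rep_len(.modality_levels, n),
    ftr_mode = rep_len(.mode_levels, n),
    excluded = FALSE,
    subject = bank$subject[idx],
    infinitive = bank$infinitive[idx],
    tail = bank$tail[idx]
  )
}

.render_response <- function(item, language, is_future, go_form, modal) {
  if (language == "english") {
    text <- if (is_future) {
      aux <- if (go_form) "is going to" else "will"
      paste(item$subject, aux, item$infinitive, item$tail)
    } else {
      paste(item$subject, item$present_forms, item$tail)
    }
  } else {
    text <- if (is_future) {
      aux <- if (go_form) "gaat" else "zal"
      paste(item$subject, aux, item$tail, item$infinitive)
    } else {
      paste(item$subject, item$present_forms, item$tail)
    }
  }
  if (!is.na(modal)) text <- paste(modal, text)
  paste0(toupper(substr(text, 1, 1)), substr(text, 2, nchar(text)), ".")
}

#' Generate elicited responses (with ground-truth labels) for a cohort
#'
#' For each participant and item, a future-marked sentence is emitted with
#' probability equal to the participant's `fut_proportion` (using either
#' the "will"/"zal" or the "going to"/"gaat" construction), otherwise a
#' present-tense sentence using the item's present form. Independently,
#' with probability `modal_injection_rate`, a modal adverb is prepended,
#' which by the class schema forces both ground-truth scores to 0.
#'
#' @param cohort A [gen_cohort()] tibble (needs `participant_id`,
#'   `language`, `fut_proportion`); only participants whose language
#'   matches the items' language are used.
#' @param items An item tibble from [default_elicitation_items()].
#' @param lexicon Unused by generation itself (the templates are
#'   within-vocabulary by construction) but accepted so call sites can
#'   pass the language bundle around; may be `NULL`.
#' @param modal_injection_rate Probability of modal injection per
#'   response.
#' @param seed Integer seed.
#' @return List with `responses` (`participant_id`, `item_id`, `text`)
#'   and `truth` (`participant_id`, `item_id`, `future`, `present`).
#' @export
gen_elicitation <- function(cohort, items, lexicon = NULL,
                            modal_injection_rate = 0.3, seed = 1) {
  .check_items(items)
  language <- unique(items$language)
  stopifnot(length(language) == 1,
            modal_injection_rate >= 0, modal_injection_rate <= 1)
  cohort <- cohort[cohort$language == language, , drop = FALSE]
  if (nrow(cohort) == 0) {
    stop("cohort has no participants for language '", language, "'",
         call. = FALSE)
  }
  set.seed(seed)
  n_p <- nrow(cohort)
  n_i <- nrow(items)
  total <- n_p * n_i
  is_future <- stats::runif(total) < rep(cohort$fut_proportion, each = n_i)
  go_form <- stats::runif(total) < 0.5
  inject <- stats::runif(total) < modal_injection_rate
  modal <- rep(NA_character_, total)
  modal[inject] <- sample(.modal_adverbs[[language]], sum(inject),
                          replace = TRUE)
  item_idx <- rep(seq_len(n_i), times = n_p)
  text <- vapply(seq_len(total), function(j) {
    .render_response(items[item_idx[j], , drop = FALSE], language,
                     is_future[j], go_form[j], modal[j])
  }, character(1))
  ids <- rep(cohort$participant_id, each = n_i)
  responses <- tibble::tibble(
    participant_id = ids,
    item_id = items$item_id[item_idx],
    text = text
  )
  truth <- tibble::tibble(
    participant_id = ids,
    item_id = items$item_id[item_idx],
    future = as.integer(is_future & !inject),
    present = as.integer(!is_future & !inject)
  )
  list(responses = responses, truth = truth)
}
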