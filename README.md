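# ftrk

Does habitual use of the grammatical future tense change how steeply
people discount delayed rewards? `ftrk` is an R package for researchers
in psycholinguistics and behavioural economics who want to test this at
the level of individual speakers in two-language (English/Dutch)
cohorts. It implements the complete analysis chain:

1. **Sentence scoring** — a deterministic closed-vocabulary classifier
   assigns each elicited sentence a binary future-tense and
   present-tense score, with *modal dominance*: any modal word (*might*,
   *possibly*, *zeker*, …) suppresses both classes, because *It will
   possibly rain tomorrow* is no longer a high-certainty future-marked
   prediction. Per participant, the proportions FUT and PRES of scorable
   responses are the language-use measures.
2. **Discount-rate estimation** — each participant's hyperbolic discount
   rate is fitted from binary choices between a smaller-sooner reward
   (SSR, now) and a larger-later reward (LLR, after delay *D* weeks).
   Subjective value follows *V = A / (1 + kD)*. Every battery item
   contributes a candidate *k* at indifference, *k* =
   (LLR/SSR − 1)/*D*; the candidate best matching the participant's
   observed choices is retained, with geometric-mean resolution of ties.
3. **Bayesian moderated mediation** — with `lang` coded English = 1,
   Dutch = 0 and `fut` the z-scaled future-tense proportion:

       fut    = λ1 + α·lang + e1
       log(k) = λ2 + τ′·lang + β1·fut + β2·fut·lang + e2

   sampled exactly from the flat-prior conjugate posterior. The
   conditional indirect effect α(β1 + β2·lang) — and its counterfactual
   combinations across languages — is summarized with posterior means,
   90%/95% credibility intervals, posterior sign probabilities (*pp*)
   and Bayesian R².
4. **Synthetic cohorts** — a seeded generator reproduces the two study
   designs' group sizes, path coefficients, marginal means,
   near-hyperbolic choice behaviour (6% flip noise) and
   classifier-exercising elicitation text, so the whole pipeline is
   testable end to end without participant data.

See `vignettes/ftrk-methods.Rmd` for the model details, parameter
defaults and their provenance, and known limitations.

## Worked example

Fit a discount rate for one simulated responder on the second battery
(8 amounts × 8 delays = 64 items), then run the full pipeline on a
simulated first-design cohort:

```r
library(ftrk)

battery <- study2_battery()
ik <- indifference_k(battery$ssr_amount, battery$llr_amount, battery$delay_weeks)
obs <- tibble::tibble(participant_id = "p01", item_id = battery$item_id,
                      choice = ifelse(0.02 > ik, "SSR", "LLR"))
fit_k(obs, battery)
#>   participant_id      k log_k match_proportion n_tied n_choices
#> 1 p01            0.0203 -3.90                1      1        64
```

A responder choosing from a true rate of 0.02/week fits to the nearest
battery candidate (0.0203, log k = −3.90) and every choice is matched.

```r
res <- run_pipeline(list(study = "study1", seed = 42))
res$coefficients
#>   path      equation estimate     se ci95_lower ci95_upper
#> 1 lambda1   mediator  -0.606  0.0713     -0.744     -0.465
#> 2 alpha     mediator   1.26   0.103       1.06       1.46
#> 3 lambda2   outcome   -3.02   0.227      -3.47      -2.58
#> 4 tau_prime outcome    0.157  0.322      -0.468      0.781
#> 5 beta1     outcome    0.0284 0.244      -0.460      0.506
#> 6 beta2     outcome   -0.430  0.319      -1.04       0.216

res$indirect[, c("alpha_source", "beta_source", "est",
                 "ci90_lower", "ci90_upper", "pp")]
#>   alpha_source beta_source     est ci90_lower ci90_upper    pp
#> 1 dutch        dutch       -0.0173    -0.258      0.226  0.548
#> 2 english      dutch        0.0356    -0.478      0.538  0.452
#> 3 dutch        english      0.244      0.0344     0.465  0.024
#> 4 english      english     -0.507     -0.952     -0.0763 0.976

res$provenance$overall_match_proportion
#> [1] 0.9404
```

English speakers in the simulated cohort use the future tense more
(α ≈ 1.26 standardized units), and the English-conditioned indirect
effect of language on discounting via future-tense use is negative
(est ≈ −0.51, pp ≈ 0.98): more habitual future marking goes with *less*
discounting, the signature of the high-certainty (modal) account. The
fitted rates reproduce 94% of the simulated choices. `res$descriptives`
and `res$correlations` hold the per-language summary tables;
`run_pipeline(config, out_dir = "out")` writes everything as TSV/JSON
with full seed provenance.

A thin command-line interface over the same functions ships in
`inst/cli/ftrk` (`simulate`, `classify`, `fitk`, `mediate`, `report`,
`run`).

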