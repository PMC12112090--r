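---
title: "Methods: future-tense use and temporal discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: future-tense use and temporal discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftrk)
```

## The scientific question

Languages differ in whether they oblige a grammatical future tense when
speakers talk about future events: English predictions require *will*,
*be going to* or *shall*, while Dutch freely permits the present tense
(*Morgen regent het*, 'Tomorrow it rains'). A long-standing hypothesis in
behavioural economics holds that obligatory future marking makes future
events feel more distant and therefore makes speakers devalue delayed
rewards more steeply ("temporal discounting"). The competing modal view
holds that future tenses encode *high certainty*, which predicts the
opposite sign: more habitual future-tense use should go with *less*
discounting.

`ftrk` implements the full analysis chain needed to test this at the
level of individual speakers: (1) score each participant's elicited
sentences for future- and present-tense use with a deterministic
closed-vocabulary classifier; (2) estimate each participant's hyperbolic
discount rate $k$ from a battery of binary intertemporal choices; (3)
relate the two with a Bayesian moderated mediation model in which
language (English = 1, Dutch = 0) predicts future-tense use, which in
turn predicts $\log_e k$, with the mediator slope allowed to differ by
language. A synthetic-cohort generator with the same path structure makes
every stage testable without participant data.

## Sentence classification

Elicited responses are scored against a closed vocabulary per language
(shipped as editable files, see `default_lexicon()`):

* **future tense = 1** if the response contains a future marker (English
  *will*, *'ll*, *shall*, *going to*, *gonna*, *about to*; Dutch *zal* /
  *zult* / *zullen*, *ga* / *gaat* / *gaan*, *staat op het punt*) and no
  modal marker;
* **present tense = 1** if the response is not future, contains no modal
  marker, and conjugates the item's target verb in one of the
  present-tense surface forms listed for that item;
* any modal marker — high- or low-certainty alike (*might*, *may*,
  *possibly*, *definitely*, *certainly*, …; *kunnen*, *zou*, *misschien*,
  *mogelijk*, *zeker*, …) — suppresses **both** classes ("modal
  dominance"): in *It will possibly rain tomorrow* the low-certainty
  semantics of *possibly* dominate *will*, so the sentence is evidence of
  neither high-certainty future marking nor plain present-tense use.

Normalization lowercases, removes parenthetical material (participants
are instructed to omit it, so parenthetical echoes of the prompt must not
be scored), expands contractions (*it'll* → *it will*, *won't* → *will
not*, *gonna* → *going to*), and tokenizes on non-alphanumeric
characters. Multiword markers match as contiguous token subsequences, so
*is/are/am going to* all match the *going to* entry. Negation does not
remove future marking: *It won't rain* is still a future-marked
prediction. Present-tense detection is item-driven (each item lists its
admissible present forms) rather than a morphological parse; this mirrors
the fact that the elicitation design fixes the target verb per item, and
keeps the classifier fully deterministic.

Two reconstruction choices deserve note. The published vocabulary lists
are exemplary ("e.g."), so the shipped lists are an explicit superset
that users can edit — they are data files, not code. And temporal
adverbials alone (without an auxiliary) do *not* mark future here: no
adverbial list was ever published, and admitting bare adverbials would
make the class depend on an unstated vocabulary. Both choices are
overridable through the lexicon files.

Per participant, `score_participants()` reports the proportion of
scorable (non-excluded) responses classed future and present. A
participant whose responses are all to excluded items is reported as
missing, never as zero.

## Discount-rate estimation

Each intertemporal choice offers a smaller-sooner reward (SSR) now
against a larger-later reward (LLR, always 10 currency units) after a
delay $D$. Subjective value follows the hyperbolic form

$$V = \frac{A}{1 + kD},$$

with $k$ the per-week discount rate. For every battery item the
*indifference rate* $k = (\mathrm{LLR}/\mathrm{SSR} - 1)/D$ makes the
discounted LLR exactly equal the SSR; the set of all items'
indifference rates is the candidate grid. A candidate $k$ predicts SSR
on an item exactly when it exceeds that item's indifference rate (ties
predict LLR, reading the choice rule's strict inequality literally), so
the grid is exhaustive: every achievable prediction vector on the
battery is realized by some candidate. `fit_k()` scores every candidate
by its proportion of matches against the participant's observed choices,
retains the best-matching set, and reports its geometric mean (a single
best candidate is returned exactly). Identical indifference rates
arising from the crossed design are collapsed (absolute tolerance
1e-12) before tie counting.

Delays are converted to weeks with 1 day = 1/7 week, 1 month =
365.25/12 days, 1 year = 365.25 days. This convention is pinned down by
the second study's battery (amounts 7.50–9.25 by 0.25; delays 2 weeks to
4½ months): its candidate extremes are
$\ln[(10/7.50 - 1)/2] \approx -1.79$ and
$\ln[(10/9.25 - 1)/(4.5 \times 4.3482)] \approx -5.49$, which are
exactly the floor and ceiling the fitted $\log_e k$ distribution must
have, since fitted rates are geometric means of candidates. The first
study's published $\log_e k$ extremes are *not* reproducible under this
(or any single) unit convention we could construct, so the convention is
validated against the second battery only; this is a documented
limitation, not a configurable option.

```{r}
ks <- candidate_ks(study2_battery())
round(log(range(ks)), 2)
```

## The mediation model

With $\mathrm{fut}_i$ the standardized future-tense proportion and
$\mathrm{lang}_i \in \{0, 1\}$:

$$\mathrm{fut}_i = \lambda_1 + \alpha\,\mathrm{lang}_i + e_{1i}, \qquad
\log_e(k)_i = \lambda_2 + \tau'\,\mathrm{lang}_i +
\beta_1\,\mathrm{fut}_i + \beta_2\,\mathrm{fut}_i\,\mathrm{lang}_i +
e_{2i}.$$

Scaling follows the published coefficient tables: the mediator is
z-scaled over the pooled sample (as outcome and as predictor, with the
interaction formed *after* scaling), the language indicator stays 0/1,
and $\log_e k$ stays on its natural scale. Under these choices
$\lambda_1$ is the standardized Dutch mean, $\alpha$ the standardized
English–Dutch gap, and $\lambda_2$ the Dutch mean of $\log_e k$;
z-scaling the binary indicator instead would halve $\alpha$ and is
inconsistent with the published table.

Both equations are normal linear models with improper flat priors, so
the exact joint posterior is available in closed form: the residual
variance has a scaled inverse-$\chi^2$ marginal with $n - p$ degrees of
freedom and the coefficients are conditionally multivariate normal
around the least-squares solution. `sample_posterior()` draws directly
from this posterior (default 4,000 draws), which is distributionally
identical to a converged MCMC run under the same priors, exactly
seedable, and free of convergence diagnostics. The two equations share
no parameters and are sampled independently.

The indirect effect of language on discounting via future-tense use is
conditional on language because of the interaction:
$\alpha(\beta_1 + \beta_2\,\mathrm{lang})$. For parity the a-term is
also conditioned by language — $\alpha$ for English, the future-tense
intercept $\lambda_1$ for Dutch — giving four combinations; the two
off-diagonal ones are counterfactuals (e.g. Dutch levels of future-tense
use combined with the English slope of discounting over future-tense
use). `conditional_indirect()` forms the product per posterior draw;
`mediation_summary()` reports the posterior mean, central 90% and 95%
credibility intervals (equal-tail quantiles, not HPD — the posteriors
here are symmetric and equal-tail matches the convention of the
reporting software family), and the posterior sign probability *pp*, the
fraction of draws whose sign matches the directional hypothesis.
`point_indirect()` exposes the product of point estimates separately,
for reproducing published table arithmetic. Bayesian $R^2$ is computed
per draw as the variance of the linear predictor over that variance plus
the residual variance.

```{r}
# published Study 1 posterior means: alpha = 1.36, beta1 = 0.26, beta2 = -0.90
point_indirect(alpha = 1.36, beta1 = 0.26, beta2 = -0.90)
```

Demographic covariates are omitted by default (the published sensitivity
analyses report they change nothing substantive); the design-matrix
interface accepts extra columns if needed.

## The synthetic-data generator

`default_params()` stores one parameterization per study design: the
published group sizes (113/122 and 301/305), the published posterior-mean
path coefficients, and four quantities the publications do not print,
fixed once as follows.

* **Back-transform.** The generator works on the standardized mediator
  scale; mapping to a proportion uses
  $\mathrm{fut} = \mathrm{clip}(\mathrm{gm} + \mathrm{gs}\cdot
  \mathrm{fut}_z,\, 0, 1)$ with
  $\mathrm{gs} = (\bar{f}_{\mathrm{eng}} - \bar{f}_{\mathrm{dut}})/\alpha$
  and $\mathrm{gm} = \bar{f}_{\mathrm{dut}} - \lambda_1 \mathrm{gs}$,
  so the latent group means land exactly on the published per-language
  future-tense means (0.59/0.33 and 0.59/0.20). Clipping keeps the
  linear path structure exactly recoverable (a Beta law would not); the
  clip rate is logged and stays below 1% at the defaults.
* **Residual scales.** $\sigma_1 = 0.75$, $\sigma_2 = 1.9$ (first
  design) and $\sigma_1 = 0.66$, $\sigma_2 = 1.38$ (second) were
  calibrated once against the published per-language SDs via
  $\mathrm{SD}(\mathrm{fut}\,|\,\mathrm{lang}) = \sigma_1 \mathrm{gs}$
  and $\mathrm{Var}(\log k\,|\,\mathrm{dut}) = \beta_1^2\sigma_1^2 +
  \sigma_2^2$ (`scripts/calibrate_generator.R` reproduces the
  derivation and a Monte-Carlo check). They are config-overridable and
  were not revisited afterwards.
* **Choice noise** $\varepsilon = 0.06$: each generated choice is the
  hyperbolic prediction at the participant's latent $k$, flipped
  independently with probability $\varepsilon$. A symmetric flip is the
  simplest noise model consistent with the published refit consistency
  (93–94% of choices correctly predicted): since refitting can only meet
  or exceed the generating rate's own agreement, $\varepsilon = 0.06$
  brackets that range. No lapse asymmetry or drift is modelled.
* **Modal injection rate** 0.3: generated responses carry a modal adverb
  with this probability (forcing both ground-truth scores to 0). The
  published future + present proportions per language leave roughly
  27–35% of responses in neither class; 0.3 is the midpoint, chosen
  once.

Elicitation text comes from a small per-language template grammar
(subject + *will*/*is going to* + infinitive, or *zal*/*gaat* with the
infinitive clause-final, versus the item's present form), optionally
prefixed by a modal adverb. It is a fixture generator that exercises
every classifier rule — multiword markers, inflection entries, modal
dominance — not a model of linguistic variation: real responses vary in
word order, spelling, adverbials and copied prompt material that the
templates never produce. Item-level factors (temporal distance, modality
condition, prediction vs intention) are carried as metadata but do not
modulate generation. Consequently, a perfect classifier round-trip on
synthetic text shows the schema is implemented exactly as specified; it
does not estimate accuracy on human text (the published human-rater
validation reported accuracy above .96 on real responses, which cannot
be reproduced without that corpus).

## Numerical choices and degenerate inputs

* Candidate de-duplication tolerance 1e-12 (absolute); the smallest
  member of a duplicate group is kept, which preserves the
  tie-goes-to-LLR rule under floating-point jitter.
* Exact indifference predicts LLR (strict inequality in the choice
  rule); a single best candidate is returned exactly rather than through
  `exp(mean(log(k)))`.
* `zscale()` rejects constant input; the mediation fit rejects
  single-language input, rank-deficient designs (naming the offending
  column) and unstandardized mediators.
* Quartiles use linear interpolation between order statistics
  (`quantile` type 7); the MAD uses the 1.4826 normal-consistency
  constant — both are the conventions of the statistical software family
  the descriptive tables follow, and both are exposed as arguments
  because the tables do not state them.
* Participants missing either task are dropped listwise from the join,
  with counts logged; nothing is imputed.
* The pipeline writes no timestamps into result files, so identical
  config and seed reproduce byte-identical artifacts; provenance carries
  the seed and a config hash instead.

## Problem sizes used in the test suite

The suite exercises the discounting grid exhaustively (all 148 battery
candidates across both designs), the classifier round trip across both
languages, three seeds and three modal-injection rates, and the
mediation machinery at the first design's sample size (235) with 200
replicate cohorts at 1,000 posterior draws each — enough that the
Monte-Carlo error of a coverage estimate (~1.5%) is small against the
margins being checked. Interval calibration of the sampler uses 200
replicates of a 60-row, 3-column fixture. These sizes were chosen so the
whole suite runs in well under a minute while keeping every stochastic
assertion comfortably away from its threshold.

## Known limitations

* The classifier is a closed-vocabulary matcher: misspellings, unlisted
  modal vocabulary, and languages other than English and Dutch require
  editing or adding lexicon files.
* The week-based delay convention is validated against the second
  battery only (see above).
* Fitted $\log_e k$ is censored at the battery's candidate extremes by
  construction; synthetic latent rates outside that range fit to the
  boundary, which mirrors how extreme responders saturate a real
  battery.
* The generator emulates the path structure, marginals and noise levels
  of the study designs, not real linguistic or behavioural
  heterogeneity; passing recovery tests demonstrates correctness of the
  estimators under the assumed model, not robustness to model
  violations.
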