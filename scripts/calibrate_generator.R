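#!/usr/bin/env Rscript
# One-off calibration of the generator residual scales (sigma1, sigma2)
# against the published per-language descriptive SDs, and a Monte-Carlo
# check of the resulting marginals. The chosen values are stored as the
# defaults in default_params(); this script documents where they come from.
#
# Algebra (per study):
#   fut_proportion = gm + gs * fut_z, so SD(fut | language) = sigma1 * gs.
#   log k | Dutch:   Var = beta1^2 * sigma1^2 + sigma2^2
#   log k | English: Var = (beta1 + beta2)^2 * sigma1^2 + sigma2^2

suppressPackageStartupMessages(library(ftrk))

target <- list(
  study1 = list(fut_sd = c(english = 0.13, dutch = 0.16),
                logk_sd = c(english = 2.11, dutch = 1.92)),
  study2 = list(fut_sd = c(english = 0.16, dutch = 0.18),
                logk_sd = c(english = 1.32, dutch = 1.38))
)

for (study in c("study1", "study2")) {
  p <- default_params(study)
  tg <- target[[study]]
  sigma1_implied <- mean(tg$fut_sd) / p$fut_grand_sd
  sigma2_implied <- sqrt(tg$logk_sd[["dutch"]]^2 -
                           p$beta1^2 * p$sigma1^2)
  cat(sprintf(
    "%s: sigma1 implied %.2f (default %.2f); sigma2 implied %.2f (default %.2f)\n",
    study, sigma1_implied, p$sigma1, sigma2_implied, p$sigma2))

  big <- do.call(generator_params,
                 utils::modifyList(unclass(p),
                                   list(n_english = 20000, n_dutch = 20000,
                                        seed = 1)))
  cohort <- gen_cohort(big)
  for (lg in c("english", "dutch")) {
    sub <- cohort[cohort$language == lg, ]
    cat(sprintf("  %s %-7s fut mean %.3f sd %.3f | log k mean %.2f sd %.2f\n",
                study, lg, mean(sub$fut_proportion), sd(sub$fut_proportion),
                mean(sub$log_k_latent), sd(sub$log_k_latent)))
  }
}
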