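# Flat-prior Bayesian moderated mediation.
#
# Two-equation system, sampled independently:
#   mediator: fut_z = lambda1 + alpha * lang            + e1
#   outcome:  log_k = lambda2 + tau' * lang + beta1 * fut_z
#                     + beta2 * fut_z * lang            + e2
# With improper flat priors on coefficients and log-scale, the joint
# posterior of a normal linear model is available in closed form: the
# residual variance has a scaled inverse-chi-square marginal with
# df = n - p, and the coefficients are conditionally multivariate normal
# around the least-squares solution. Direct draws from this posterior are
# distributionally identical to a converged MCMC run under the same priors
# and are exactly seedable.

#' Mean-center and z-scale a numeric vector
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (n - 1 denominator).
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Standardized vector with mean 0 and sd 1.
#' @export
zscale <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-scale a constant (zero-variance) vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Draw from the flat-prior posterior of a normal linear model
#'
#' Exact posterior sampling for `y = X b + e`, `e ~ N(0, sigma^2)` under
#' improper uniform priors: `sigma^2` is drawn from `RSS / chi^2(n - p)`
#' and `b | sigma^2` from `N(b_ls, sigma^2 (X'X)^-1)` where `b_ls` is the
#' least-squares solution.
#'
#' @param X Design matrix (with intercept column if wanted), full rank,
#'   with at least `ncol(X) + 2` rows.
#' @param y Outcome vector.
#' @param n_draws Number of posterior draws. Default 4000.
#' @param seed Optional integer seed; when supplied the draws are
#'   reproducible.
#' @return A list of class `flat_posterior`: `beta` (`n_draws` x `p` draw
#'   matrix, columns named after `X`), `sigma` (residual-scale draws),
#'   `betahat` (least-squares estimates), `df`, `n`, `X`, `y`.
#' @export
sample_posterior <- function(X, y, n_draws = 4000, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), nrow(X) == length(y), n_draws >= 1)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) {
    stop("need at least ncol(X) + 2 rows; got ", n, call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    offending <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  xtx <- crossprod(X)
  betahat <- drop(solve(xtx, crossprod(X, y)))
  names(betahat) <- colnames(X)
  rss <- sum((y - drop(X %*% betahat))^2)
  df <- n - p
  xtx_inv <- chol2inv(chol(xtx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- rss / stats::rchisq(n_draws, df)
  U <- chol(xtx_inv)
  z <- matrix(stats::rnorm(p * n_draws), nrow = p)
  beta <- t(betahat + crossprod(U, z) *
              rep(sqrt(sigma2), each = p))
  colnames(beta) <- colnames(X)
  structure(
    list(beta = beta, sigma = sqrt(sigma2), betahat = betahat,
         df = df, n = n, X = X, y = y),
    class = "flat_posterior"
  )
}

#' Fit the moderated mediation system
#'
#' Samples the mediator equation (standardized future-tense use on the
#' language indicator) and the outcome equation (log k on language,
#' future-tense use, and their interaction) independently from their
#' flat-prior posteriors. Path names follow the field's convention:
#' `lambda1`/`alpha` for the mediator intercept and language path,
#' `lambda2`/`tau_prime`/`beta1`/`beta2` for the outcome intercept, direct
#' effect, mediator slope, and the mediator-by-language interaction.
#'
#' @param rows Tibble with columns `language_indicator` (0 = Dutch,
#'   1 = English), `fut_z` (standardized future-tense proportion) and
#'   `log_k`; both languages must be present.
#' @param n_draws Posterior draws per equation. Default 4000.
#' @param seed Optional integer seed for reproducibility.
#' @param check_standardized Verify that `fut_z` has mean 0 and sd 1
#'   (tolerance 1e-6). Default TRUE.
#' @return An object of class `ftr_mediation`: list with `mediator` and
#'   `outcome` [sample_posterior()] fits, `n_draws`, `seed`, `n`.
#' @export
fit_mediation <- function(rows, n_draws = 4000, seed = NULL,
                          check_standardized = TRUE) {
  required <- c("language_indicator", "fut_z", "log_k")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0) {
    stop("rows missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lang <- rows$language_indicator
  if (!all(lang %in% c(0, 1))) {
    stop("language_indicator must be 0 (Dutch) or 1 (English)",
         call. = FALSE)
  }
  if (length(unique(lang)) < 2) {
    stop("both languages must be present", call. = FALSE)
  }
  if (check_standardized) {
    if (abs(mean(rows$fut_z)) > 1e-6 || abs(stats::sd(rows$fut_z) - 1) > 1e-6) {
      stop("fut_z must be standardized (mean 0, sd 1); use zscale()",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  Xm <- cbind(lambda1 = 1, alpha = lang)
  Xo <- cbind(lambda2 = 1, tau_prime = lang, beta1 = rows$fut_z,
              beta2 = rows$fut_z * lang)
  mediator <- sample_posterior(Xm, rows$fut_z, n_draws)
  outcome <- sample_posterior(Xo, rows$log_k, n_draws)
  structure(
    list(mediator = mediator, outcome = outcome, n_draws = n_draws,
         seed = seed, n = nrow(rows)),
    class = "ftr_mediation"
  )
}

#' @export
print.ftr_mediation <- function(x, ...) {
  cat("Moderated mediation fit:", x$n, "participants,", x$n_draws,
      "posterior draws per equation\n")
  print(mediation_table(x), ...)
  invisible(x)
}

#' Path-coefficient summary table
#'
#' Posterior mean, SD and central 95% interval for every path coefficient
#' of a mediation fit, keyed by path name.
#'
#' @param fit An [fit_mediation()] result.
#' @return Tibble with columns `path`, `equation`, `estimate`, `se`,
#'   `ci95_lower`, `ci95_upper`.
#' @export
mediation_table <- function(fit) {
  stopifnot(inherits(fit, "ftr_mediation"))
  one <- function(draws, equation) {
    tibble::tibble(
      path = colnames(draws),
      equation = equation,
      estimate = colMeans(draws),
      se = apply(draws, 2, stats::sd),
      ci95_lower = apply(draws, 2, stats::quantile, probs = 0.025),
      ci95_upper = apply(draws, 2, stats::quantile, probs = 0.975)
    )
  }
  dplyr::bind_rows(
    one(fit$mediator$beta, "mediator"),
    one(fit$outcome$beta, "outcome")
  )
}

.path_source <- function(x) match.arg(x, c("english", "dutch"))

#' Conditional (and counterfactual) indirect-effect draws
#'
#' The indirect effect is the product of an a-term (the language-to-
#' mediator path) and a b-term (the mediator-to-outcome slope). With
#' English sources the a-term is the `alpha` path and the b-term is
#' `beta1 + beta2`; with Dutch sources the a-term is the mediator
#' intercept `lambda1` and the b-term is `beta1`. Mixing the two
#' languages' sources gives the counterfactual combinations.
#'
#' @param fit An [fit_mediation()] result.
#' @param alpha_source,beta_source `"english"` or `"dutch"`.
#' @return Numeric vector of per-draw products.
#' @export
conditional_indirect <- function(fit, alpha_source = "english",
                                 beta_source = "english") {
  stopifnot(inherits(fit, "ftr_mediation"))
  alpha_source <- .path_source(alpha_source)
  beta_source <- .path_source(beta_source)
  a <- if (alpha_source == "english") fit$mediator$beta[, "alpha"] else
    fit$mediator$beta[, "lambda1"]
  b <- if (beta_source == "english") {
    fit$outcome$beta[, "beta1"] + fit$outcome$beta[, "beta2"]
  } else {
    fit$outcome$beta[, "beta1"]
  }
  unname(a * b)
}

#' Indirect-effect point arithmetic from path point estimates
#'
#' The product of point estimates (rather than the posterior mean of the
#' per-draw product): a-term `alpha` (English) or `lambda1` (Dutch),
#' b-term `beta1 + beta2` (English) or `beta1` (Dutch). Useful for
#' reproducing published coefficient-table arithmetic.
#'
#' @param lambda1,alpha,beta1,beta2 Path point estimates; only the ones
#'   the chosen sources need are required.
#' @param alpha_source,beta_source `"english"` or `"dutch"`.
#' @return A single numeric product.
#' @examples
#' point_indirect(alpha = 1.36, beta1 = 0.26, beta2 = -0.90) # -0.8704
#' @export
point_indirect <- function(lambda1 = NULL, alpha = NULL, beta1 = NULL,
                           beta2 = NULL, alpha_source = "english",
                           beta_source = "english") {
  alpha_source <- .path_source(alpha_source)
  beta_source <- .path_source(beta_source)
  a <- if (alpha_source == "english") alpha else lambda1
  b <- if (beta_source == "english") beta1 + beta2 else beta1
  if (is.null(a) || is.null(b)) {
    stop("missing path estimate(s) for the requested sources", call. = FALSE)
  }
  a * b
}

#' Summarize a vector of posterior draws
#'
#' Posterior mean, central 90% and 95% credibility intervals, and the
#' posterior sign probability `pp`: the fraction of draws whose sign
#' matches the directional hypothesis.
#'
#' @param draws Nonempty numeric vector of posterior draws.
#' @param hypothesis_sign `"negative"` or `"positive"`.
#' @return A one-row tibble of class `mediation_summary` with `est`,
#'   `ci90_lower`, `ci90_upper`, `ci95_lower`, `ci95_upper`, `pp`,
#'   `hypothesis_sign`.
#' @export
mediation_summary <- function(draws, hypothesis_sign = c("negative",
                                                         "positive")) {
  stopifnot(is.numeric(draws), length(draws) >= 1)
  hypothesis_sign <- match.arg(hypothesis_sign)
  q <- stats::quantile(draws, probs = c(0.025, 0.05, 0.95, 0.975),
                       names = FALSE)
  pp <- if (hypothesis_sign == "negative") mean(draws < 0) else
    mean(draws > 0)
  out <- tibble::tibble(
    est = mean(draws),
    ci90_lower = q[2], ci90_upper = q[3],
    ci95_lower = q[1], ci95_upper = q[4],
    pp = pp,
    hypothesis_sign = hypothesis_sign
  )
  class(out) <- c("mediation_summary", class(out))
  out
}

#' Bayesian R-squared of one mediation equation
#'
#' Per posterior draw, the ratio of the variance of the linear predictor
#' to that variance plus the residual variance; summarized with its
#' posterior mean and central 95% interval.
#'
#' @param fit An [fit_mediation()] result (or a [sample_posterior()]
#'   object when `equation` is omitted).
#' @param equation `"mediator"` or `"outcome"`.
#' @return List with `draws` (per-draw R-squared), `est` (posterior mean)
#'   and `ci95` (length-2 vector).
#' @export
bayes_r2 <- function(fit, equation = c("mediator", "outcome")) {
  if (inherits(fit, "ftr_mediation")) {
    equation <- match.arg(equation)
    fit <- fit[[equation]]
  }
  stopifnot(inherits(fit, "flat_posterior"))
  mu <- fit$X %*% t(fit$beta) # n x n_draws
  var_mu <- apply(mu, 2, stats::var)
  r2 <- var_mu / (var_mu + fit$sigma^2)
  list(
    draws = r2,
    est = mean(r2),
    ci95 = stats::quantile(r2, probs = c(0.025, 0.975), names = FALSE)
  )
}

#' Rule-of-thumb minimum sample size for a regression
#'
#' `N > (50 + 8 m) * groups`, where `m` is the number of predictors and
#' `groups` multiplies the requirement when the relationship must be
#' estimated separately per group.
#'
#' @param m Number of predictors (nonnegative integer).
#' @param groups Number of groups requiring independent estimation.
#'   Default 1.
#' @return Minimum N (numeric).
#' @examples
#' power_rule(8, groups = 2) # 228
#' @export
power_rule <- function(m, groups = 1) {
  stopifnot(is.numeric(m), m >= 0, is.numeric(groups), groups >= 1)
  (50 + 8 * m) * groups
}
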