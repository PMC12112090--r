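# Descriptive surfaces: per-language summary statistics and Pearson
# correlations of the participant table.

#' Descriptive statistics per variable and language
#'
#' Mean, sample SD (n - 1), median, MAD (scaled by the 1.4826 normal
#' consistency constant by default), min, max and quartiles (linear
#' interpolation between order statistics, i.e. `stats::quantile` type 7)
#' for each requested variable within each language.
#'
#' @param participants Tibble with a `language` column and the requested
#'   numeric variables.
#' @param variables Character vector of column names to summarize.
#'   Default `c("fut_proportion", "pres_proportion", "log_k")`.
#' @param mad_constant Consistency constant for the MAD. Default 1.4826.
#' @return Tibble with one row per variable x language: `variable`,
#'   `language`, `mean`, `sd`, `median`, `mad`, `min`, `max`, `q25`,
#'   `q75`.
#' @export
descriptive_table <- function(participants,
                              variables = c("fut_proportion",
                                            "pres_proportion", "log_k"),
                              mad_constant = 1.4826) {
  stopifnot("language" %in% names(participants))
  missing <- setdiff(variables, names(participants))
  if (length(missing) > 0) {
    stop("participants table missing variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  languages <- unique(participants$language)
  rows <- list()
  for (v in variables) {
    for (lg in languages) {
      x <- participants[[v]][participants$language == lg]
      x <- x[!is.na(x)]
      if (length(x) == 0) {
        stop("no data for variable '", v, "' in language '", lg, "'",
             call. = FALSE)
      }
      q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, language = lg,
        mean = mean(x), sd = stats::sd(x),
        median = q[2],
        mad = stats::mad(x, constant = mad_constant),
        min = min(x), max = max(x), q25 = q[1], q75 = q[3]
      )
    }
  }
  dplyr::bind_rows(rows)
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, ".", ""))))
}

#' Per-language Pearson correlations
#'
#' Product-moment correlations with two-sided p-values for every pair of
#' the requested variables, computed separately within each language.
#' Significance stars follow the .001/.01/.05/.1 thresholds.
#'
#' @inheritParams descriptive_table
#' @return Tibble `language`, `var1`, `var2`, `r`, `p_value`, `stars`,
#'   `n`.
#' @export
pearson_correlations <- function(participants,
                                 variables = c("fut_proportion",
                                               "pres_proportion",
                                               "log_k")) {
  stopifnot("language" %in% names(participants), length(variables) >= 2)
  rows <- list()
  for (lg in unique(participants$language)) {
    sub <- participants[participants$language == lg, , drop = FALSE]
    if (nrow(sub) < 3) {
      stop("need at least 3 participants per language; language '", lg,
           "' has ", nrow(sub), call. = FALSE)
    }
    for (i in seq_len(length(variables) - 1)) {
      for (j in seq(i + 1, length(variables))) {
        x <- sub[[variables[i]]]
        y <- sub[[variables[j]]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          stop("zero-variance variable in language '", lg, "': ",
               variables[if (stats::sd(x) == 0) i else j], call. = FALSE)
        }
        ct <- stats::cor.test(x, y, method = "pearson")
        rows[[length(rows) + 1]] <- tibble::tibble(
          language = lg, var1 = variables[i], var2 = variables[j],
          r = unname(ct$estimate), p_value = ct$p.value,
          stars = .p_stars(ct$p.value), n = nrow(sub)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
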