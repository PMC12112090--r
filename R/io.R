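# Delimited-text schemas shared by the generator and the analysis chain.
# All tables are TSV with headered columns; schema violations are reported
# with the file and the offending column.

.read_schema <- function(path, required, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a choice battery file
#'
#' Expects columns `item_id`, `ssr_amount`, `llr_amount`, `delay_label`;
#' `delay_weeks` is recomputed from the label via [delay_in_weeks()].
#'
#' @param path Path to a TSV file.
#' @return A battery tibble.
#' @export
read_battery <- function(path) {
  out <- .read_schema(path,
                      c("item_id", "ssr_amount", "llr_amount", "delay_label"),
                      readr::cols())
  out$delay_weeks <- delay_in_weeks(out$delay_label)
  .check_battery(out)
  out
}

#' Read choice observations
#'
#' Columns: `participant_id`, `item_id`, `choice` (`"SSR"`/`"LLR"`).
#'
#' @param path Path to a TSV file.
#' @return Tibble of observations.
#' @export
read_choices <- function(path) {
  .read_schema(path, c("participant_id", "item_id", "choice"),
               readr::cols(.default = readr::col_character()))
}

#' Read elicitation item metadata
#'
#' Columns: `item_id`, `language`, `present_forms` (semicolon-separated),
#' `excluded` (logical), plus any additional metadata columns.
#'
#' @param path Path to a TSV file.
#' @return Tibble of items.
#' @export
read_items <- function(path) {
  out <- .read_schema(path,
                      c("item_id", "language", "present_forms", "excluded"),
                      readr::cols())
  out$excluded <- as.logical(out$excluded)
  .check_items(out)
  out
}

#' Read elicitation responses
#'
#' Columns: `participant_id`, `item_id`, `text`.
#'
#' @param path Path to a TSV file.
#' @return Tibble of responses.
#' @export
read_responses <- function(path) {
  .read_schema(path, c("participant_id", "item_id", "text"),
               readr::cols(.default = readr::col_character()))
}

#' Read a joined participant table
#'
#' Columns: `participant_id`, `language`, `fut_proportion`, `log_k`
#' (further columns pass through).
#'
#' @param path Path to a TSV file.
#' @return Tibble of participants.
#' @export
read_participants <- function(path) {
  .read_schema(path,
               c("participant_id", "language", "fut_proportion", "log_k"),
               readr::cols())
}

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write the full set of study files a simulated cohort produces
#'
#' Emits the delimited files the analysis chain consumes (items,
#' responses, battery, choices, participant ground truth) into a
#' directory.
#'
#' @param bundle A list as returned by [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_study_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(bundle$items, file.path(dir, "items.tsv"))
  .write_tsv(bundle$responses, file.path(dir, "responses.tsv"))
  .write_tsv(bundle$battery, file.path(dir, "battery.tsv"))
  .write_tsv(bundle$choices, file.path(dir, "choices.tsv"))
  .write_tsv(bundle$cohort, file.path(dir, "ground_truth.tsv"))
  .write_tsv(bundle$truth, file.path(dir, "response_labels.tsv"))
  invisible(dir)
}
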