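# Choice batteries: crossed grids of smaller-sooner amounts and verbal delays.

.word_numbers <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
  seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12
)

# Delay-unit convention: everything is expressed in weeks, with a month
# defined as 365.25/12 days and a year as 365.25 days.
.unit_weeks <- c(
  day = 1 / 7,
  week = 1,
  month = 365.25 / 12 / 7,
  year = 365.25 / 7
)

#' Convert a verbal delay label to weeks
#'
#' Labels are of the form `"<quantity> <unit>"`, where the quantity is a
#' number word (`"one"` ... `"twelve"`) or a numeral (possibly with a
#' vulgar-half glyph, e.g. `"1½ months"` or `"4.5 months"`), and the
#' unit is `day`, `week`, `month` or `year` (singular or plural). The
#' conversion is fixed: 1 day = 1/7 week, 1 month = 365.25/12 days,
#' 1 year = 365.25 days.
#'
#' @param label Character vector of delay labels.
#' @return Numeric vector of delays in weeks.
#' @examples
#' delay_in_weeks("one week")
#' delay_in_weeks(c("one day", "4½ months"))
#' @export
delay_in_weeks <- function(label) {
  stopifnot(is.character(label), length(label) >= 1)
  vapply(label, .delay_one, numeric(1), USE.NAMES = FALSE)
}

.delay_one <- function(label) {
  s <- tolower(trimws(label))
  s <- gsub("½", ".5", s, fixed = TRUE) # "1½ months" -> "1.5 months"
  parts <- strsplit(s, "[[:space:]]+")[[1]]
  if (length(parts) != 2) {
    stop("unparseable delay label: '", label, "'", call. = FALSE)
  }
  qty <- if (parts[1] %in% names(.word_numbers)) {
    .word_numbers[[parts[1]]]
  } else {
    suppressWarnings(as.numeric(parts[1]))
  }
  unit <- sub("s$", "", parts[2])
  if (is.na(qty) || qty <= 0 || !unit %in% names(.unit_weeks)) {
    stop("unknown delay label: '", label, "'", call. = FALSE)
  }
  qty * .unit_weeks[[unit]]
}

#' Construct a choice battery from crossed amounts and delays
#'
#' Every smaller-sooner amount is crossed with every delay; the larger-later
#' amount is fixed across items, so a battery of `m` amounts and `d` delays
#' has exactly `m * d` items.
#'
#' @param ssr_amounts Numeric vector of smaller-sooner amounts (currency).
#' @param delay_labels Character vector of verbal delay labels
#'   (see [delay_in_weeks()]).
#' @param llr_amount Larger-later amount, a single value exceeding every
#'   `ssr_amounts` entry. Default 10.
#' @return A tibble with columns `item_id`, `ssr_amount`, `llr_amount`,
#'   `delay_label`, `delay_weeks`.
#' @seealso [study1_battery()], [study2_battery()]
#' @export
choice_battery <- function(ssr_amounts, delay_labels, llr_amount = 10) {
  stopifnot(
    is.numeric(ssr_amounts), length(ssr_amounts) >= 1, all(ssr_amounts > 0),
    is.character(delay_labels), length(delay_labels) >= 1,
    is.numeric(llr_amount), length(llr_amount) == 1, llr_amount > 0
  )
  if (any(ssr_amounts >= llr_amount)) {
    stop("every ssr_amount must be strictly below llr_amount", call. = FALSE)
  }
  weeks <- delay_in_weeks(delay_labels)
  grid <- expand.grid(
    ssr_amount = ssr_amounts, delay_label = delay_labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$delay_weeks <- weeks[match(grid$delay_label, delay_labels)]
  tibble::tibble(
    item_id = sprintf("ssr%05.2f_%s", grid$ssr_amount,
                      gsub("[[:space:]]+", "_", grid$delay_label)),
    ssr_amount = grid$ssr_amount,
    llr_amount = llr_amount,
    delay_label = grid$delay_label,
    delay_weeks = grid$delay_weeks
  )
}

#' Built-in intertemporal-choice batteries
#'
#' `study1_battery()` crosses smaller-sooner amounts of 4.00-9.50 in steps
#' of 0.50 with delays of one day, two days, one week, two weeks, one month,
#' six months and two years (84 items). `study2_battery()` crosses amounts
#' 7.50-9.25 in steps of 0.25 with delays of 2 weeks and 1-4.5 months
#' (64 items). The larger-later reward is always 10.
#'
#' @return A battery tibble as produced by [choice_battery()].
#' @export
study1_battery <- function() {
  choice_battery(
    ssr_amounts = seq(4.00, 9.50, by = 0.50),
    delay_labels = c("one day", "two days", "one week", "two weeks",
                     "one month", "six months", "two years")
  )
}

#' @rdname study1_battery
#' @export
study2_battery <- function() {
  choice_battery(
    ssr_amounts = seq(7.50, 9.25, by = 0.25),
    delay_labels = c("2 weeks", "1 month", "1½ months", "2 months",
                     "2½ months", "3 months", "4 months", "4½ months")
  )
}

.battery_by_name <- function(name) {
  switch(name,
    study1 = study1_battery(),
    study2 = study2_battery(),
    stop("unknown battery: '", name, "' (use 'study1' or 'study2')",
         call. = FALSE)
  )
}

.check_battery <- function(battery) {
  required <- c("item_id", "ssr_amount", "llr_amount", "delay_label",
                "delay_weeks")
  missing <- setdiff(required, names(battery))
  if (length(missing) > 0) {
    stop("battery is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(battery) == 0) stop("battery is empty", call. = FALSE)
  if (anyDuplicated(battery$item_id)) {
    stop("battery has duplicated item_id values", call. = FALSE)
  }
  stopifnot(
    all(battery$ssr_amount > 0), all(battery$llr_amount > 0),
    all(battery$ssr_amount < battery$llr_amount), all(battery$delay_weeks > 0)
  )
  invisible(battery)
}
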