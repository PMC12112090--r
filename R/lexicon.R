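# Closed-vocabulary lexicons: future markers, modal markers, contractions.

#' Construct an FTR lexicon
#'
#' A lexicon holds the closed vocabulary the classifier keys on: future
#' markers (auxiliaries and constructions such as "going to"), modal
#' markers (both high- and low-certainty; any of them suppresses the
#' future- and present-tense classes), and an ordered contraction map
#' applied to the surface string before tokenization. Multiword markers
#' are matched as contiguous token subsequences.
#'
#' @param language `"english"` or `"dutch"` (any label is accepted; the
#'   two shipped lexicons use these).
#' @param future_markers Character vector of marker phrases (lowercase;
#'   multiword phrases space-separated).
#' @param modal_markers Character vector of modal phrases, disjoint from
#'   `future_markers`.
#' @param contraction_map Named character vector: surface form to
#'   replacement, applied in order with fixed matching.
#' @return An object of class `ftr_lexicon`.
#' @export
ftr_lexicon <- function(language, future_markers, modal_markers,
                        contraction_map = character()) {
  stopifnot(
    is.character(language), length(language) == 1, nzchar(language),
    is.character(future_markers), length(future_markers) >= 1,
    is.character(modal_markers)
  )
  future_markers <- tolower(trimws(future_markers))
  modal_markers <- tolower(trimws(modal_markers))
  overlap <- intersect(future_markers, modal_markers)
  if (length(overlap) > 0) {
    stop("future and modal markers must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      language = tolower(language),
      future_markers = future_markers,
      modal_markers = modal_markers,
      contraction_map = contraction_map,
      future_tokens = strsplit(future_markers, " ", fixed = TRUE),
      modal_tokens = strsplit(modal_markers, " ", fixed = TRUE)
    ),
    class = "ftr_lexicon"
  )
}

#' @export
print.ftr_lexicon <- function(x, ...) {
  cat("FTR lexicon (", x$language, "): ",
      length(x$future_markers), " future marker(s), ",
      length(x$modal_markers), " modal marker(s), ",
      length(x$contraction_map), " contraction rule(s)\n", sep = "")
  invisible(x)
}

#' Read a lexicon from a sectioned plain-text file
#'
#' The format has a `language:` header line, then `[future]`, `[modal]`
#' and `[contractions]` sections. Marker sections hold one phrase per
#' line; the contraction section holds `surface => replacement` rules.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the lexicon file.
#' @return An [ftr_lexicon()] object.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("^#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  language <- NULL
  section <- NA_character_
  future <- character()
  modal <- character()
  con_from <- character()
  con_to <- character()
  for (ln in lines) {
    if (grepl("^language:", ln)) {
      language <- trimws(sub("^language:", "", ln))
    } else if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (identical(section, "future")) {
      future <- c(future, ln)
    } else if (identical(section, "modal")) {
      modal <- c(modal, ln)
    } else if (identical(section, "contractions")) {
      parts <- strsplit(ln, "=>", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("bad contraction rule in ", path, ": '", ln, "'", call. = FALSE)
      }
      con_from <- c(con_from, trimws(parts[1]))
      con_to <- c(con_to, trimws(parts[2]))
    } else {
      stop("line outside any section in ", path, ": '", ln, "'",
           call. = FALSE)
    }
  }
  if (is.null(language)) {
    stop("lexicon file ", path, " lacks a 'language:' header", call. = FALSE)
  }
  ftr_lexicon(language, future, modal, stats::setNames(con_to, con_from))
}

#' The lexicons shipped with the package
#'
#' Editable copies live under `inst/extdata/` (`lexicon_english.txt`,
#' `lexicon_dutch.txt`). The marker lists are an explicit reconstruction
#' of the commonly accepted future auxiliaries and modal vocabulary for
#' each language and can be overridden by editing a copy of the file and
#' loading it with [read_lexicon()].
#'
#' @param language `"english"` or `"dutch"`.
#' @return An [ftr_lexicon()] object.
#' @export
default_lexicon <- function(language = c("english", "dutch")) {
  language <- match.arg(language)
  path <- system.file("extdata", paste0("lexicon_", language, ".txt"),
                      package = "ftrk", mustWork = TRUE)
  read_lexicon(path)
}
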