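#' Read a chip chart from a tab-separated file
#'
#' Two dialects are supported. `"wcs_lab_table"` is the World Color Survey
#' chart table (`cnum-vhcm-lab-new.txt`): a header line followed by one row
#' per chip with the chip number, Munsell value/hue/chroma codes and the
#' CIELAB `L*`, `a*`, `b*` coordinates; the full WCS chart yields 330
#' chips. `"generic_tsv"` expects a header with columns `chip`, `L`, `a`,
#' `b` (extra columns ignored). External chip numbers are kept 1-based in
#' the `wcs_chip` column; rows are sorted by chip number and re-indexed
#' 0-based internally.
#'
#' @param path file path.
#' @param dialect `"wcs_lab_table"` or `"generic_tsv"`.
#' @param name chart name (defaults to the file name).
#' @return a [chip_chart()].
#' @export
read_chip_chart <- function(path, dialect = c("wcs_lab_table", "generic_tsv"),
                            name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("parse error: ", path, " contains no chip rows")
  if (dialect == "wcs_lab_table") {
    cnum_col <- grep("cnum|chip", names(df), ignore.case = TRUE)[1L]
    lab_cols <- match(c("L*", "a*", "b*"), names(df))
    if (is.na(cnum_col) || anyNA(lab_cols))
      stop("parse error: expected chip-number and L*/a*/b* columns in ", path)
    hue_col <- match("MunH", names(df))
    if (is.na(hue_col)) hue_col <- match("H", names(df))
    val_col <- match("MunV", names(df))
    if (is.na(val_col)) val_col <- match("V", names(df))
    chip_no <- df[[cnum_col]]
    coords <- as.matrix(df[, lab_cols])
    mh <- if (!is.na(hue_col)) as.character(df[[hue_col]]) else NULL
    mv <- if (!is.na(val_col)) as.character(df[[val_col]]) else NULL
  } else {
    need <- match(c("chip", "L", "a", "b"), names(df))
    if (anyNA(need))
      stop("parse error: generic_tsv needs columns chip, L, a, b in ", path)
    chip_no <- df$chip
    coords <- as.matrix(df[, c("L", "a", "b")])
    mh <- mv <- NULL
  }
  chip_no <- suppressWarnings(as.integer(chip_no))
  storage.mode(coords) <- "double"
  bad <- which(is.na(chip_no) | rowSums(!is.finite(coords)) > 0)
  if (length(bad))
    stop(sprintf("parse error: malformed chip row at line %d of %s",
                 bad[1L] + 1L, path))
  if (anyDuplicated(chip_no))
    stop("integrity error: duplicate chip number ",
         chip_no[duplicated(chip_no)][1L], " in ", path)
  o <- order(chip_no)
  chip_chart(coords[o, , drop = FALSE], name = name,
             wcs_chip = chip_no[o],
             munsell_hue = if (!is.null(mh)) mh[o],
             munsell_value = if (!is.null(mv)) mv[o])
}

#' Write a chip chart as a generic TSV
#' @param chart a [chip_chart()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chip_chart <- function(chart, path) {
  stopifnot(inherits(chart, "chip_chart"))
  df <- data.frame(chip = if (!is.null(chart$wcs_chip)) chart$wcs_chip
                          else chart$chip_id + 1L,
                   L = chart$L, a = chart$a, b = chart$b)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_language_naming_data <- function(language_id, speakers, terms) {
  structure(list(language_id = as.integer(language_id),
                 speakers = speakers,
                 term_inventory = sort(unique(terms))),
            class = "language_naming_data")
}

#' @export
print.language_naming_data <- function(x, ...) {
  cat(sprintf("<language_naming_data: language %d, %d speakers, %d terms>\n",
              x$language_id, length(x$speakers),
              length(x$term_inventory)))
  invisible(x)
}

#' Read per-speaker naming responses
#'
#' Reads a WCS-style term file: tab-separated rows of
#' `language<TAB>speaker<TAB>chip<TAB>term` with no header, where `chip` is
#' the 1-based chip number of the chart. Responses are grouped into one
#' `language_naming_data` object per language, each holding its speakers'
#' chip-to-term response maps (internally keyed by 0-based `chip_id`) and
#' the language's term inventory.
#'
#' @param path file path.
#' @param chart optional [chip_chart()]; when given, responses referencing
#'   chips outside the chart raise an integrity error.
#' @return named list of `language_naming_data`, one element per language.
#' @export
read_naming_data <- function(path, chart = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("language", "speaker", "chip", "term"))
  if (nrow(df) == 0L) stop("parse error: ", path, " contains no responses")
  df$language <- as.integer(df$language)
  df$speaker <- as.integer(df$speaker)
  df$chip <- as.integer(df$chip)
  if (anyNA(df$language) || anyNA(df$speaker) || anyNA(df$chip))
    stop("parse error: non-integer language/speaker/chip field in ", path)
  if (!is.null(chart)) {
    n <- n_chips(chart)
    bad <- df$chip[df$chip < 1L | df$chip > n]
    if (length(bad))
      stop(sprintf(
        "integrity error: response references chip %d outside the %d-chip chart",
        bad[1L], n))
  }
  out <- lapply(split(df, df$language), function(ld) {
    speakers <- lapply(split(ld, ld$speaker), function(sd) {
      if (anyDuplicated(sd$chip))
        stop(sprintf(
          "integrity error: speaker %d of language %d names chip %d twice",
          sd$speaker[1L], sd$language[1L], sd$chip[anyDuplicated(sd$chip)]))
      resp <- as.character(sd$term)
      names(resp) <- sd$chip - 1L          # store by 0-based chip_id
      list(speaker_id = sd$speaker[1L], responses = resp)
    })
    new_language_naming_data(ld$language[1L], unname(speakers), ld$term)
  })
  names(out) <- vapply(out, function(l) as.character(l$language_id),
                       character(1L))
  out
}

#' Write naming data in the WCS term-file dialect
#' @param langs list of `language_naming_data` (as from
#'   [read_naming_data()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_naming_data <- function(langs, path) {
  if (inherits(langs, "language_naming_data")) langs <- list(langs)
  rows <- do.call(rbind, lapply(langs, function(l) {
    do.call(rbind, lapply(l$speakers, function(s) {
      data.frame(language = l$language_id, speaker = s$speaker_id,
                 chip = as.integer(names(s$responses)) + 1L,
                 term = unname(s$responses))
    }))
  }))
  rows <- rows[order(rows$language, rows$speaker, rows$chip), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# term frequency table of one chip across a language's speakers
chip_term_counts <- function(lang, chip_id) {
  key <- as.character(chip_id)
  terms <- unlist(lapply(lang$speakers,
                         function(s) unname(s$responses[key])),
                  use.names = FALSE)
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0L) return(NULL)
  table(terms)
}

#' Modal naming map of a language
#'
#' The mode map: each chip is labeled with the term most frequently used
#' for it across the language's speakers. Ties are broken toward the
#' lexicographically smallest term, so the map is deterministic.
#'
#' @param lang a `language_naming_data`.
#' @param chart the [chip_chart()] the responses refer to.
#' @return a [color_partition()].
#' @export
human_mode_map <- function(lang, chart) {
  stopifnot(inherits(lang, "language_naming_data"),
            inherits(chart, "chip_chart"))
  n <- n_chips(chart)
  labels <- character(n)
  uncovered <- integer(0)
  for (cid in seq_len(n) - 1L) {
    counts <- chip_term_counts(lang, cid)
    if (is.null(counts)) { uncovered <- c(uncovered, cid); next }
    top <- names(counts)[counts == max(counts)]
    labels[cid + 1L] <- sort(top)[1L]
  }
  if (length(uncovered))
    stop("coverage error: no responses for chip(s) ",
         paste(uncovered, collapse = ", "))
  color_partition(labels, chart)
}

#' Empirical term distribution of a chip, p(w | c)
#'
#' The fraction of the language's respondents using each term for the
#' given chip.
#'
#' @param lang a `language_naming_data`.
#' @param chip_id 0-based chip id.
#' @return named numeric vector of term probabilities (sums to 1).
#' @export
estimate_p_w_given_c <- function(lang, chip_id) {
  stopifnot(inherits(lang, "language_naming_data"))
  counts <- chip_term_counts(lang, chip_id)
  if (is.null(counts))
    stop("coverage error: no responses for chip ", chip_id)
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  p
}

#' Empirical naming model of a language
#'
#' Assembles [estimate_p_w_given_c()] over every chart chip into a
#' [naming_model()] whose columns are the language's term inventory.
#'
#' @inheritParams human_mode_map
#' @return a [naming_model()].
#' @export
empirical_naming_model <- function(lang, chart) {
  stopifnot(inherits(lang, "language_naming_data"),
            inherits(chart, "chip_chart"))
  n <- n_chips(chart)
  terms <- lang$term_inventory
  m <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (cid in seq_len(n) - 1L) {
    p <- estimate_p_w_given_c(lang, cid)
    m[cid + 1L, names(p)] <- p
  }
  naming_model(m, terms = terms)
}
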