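# AAindex1 flat-file records list one 20-value scale each.  The value block
# is introduced by an "I" header line whose column pairs fix the residue
# order: A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V, i.e. the first value row
# carries A R N D C Q E G H I and the second L K M F P S T W Y V.
AAINDEX1_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAINDEX1_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse AAindex1 flat-file records
#'
#' Reads descriptor scales from the AAindex1 flat-file format: records with
#' an `H` accession line, a `D` description line, an `I` line announcing the
#' two ten-value rows in the standard `A/L R/K N/M D/F C/P Q/S E/T G/W H/Y
#' I/V` column order, terminated by `//`. Other record lines (`R`, `A`, `T`,
#' `J`, `C`, `*`) are ignored.
#'
#' Records whose value block contains the token `NA` are skipped (AAindex1
#' holds a number of incomplete scales); the accessions of skipped records
#' are reported in a message and returned in the `"skipped"` attribute.
#'
#' @param x Path to an AAindex1 file, a connection, or a character vector of
#'   lines.
#' @return A list of [aa_scale()] objects, one per complete record, with a
#'   character attribute `"skipped"` naming any records excluded for
#'   missing values.
#' @seealso [write_aaindex1()] for the inverse, [descriptor_db()] for the
#'   bundled database.
#' @examples
#' rec <- c("H DEMO000101", "D A demo scale",
#'          "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
#'          paste(sprintf("%6.1f", 1:10), collapse = " "),
#'          paste(sprintf("%6.1f", 11:20), collapse = " "),
#'          "//")
#' parse_aaindex1(rec)[[1]]$values[["A"]]
#' @export
parse_aaindex1 <- function(x) {
  lines <- if (is.character(x) && length(x) != 1L) x
           else if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
                    file.exists(x)) readLines(x, warn = FALSE)
           else if (inherits(x, "connection")) readLines(x, warn = FALSE)
           else strsplit(as.character(x), "\n", fixed = TRUE)[[1]]

  scales <- list()
  skipped <- character(0)
  rec_start <- NULL     # line number of current record's H line
  acc <- NULL; descr <- ""; i_line <- NULL

  flush_record <- function(end_line) {
    if (is.null(acc))
      abort(sprintf("line %d: record terminator '//' with no 'H' accession line.",
                    end_line))
    if (is.null(i_line))
      abort(sprintf("record '%s' (line %d): missing 'I' value-header line.",
                    acc, rec_start))
    value_lines <- lines[(i_line + 1L):(end_line - 1L)]
    toks <- unlist(strsplit(trimws(value_lines), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 20L)
      abort(sprintf("record '%s' (line %d): expected 20 values after 'I' line, found %d.",
                    acc, i_line, length(toks)))
    if (any(toks == "NA")) {
      skipped <<- c(skipped, acc)
      return(invisible(NULL))
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      abort(sprintf("record '%s' (line %d): non-numeric value token.", acc, i_line))
    names(vals) <- c(AAINDEX1_ROW1, AAINDEX1_ROW2)
    scales[[length(scales) + 1L]] <<- aa_scale(acc, descr, vals)
    invisible(NULL)
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    tag <- substr(line, 1L, 1L)
    if (tag == "H") {
      acc <- trimws(substring(line, 2L)); rec_start <- ln
      descr <- ""; i_line <- NULL
      if (!nzchar(acc))
        abort(sprintf("line %d: empty accession on 'H' line.", ln))
    } else if (tag == "D" && !is.null(acc) && is.null(i_line)) {
      descr <- paste0(descr, if (nzchar(descr)) " " else "",
                      trimws(substring(line, 2L)))
    } else if (tag == "I") {
      i_line <- ln
    } else if (startsWith(line, "//")) {
      flush_record(ln)
      acc <- NULL; descr <- ""; i_line <- NULL; rec_start <- NULL
    }
  }
  if (!is.null(acc))
    abort(sprintf("record '%s' (line %d): missing '//' terminator.", acc, rec_start))
  if (length(skipped))
    inform(sprintf("parse_aaindex1: skipped %d record(s) with NA values: %s",
                   length(skipped), paste(skipped, collapse = ", ")))
  attr(scales, "skipped") <- skipped
  scales
}

#' Serialize descriptor scales to AAindex1 format
#'
#' Writes a minimal AAindex1 flat file (`H`, `D`, `I` lines and the two
#' ten-value rows per record) that [parse_aaindex1()] reads back
#' value-identically.
#'
#' @param scales A list of [aa_scale()] objects.
#' @param path File path, or `NULL` to return the lines invisibly.
#' @return (Invisibly) the character vector of lines written.
#' @export
write_aaindex1 <- function(scales, path = NULL) {
  fmt_row <- function(v) paste(sprintf("%8.6g", v), collapse = " ")
  lines <- unlist(lapply(scales, function(s) {
    v <- s$values
    c(paste("H", s$accession),
      paste("D", s$description),
      paste("I",
            paste(sprintf("%s/%s", AAINDEX1_ROW1, AAINDEX1_ROW2), collapse = "  ")),
      fmt_row(v[AAINDEX1_ROW1]),
      fmt_row(v[AAINDEX1_ROW2]),
      "//")
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write / read the tab-separated descriptor snapshot format
#'
#' The snapshot format stores one scale per row: `accession`, `description`,
#' `empirical` flag and the 20 values in canonical residue order. It is the
#' package's plain-text interchange format for descriptor databases.
#'
#' @param scales A list of [aa_scale()] objects (or an `aa_scale_db`).
#' @param path File path.
#' @return `write_scale_snapshot()` returns `path` invisibly;
#'   `read_scale_snapshot()` returns a list of `aa_scale` objects.
#' @export
write_scale_snapshot <- function(scales, path) {
  if (inherits(scales, "aa_scale_db")) scales <- scales$scales
  tb <- purrr::map_dfr(scales, function(s) {
    tibble::as_tibble_row(c(
      list(accession = s$accession, description = s$description,
           empirical = s$empirical),
      as.list(s$values)))
  })
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname write_scale_snapshot
#' @export
read_scale_snapshot <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  purrr::pmap(tb, function(accession, description, empirical, ...) {
    aa_scale(accession, description, unlist(list(...))[AA_CANONICAL],
             empirical = empirical)
  })
}
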