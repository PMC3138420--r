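#' Read sequences from a FASTA file into a tibble
#'
#' Accepts multi-record FASTA with wrapped sequence lines and mixed case.
#' The record id is the first whitespace-delimited token after `>`;
#' duplicate ids are deduplicated by suffixing `_2`, `_3`, ... with a
#' warning so row identifiers never collide downstream. Sequence data
#' before any header, or a header with no sequence, is a format error
#' naming the offending line.
#'
#' @param path Path to a FASTA file (or a character vector of lines).
#' @return A tibble with columns `id`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "CTRP", "NNNT", ">s2", "ARND"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path, fixed = TRUE))
    readLines(path, warn = FALSE) else unlist(strsplit(path, "\n", fixed = TRUE))
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_seq <- character(0); header_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    s <- paste(cur_seq, collapse = "")
    if (!nzchar(s))
      abort(sprintf("empty record '%s' (header at line %d).", cur_id, header_line))
    ids <<- c(ids, cur_id); seqs <<- c(seqs, s)
    invisible(NULL)
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      cur_id <- strsplit(trimws(substring(line, 2L)), "[[:space:]]+")[[1]][1]
      if (is.na(cur_id) || !nzchar(cur_id)) cur_id <- sprintf("seq%d", length(ids) + 1L)
      header_line <- ln
      cur_seq <- character(0)
    } else {
      if (is.null(cur_id))
        abort(sprintf("line %d: sequence data before any '>' header.", ln))
      cur_seq <- c(cur_seq, gsub("[[:space:]]", "", line))
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warn(sprintf("deduplicated %d duplicate id(s): %s", length(dup),
                 paste(head(dup, 5L), collapse = ", ")))
    ids <- make_unique_ids(ids)
  }
  tibble(id = ids, sequence = seqs)
}

# "a","a","b","a" -> "a","a_2","b","a_3"
make_unique_ids <- function(ids) {
  seen <- new.env(parent = emptyenv())
  vapply(ids, function(id) {
    k <- get0(id, envir = seen, ifnotfound = 0L) + 1L
    assign(id, k, envir = seen)
    if (k == 1L) id else paste0(id, "_", k)
  }, character(1), USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param data A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  lines <- unlist(purrr::map2(data$id, data$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain class-label file
#'
#' One label (`0` or `1`) per line, the demo classifier's label format.
#'
#' @param path Path to the label file.
#' @return Integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (!all(x %in% c("0", "1")))
    abort("label file must contain one 0 or 1 per line.")
  as.integer(x)
}

#' Write and read a feature matrix as CSV/TSV
#'
#' Writes the `id` column, any extra columns (e.g. `label`) and the
#' feature columns `p1..pD` with a header row. Doubles are rendered with
#' shortest round-trip precision, so `read_feature_matrix()` recovers the
#' written values bit-for-bit.
#'
#' @param data A feature matrix tibble from [build_feature_matrix()] (or
#'   any data frame with an `id` column).
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a tibble.
#' @export
write_feature_matrix <- function(data, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  # render doubles at 17 significant digits so the decimal text determines
  # the binary value uniquely (readr's own shortest rendering can drop the
  # last ulp)
  out <- dplyr::mutate(as_tibble(data), dplyr::across(
    dplyr::where(is.double), function(v) sub("^(-?\\d+)\\.?0*$", "\\1",
                                             sprintf("%.17g", v))))
  if (dialect == "csv") readr::write_csv(out, path) else readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  # base read.csv parses doubles with C strtod (correctly rounded), which
  # together with the 17-digit rendering makes the round trip bit-exact
  df <- utils::read.csv(path, sep = if (dialect == "csv") "," else "\t",
                        check.names = FALSE)
  as_tibble(df)
}
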