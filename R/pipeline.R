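#' Build a fixed-width feature matrix from variable-length sequences
#'
#' The dataset-level driver: each sequence is encoded with a descriptor
#' scale ([encode_sequence()]) and its encoding resampled to a common
#' length ([resample()]), giving one row per sequence and one column per
#' normalized position. Rows keep the input order; any non-feature input
#' columns (e.g. `label`) are carried through.
#'
#' When `dims` is not given it defaults to the rounded median input
#' length (reported in a message). A warning is issued when any
#' stretch/squeeze ratio `length/dims` or `dims/length` exceeds 2:
#' squeezing below half the original length in general loses information,
#' and stretching far beyond it inflates the feature space.
#'
#' Cubic interpolants can overshoot the knot range, so with interval
#' normalization the matrix may leave the nominal interval slightly;
#' `clamp = TRUE` truncates entries to the mode interval instead
#' (off by default — clamping distorts the interpolant).
#'
#' @param data A data frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()] or [generate_synthetic()]), or a character vector of
#'   sequences.
#' @param descriptor Descriptor index, default 151 (hydropathy).
#' @param dims Target length; default: rounded median sequence length.
#' @param method Interpolation method, see [interpolation_methods()].
#' @param normalize Interval normalization mode (see [encode_sequence()]).
#' @param residue_policy `"strict"` or `"lenient"`.
#' @param clamp Truncate features to the normalization interval.
#' @param skip_errors Collect per-sequence failures (reported in a warning
#'   and in the `"failures"` attribute) instead of aborting on the first.
#' @param db Descriptor database, default [descriptor_db()].
#' @return A tibble of class `feature_matrix`: `id`, carried-through
#'   columns, then `p1..pD`; attributes `descriptor`, `accession`,
#'   `method`, `normalize`, `dims`.
#' @examples
#' set.seed(1)
#' synth <- generate_synthetic(synth_config(n0 = 5, n1 = 5))
#' build_feature_matrix(synth, dims = 35)
#' @export
build_feature_matrix <- function(data, descriptor = 151, dims = NULL,
                                 method = "linear", normalize = "none",
                                 residue_policy = c("strict", "lenient"),
                                 clamp = FALSE, skip_errors = FALSE,
                                 db = descriptor_db()) {
  residue_policy <- match.arg(residue_policy)
  normalize <- parse_normalization_mode(normalize)
  method <- match_method(method)
  if (is.character(data))
    data <- tibble(id = sprintf("seq%d", seq_along(data)), sequence = data)
  if (!is.data.frame(data) || !all(c("id", "sequence") %in% names(data)))
    abort("`data` must be a data frame with columns `id` and `sequence`.")
  if (nrow(data) == 0L) abort("`data` contains no sequences.")

  lens <- nchar(gsub("[-.[:space:]]", "", data$sequence))
  if (is.null(dims)) {
    dims <- as.integer(round(median(lens)))
    inform(sprintf("`dims` not given; using rounded median sequence length %d.",
                   dims))
  }
  if (any(pmax(lens / dims, dims / lens) > 2))
    warn(sprintf(
      "%d sequence(s) are stretched or squeezed by more than 2x relative to dims = %d.",
      sum(pmax(lens / dims, dims / lens) > 2), dims))

  rows <- vector("list", nrow(data))
  failures <- character(0)
  for (i in seq_len(nrow(data))) {
    row <- tryCatch({
      enc <- encode_sequence(data$sequence[[i]], db = db,
                             descriptor = descriptor, normalize = normalize,
                             residue_policy = residue_policy)
      resample(as.numeric(enc), dims, method = method)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      if (!skip_errors)
        abort(sprintf("record '%s': %s", data$id[[i]], conditionMessage(row)))
      failures <- c(failures, sprintf("%s: %s", data$id[[i]],
                                      conditionMessage(row)))
      rows[i] <- list(NULL)
    } else rows[[i]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) abort("all records failed to encode.")
  if (length(failures))
    warn(sprintf("skipped %d failing record(s); see attr(., 'failures').",
                 length(failures)))
  mat <- do.call(rbind, rows[keep])
  if (clamp && normalize != "none") {
    iv <- mode_interval(normalize)
    mat <- pmin(pmax(mat, iv[1]), iv[2])
  }
  colnames(mat) <- paste0("p", seq_len(dims))
  out <- dplyr::bind_cols(
    data[keep, setdiff(names(data), c("sequence", colnames(mat))), drop = FALSE],
    as_tibble(mat))
  structure(out,
            class = c("feature_matrix", class(out)),
            descriptor = as.integer(descriptor),
            accession = get_scale(db, descriptor)$accession,
            method = method, normalize = normalize, dims = as.integer(dims),
            failures = failures)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d sequences x %d positions (descriptor %d [%s], %s, normalize = %s)\n",
    nrow(x), attr(x, "dims"), attr(x, "descriptor"), attr(x, "accession"),
    attr(x, "method"), attr(x, "normalize")))
  NextMethod()
}

feature_columns <- function(data) {
  grep("^p[0-9]+$", names(data), value = TRUE)
}

#' Long-format view of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `position`, `value` (plus any
#'   carried-through columns).
#' @export
tidy.feature_matrix <- function(x, ...) {
  pc <- feature_columns(x)
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(pc),
                      names_to = "position", values_to = "value") |>
    dplyr::mutate(position = as.integer(sub("^p", "", .data$position)))
}
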