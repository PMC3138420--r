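#' Encode an amino-acid sequence as a numeric descriptor vector
#'
#' Maps each residue of a sequence to the value a descriptor scale assigns
#' it, producing one number per residue. The default descriptor is index
#' 151 of the bundled database, the Kyte-Doolittle hydropathy scale.
#' Interval normalization (`normalize`) rescales the descriptor scale
#' itself onto `[0,1]` or `[-1,1]` before encoding, so encoded values stay
#' comparable across sequences.
#'
#' Residue handling: input is uppercased; under the default `"strict"`
#' policy only the 20 canonical one-letter codes are admitted and anything
#' else is an error naming the character and its position. The `"lenient"`
#' policy strips gap characters `-` and `.`, and imputes the ambiguity
#' codes `B` as mean(D, N), `Z` as mean(E, Q) and `X` as the mean of all 20
#' scale values, warning with counts when it does either.
#'
#' @param sequence A single string of one-letter residue codes (or a
#'   character vector of single codes).
#' @param db Descriptor database; defaults to the bundled
#'   [descriptor_db()].
#' @param descriptor 1-based scale index, default `151` (hydropathy).
#' @param normalize Interval normalization mode: `"none"` (default, code
#'   0), `"symmetric_unit"` (code 1, `[-1,1]`) or `"unit"` (code 2,
#'   `[0,1]`); see [rescale_scale()].
#' @param residue_policy `"strict"` (default) or `"lenient"`.
#' @return A numeric vector of class `encoded_seq`, one element per
#'   admitted residue, with attributes `descriptor` (index), `accession`,
#'   `normalize` and `source_length`.
#' @examples
#' encode_sequence("IR")                      # c(4.5, -4.5)
#' encode_sequence("CTRPNNNT", normalize = "unit")
#' @export
encode_sequence <- function(sequence, db = descriptor_db(), descriptor = 151,
                            normalize = "none",
                            residue_policy = c("strict", "lenient")) {
  residue_policy <- match.arg(residue_policy)
  normalize <- parse_normalization_mode(normalize)
  if (!is.character(sequence) || length(sequence) < 1L)
    abort("`sequence` must be a character string.")
  chars <- if (length(sequence) == 1L)
    strsplit(sequence, "", fixed = TRUE)[[1]] else sequence
  chars <- toupper(chars[!grepl("^[[:space:]]*$", chars)])
  if (length(chars) == 0L) abort("`sequence` is empty.")

  scale <- rescale_scale(get_scale(db, descriptor), normalize)
  v <- scale$values

  if (residue_policy == "lenient") {
    gaps <- chars %in% c("-", ".")
    if (any(gaps)) {
      warn(sprintf("stripped %d gap character(s) from sequence.", sum(gaps)))
      chars <- chars[!gaps]
    }
    if (length(chars) == 0L) abort("sequence is empty after gap stripping.")
    amb <- sum(chars %in% c("B", "Z", "X"))
    if (amb > 0L)
      warn(sprintf("imputed %d ambiguity code(s) (B/Z/X) from scale means.", amb))
    v <- c(v, B = mean(v[c("D", "N")]), Z = mean(v[c("E", "Q")]), X = mean(v))
  }
  bad <- which(!chars %in% names(v))
  if (length(bad))
    abort(sprintf("non-admissible residue '%s' at position %d (policy: %s).",
                  chars[bad[1L]], bad[1L], residue_policy))

  structure(unname(v[chars]),
            class = "encoded_seq",
            descriptor = as.integer(descriptor),
            accession = scale$accession,
            normalize = normalize,
            source_length = length(chars))
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> %d residues, descriptor %d (%s), normalize = %s\n",
              attr(x, "source_length"), attr(x, "descriptor"),
              attr(x, "accession"), attr(x, "normalize")))
  print(as.numeric(x))
  invisible(x)
}

#' @rdname encode_sequence
#' @param x An `encoded_seq`.
#' @param ... Unused.
#' @export
tidy.encoded_seq <- function(x, ...) {
  tibble(position = seq_along(x), value = as.numeric(x))
}
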