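#' Construct a descriptor scale
#'
#' A descriptor scale maps each of the 20 canonical amino acids to a real
#' number quantifying some physicochemical or statistical property
#' (hydropathy, net charge, molecular weight, ...). Scales are the unit of
#' the bundled descriptor database and the input to [encode_sequence()].
#'
#' @param accession Short string identifier (AAindex style, e.g.
#'   `"KYTJ820101"`). Must be non-empty.
#' @param description Free-text description of the scale.
#' @param values Numeric vector of length 20 named by the canonical
#'   one-letter residue codes (any order; stored in [AA_CANONICAL] order).
#'   All values must be finite.
#' @param empirical Logical flag marking a scale that does not originate
#'   from AAindex.
#'
#' @return An object of class `aa_scale`: a list with elements `accession`,
#'   `description`, `values` (named numeric, canonical order) and
#'   `empirical`.
#' @examples
#' rank_scale <- aa_scale("RANK", "alphabet rank",
#'                        setNames(1:20, AA_CANONICAL), empirical = TRUE)
#' rank_scale$values[["V"]]
#' @export
aa_scale <- function(accession, description, values, empirical = FALSE) {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession))
    abort("`accession` must be a single non-empty string.")
  if (!is.numeric(values) || length(values) != 20L)
    abort(sprintf("scale '%s': `values` must be a numeric vector of length 20.",
                  accession))
  nm <- toupper(names(values) %||% character(0))
  if (!setequal(nm, AA_CANONICAL))
    abort(sprintf(
      "scale '%s': `values` must be named by the 20 canonical residue codes.",
      accession))
  if (!all(is.finite(values)))
    abort(sprintf("scale '%s': all 20 values must be finite.", accession))
  names(values) <- nm
  structure(
    list(accession = accession,
         description = as.character(description),
         values = values[AA_CANONICAL],
         empirical = isTRUE(empirical)),
    class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat(sprintf("<aa_scale> %s%s\n  %s\n", x$accession,
              if (x$empirical) " (empirical)" else "", x$description))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
format.aa_scale <- function(x, ...) {
  sprintf("%s: %s", x$accession, x$description)
}

#' Rescale a descriptor scale onto a fixed interval
#'
#' Applies the interval normalization modes to the 20 values of a scale:
#' mode `"none"` (code 0) leaves the scale untouched, `"symmetric_unit"`
#' (code 1) maps the values affinely so that their minimum and maximum land
#' on -1 and 1, and `"unit"` (code 2) maps them onto 0 and 1.
#'
#' Normalization is applied to the scale itself — globally over its 20
#' values — not per encoded sequence, so encoded values remain comparable
#' across sequences of different composition.
#'
#' @param scale An [aa_scale()] object.
#' @param mode One of `"none"`, `"symmetric_unit"`, `"unit"`, or the
#'   integer codes `0`, `1`, `2` respectively.
#' @return An `aa_scale` with rescaled values (`description` annotated with
#'   the interval for the non-trivial modes).
#' @examples
#' db <- descriptor_db()
#' kd <- rescale_scale(get_scale(db, 151), "unit")
#' range(kd$values)  # exactly 0 .. 1
#' @export
rescale_scale <- function(scale, mode = "none") {
  stopifnot(inherits(scale, "aa_scale"))
  mode <- parse_normalization_mode(mode)
  if (mode == "none") return(scale)
  lo <- min(scale$values)
  hi <- max(scale$values)
  if (hi <= lo)
    abort(sprintf(
      "scale '%s': all 20 values are identical; interval normalization is undefined.",
      scale$accession))
  target <- if (mode == "unit") c(0, 1) else c(-1, 1)
  v <- target[1] + (scale$values - lo) * (target[2] - target[1]) / (hi - lo)
  out <- scale
  out$values <- v
  out$description <- sprintf("%s [rescaled to [%g,%g]]", scale$description,
                             target[1], target[2])
  out
}

#' Parse an interval-normalization mode
#'
#' Accepts the mode names `"none"`, `"symmetric_unit"`, `"unit"` or their
#' integer codes `0`, `1`, `2` and returns the canonical name.
#'
#' @param mode Mode name or code.
#' @return One of `"none"`, `"symmetric_unit"`, `"unit"`.
#' @export
parse_normalization_mode <- function(mode) {
  if (is.numeric(mode) && length(mode) == 1L && mode %in% 0:2)
    return(c("none", "symmetric_unit", "unit")[mode + 1L])
  if (is.character(mode) && length(mode) == 1L &&
      mode %in% c("none", "symmetric_unit", "unit"))
    return(mode)
  abort(paste0("`mode` must be one of \"none\" (0), \"symmetric_unit\" (1), ",
               "\"unit\" (2)."))
}

# interval endpoints of a normalization mode, or NULL for "none"
mode_interval <- function(mode) {
  switch(mode, none = NULL, symmetric_unit = c(-1, 1), unit = c(0, 1))
}
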