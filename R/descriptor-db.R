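the_db_cache <- new.env(parent = emptyenv())

# three-letter names used by seqinr::aaindex, in canonical order
AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

#' The bundled descriptor database
#'
#' Returns the package's database of 532 amino-acid descriptor scales:
#' the 531 complete (all-numeric) scales of the AAindex1 database, in
#' accession order, followed by one empirical scale at index 532. Index 151
#' is the Kyte-Doolittle hydropathy scale (`KYTJ820101`), the package-wide
#' default descriptor.
#'
#' The AAindex scales are materialized from the `aaindex` dataset shipped
#' with the seqinr package; the 13 AAindex1 entries containing `NA` values
#' are excluded, leaving exactly 531. The empirical 532nd scale is a
#' synthetic stand-in: the alphabet-rank scale assigning A=1 ... V=20 in
#' canonical residue order. It carries no physicochemical meaning and is
#' flagged `empirical`; it exists so that integer descriptor indices span
#' the full documented range 1-532.
#'
#' The database is built once per session and cached.
#'
#' @return An object of class `aa_scale_db`: a list with element `scales`
#'   (list of 532 [aa_scale()] objects, indexed 1-based).
#' @seealso [get_scale()], [list_descriptors()], [encode_sequence()]
#' @examples
#' db <- descriptor_db()
#' length(db)
#' get_scale(db, 151)$accession
#' @export
descriptor_db <- function() {
  if (!is.null(the_db_cache$db)) return(the_db_cache$db)
  aaindex <- NULL  # appease R CMD check; filled by data()
  utils::data("aaindex", package = "seqinr", envir = environment())
  scales <- purrr::compact(purrr::map(aaindex, function(e) {
    v <- e$I
    if (!all(is.finite(v))) return(NULL)
    names(v) <- AA_CANONICAL[match(names(v), AA_THREE)]
    aa_scale(e$H, e$D, v)
  }))
  names(scales) <- NULL  # keep the snapshot's accession order; 151 = KYTJ820101
  scales[[length(scales) + 1L]] <- aa_scale(
    "EMPIRICAL1",
    paste("Alphabet-rank scale, A=1..V=20 in canonical residue order",
          "(synthetic empirical stand-in, not from AAindex)"),
    setNames(as.numeric(1:20), AA_CANONICAL),
    empirical = TRUE)
  db <- structure(list(scales = scales), class = "aa_scale_db")
  the_db_cache$db <- db
  db
}

#' @export
length.aa_scale_db <- function(x) length(x$scales)

#' @export
print.aa_scale_db <- function(x, ...) {
  n_emp <- sum(purrr::map_lgl(x$scales, "empirical"))
  cat(sprintf("<aa_scale_db> %d descriptor scales (%d AAindex, %d empirical)\n",
              length(x$scales), length(x$scales) - n_emp, n_emp))
  invisible(x)
}

#' Look up a descriptor scale by its 1-based index
#'
#' @param db An `aa_scale_db`, typically [descriptor_db()].
#' @param index Integer index in `1:length(db)` (1-532 for the bundled
#'   database). The conventional default descriptor, 151, is applied by
#'   [encode_sequence()], not here.
#' @return The [aa_scale()] at that index.
#' @examples
#' get_scale(descriptor_db(), 151)  # Kyte-Doolittle hydropathy
#' @export
get_scale <- function(db, index) {
  stopifnot(inherits(db, "aa_scale_db"))
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index != as.integer(index) || index < 1L || index > length(db$scales))
    abort(sprintf("descriptor `index` must be a single integer in 1..%d.",
                  length(db$scales)))
  db$scales[[as.integer(index)]]
}

#' List the descriptor scales of a database as a tibble
#'
#' @param db An `aa_scale_db`; defaults to the bundled [descriptor_db()].
#' @return A tibble with columns `index`, `accession`, `description`,
#'   `empirical`.
#' @examples
#' list_descriptors() |> dplyr::filter(grepl("Hydropathy", description))
#' @export
list_descriptors <- function(db = descriptor_db()) {
  stopifnot(inherits(db, "aa_scale_db"))
  tibble(
    index = seq_along(db$scales),
    accession = purrr::map_chr(db$scales, "accession"),
    description = purrr::map_chr(db$scales, "description"),
    empirical = purrr::map_lgl(db$scales, "empirical"))
}

#' @export
as_tibble.aa_scale_db <- function(x, ...) list_descriptors(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname list_descriptors
#' @param x An `aa_scale_db`.
#' @param ... Unused.
#' @export
tidy.aa_scale_db <- function(x, ...) list_descriptors(x)
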