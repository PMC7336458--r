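#' Restriction enzymes
#'
#' A restriction enzyme is described by its recognition motif and the number of
#' motif bases 5' of the cut. XhoI recognizes `CTCGAG` and cleaves after the
#' first C (`C^TCGAG`), so its `cut_offset` is 1.
#'
#' @param name Short enzyme name, e.g. `"XhoI"`.
#' @param motif Recognition sequence over `A`, `C`, `G`, `T` (length >= 4).
#' @param cut_offset Number of bases after the motif start after which the cut
#'   occurs; must satisfy `0 <= cut_offset < nchar(motif)`.
#'
#' @return An object of class `restriction_enzyme`.
#' @examples
#' xhoi()
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  if (nchar(motif) < 4L || grepl("[^ACGT]", motif)) {
    abort("`motif` must be a string over A/C/G/T of length >= 4.")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset >= nchar(motif)) {
    abort("`cut_offset` must satisfy 0 <= cut_offset < nchar(motif).")
  }
  structure(
    list(name = name, motif = motif, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @rdname restriction_enzyme
#' @export
xhoi <- function() restriction_enzyme("XhoI", "CTCGAG", 1L)

#' @export
print.restriction_enzyme <- function(x, ...) {
  cut <- paste0(
    substr(x$motif, 1L, x$cut_offset), "^",
    substr(x$motif, x$cut_offset + 1L, nchar(x$motif))
  )
  cat("<restriction_enzyme> ", x$name, ": ", cut, "\n", sep = "")
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_palindromic_motif <- function(motif) identical(revcomp(motif), motif)
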