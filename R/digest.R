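#' In silico restriction digestion
#'
#' Computes the optical map of a DNA sequence by locating every occurrence of
#' the enzyme's recognition motif and cutting after `cut_offset` bases of the
#' motif. Fragment lengths are the distances between consecutive cuts, with
#' both sequence ends included, in 5' to 3' order. Overlapping motif
#' occurrences each yield a cut; duplicate cut coordinates are collapsed.
#'
#' Optical maps are plain tibbles with one row per fragment and columns
#' `map_id`, `enzyme`, `fragment` (0-based index along the map), `length`
#' (base pairs; real-valued maps are permitted after perturbation or
#' coloring), and `color` (integer reference color or `NA` when uncolored).
#'
#' @param sequence A single DNA string over `A`, `C`, `G`, `T`, `N`. `N`
#'   never matches a motif base.
#' @param enzyme A [restriction_enzyme()].
#' @param map_id Identifier stored in the resulting map.
#' @param both_strands Scan the reverse strand as well and merge cut
#'   positions. XhoI's motif is its own reverse complement so the default
#'   forward-only scan is lossless for it.
#'
#' @return A tibble optical map (one row per fragment).
#' @examples
#' digest("ACTCGAGT", xhoi())
#' @export
digest <- function(sequence, enzyme, map_id = "map", both_strands = FALSE) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty DNA string.")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    abort("`sequence` may only contain A, C, G, T, N.")
  }
  cuts <- cut_positions(sequence, enzyme, both_strands)
  lens <- diff(c(0L, cuts, nchar(sequence)))
  optical_map(map_id, enzyme$name, lens)
}

# 0-based cut coordinates (number of bases 5' of the cut), sorted, unique,
# strictly inside the sequence. Overlapping occurrences found with a
# lookahead so every motif instance yields a cut.
cut_positions <- function(sequence, enzyme, both_strands = FALSE) {
  starts <- motif_starts(sequence, enzyme$motif)
  cuts <- starts + enzyme$cut_offset
  if (both_strands && !is_palindromic_motif(enzyme$motif)) {
    rc_starts <- motif_starts(sequence, revcomp(enzyme$motif))
    # a reverse-strand site cuts cut_offset bases into the motif read 3'->5'
    cuts <- c(cuts, rc_starts + nchar(enzyme$motif) - enzyme$cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

motif_starts <- function(sequence, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Construct an optical map tibble
#'
#' @param map_id Map identifier.
#' @param enzyme Enzyme name (a string).
#' @param lengths Ordered positive fragment lengths.
#' @param colors Optional integer colors, one per fragment (`NA` = uncolored).
#' @return A tibble with columns `map_id`, `enzyme`, `fragment`, `length`,
#'   `color`.
#' @export
optical_map <- function(map_id, enzyme, lengths, colors = NA_integer_) {
  if (length(lengths) == 0L) abort("an optical map needs at least one fragment")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("all fragment lengths must be positive and finite")
  }
  tibble(
    map_id = as.character(map_id),
    enzyme = as.character(enzyme),
    fragment = seq_along(lengths) - 1L,
    length = as.numeric(lengths),
    color = as.integer(rep_len(colors, length(lengths)))
  )
}

#' Digest every record of a genome
#'
#' Applies [digest()] to each record of a multi-FASTA file or a named
#' `DNAStringSet`, producing one optical map per record (`map_id` = record
#' id), in record order.
#'
#' @param genome Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param enzyme A [restriction_enzyme()].
#' @param both_strands See [digest()].
#' @return A tibble of optical maps (all records stacked; may have zero rows
#'   for an empty FASTA).
#' @export
digest_genome <- function(genome, enzyme, both_strands = FALSE) {
  seqs <- as_dna(genome)
  ids <- names(seqs) %||% character(0)
  if (anyDuplicated(ids)) abort("duplicate record ids in FASTA input")
  if (length(seqs) == 0L) {
    return(optical_map("x", enzyme$name, 1)[0, ])
  }
  purrr::map2(
    as.character(seqs), ids,
    function(s, id) digest(s, enzyme, map_id = id, both_strands = both_strands)
  ) |>
    bind_rows()
}

# Accepts a file path, DNAStringSet, or named character vector.
as_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    dna <- Biostrings::readDNAStringSet(x)
    # keep only the first whitespace-delimited token of FASTA headers
    names(dna) <- sub("\\s.*$", "", names(dna))
    return(dna)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  abort("expected a FASTA path, DNAStringSet, or named character vector")
}

#' Split a stacked map tibble into a named list of single maps
#' @param maps A tibble of optical maps.
#' @return Named list of single-map tibbles, input order preserved.
#' @export
split_maps <- function(maps) {
  ids <- unique(maps$map_id)
  setNames(lapply(ids, function(i) maps[maps$map_id == i, ]), ids)
}

#' Fragment lengths of one map
#' @param maps A tibble of optical maps.
#' @param id Which `map_id` to extract (default: the only one present).
#' @return Numeric vector of fragment lengths.
#' @export
map_lengths <- function(maps, id = NULL) {
  if (!is.null(id)) maps <- maps[maps$map_id == id, ]
  if (length(unique(maps$map_id)) != 1L) {
    abort("`maps` must contain exactly one map (or pass `id`)")
  }
  maps$length[order(maps$fragment)]
}
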