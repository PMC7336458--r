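#' Assign globally unique colors to reference fragments
#'
#' Fragments of chromosome `k` (0-based, in input order) are numbered
#' `k * s + i` where `i` is the fragment index and `s` is the smallest power
#' of ten strictly greater than the largest fragment count over chromosomes.
#' Every color therefore occurs exactly once genome-wide and the `k * s` term
#' identifies the chromosome of any color.
#'
#' @param ref_maps Stacked map tibble with one map per chromosome,
#'   chromosome order = input order.
#' @return A `ref_coloring` object: list with `maps` (the colored map
#'   tibble), `s`, and `chromosome_order`.
#' @examples
#' maps <- dplyr::bind_rows(
#'   optical_map("chr0", "XhoI", c(5, 6, 7)),
#'   optical_map("chr1", "XhoI", c(8, 9))
#' )
#' assign_reference_colors(maps)$maps
#' @export
assign_reference_colors <- function(ref_maps) {
  chrom <- split_maps(ref_maps)
  if (length(chrom) == 0L) abort("need at least one chromosome map")
  counts <- purrr::map_int(chrom, nrow)
  if (any(counts == 0L)) abort("empty chromosome map")
  s <- 10^ceiling(log10(max(counts) + 1L))
  maps <- purrr::imap(chrom, function(m, id) {
    k <- match(id, names(chrom)) - 1L
    m$color <- as.integer(k * s + m$fragment)
    m
  }) |> bind_rows()
  structure(
    list(maps = maps, s = as.integer(s), chromosome_order = names(chrom)),
    class = "ref_coloring"
  )
}

#' @export
print.ref_coloring <- function(x, ...) {
  cat(sprintf("<ref_coloring> %d chromosome(s), s = %d, %d fragments\n",
              length(x$chromosome_order), x$s, nrow(x$maps)))
  invisible(x)
}

#' Chromosome index of a color
#' @param color Integer color(s).
#' @param s The chromosome offset factor (power of ten).
#' @return Integer chromosome indices (0-based).
#' @export
color_chromosome <- function(color, s) color %/% s

#' Transfer reference colors onto a contig map through an alignment
#'
#' Applies the generalized block coloring rule: for a block in which `N`
#' contig fragments of total length `n` map to `M` reference fragments of
#' total length `m`, the `N` contig fragments are replaced by `M` new
#' fragments of lengths `ref_len * n / m` carrying the reference colors, so
#' block length is conserved while reference proportions are kept. Contig
#' fragments outside every block keep their length and stay uncolored. For a
#' reverse-orientation alignment the result is expressed in the contig's
#' original orientation, so its colors run in decreasing reference order.
#'
#' @param contig_map Single-map tibble of the contig.
#' @param aln An `om_alignment` of that contig onto a colored chromosome.
#' @param ref_coloring A [assign_reference_colors()] result.
#' @return A colored map tibble for the contig (real-valued lengths).
#' @export
color_contig <- function(contig_map, aln, ref_coloring) {
  stopifnot(inherits(aln, "om_alignment"), inherits(ref_coloring, "ref_coloring"))
  if (!identical(aln$query_id, contig_map$map_id[1L])) {
    abort("alignment does not refer to this contig")
  }
  ref <- ref_coloring$maps[ref_coloring$maps$map_id == aln$ref_id, ]
  if (nrow(ref) == 0L) abort("alignment reference not present in ref_coloring")
  lens <- map_lengths(contig_map)
  if (identical(aln$orientation, "reverse")) lens <- rev(lens)
  nq <- length(lens)
  blocks <- arrange(aln$blocks, .data$q_from)
  if (nrow(blocks) > 0 &&
      (min(blocks$q_from) < 0L || max(blocks$q_to) >= nq ||
       min(blocks$r_from) < 0L || max(blocks$r_to) >= nrow(ref))) {
    abort("alignment block indices out of range")
  }
  out_len <- numeric(0)
  out_col <- integer(0)
  pos <- 0L  # next unconsumed query fragment
  for (bi in seq_len(nrow(blocks))) {
    b <- blocks[bi, ]
    if (b$q_from > pos) {  # uncovered fragments keep length, uncolored
      idx <- (pos + 1L):b$q_from
      out_len <- c(out_len, lens[idx])
      out_col <- c(out_col, rep(NA_integer_, length(idx)))
    }
    n <- sum(lens[(b$q_from + 1L):(b$q_to + 1L)])
    ridx <- (b$r_from + 1L):(b$r_to + 1L)
    m <- sum(ref$length[ridx])
    out_len <- c(out_len, ref$length[ridx] * n / m)
    out_col <- c(out_col, ref$color[ridx])
    pos <- b$q_to + 1L
  }
  if (pos < nq) {
    idx <- (pos + 1L):nq
    out_len <- c(out_len, lens[idx])
    out_col <- c(out_col, rep(NA_integer_, length(idx)))
  }
  if (identical(aln$orientation, "reverse")) {
    out_len <- rev(out_len)
    out_col <- rev(out_col)
  }
  optical_map(contig_map$map_id[1L], contig_map$enzyme[1L], out_len, out_col)
}

#' Color every placed contig
#'
#' @param contig_maps Stacked contig map tibble.
#' @param placements Named list of `om_alignment`s (see [place_contigs()]).
#' @param ref_coloring A [assign_reference_colors()] result.
#' @return A stacked colored map tibble containing only the placed contigs.
#' @export
color_contigs <- function(contig_maps, placements, ref_coloring) {
  maps <- split_maps(contig_maps)
  ids <- intersect(names(maps), names(placements))
  purrr::map(ids, function(id) {
    color_contig(maps[[id]], placements[[id]], ref_coloring)
  }) |> bind_rows()
}
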