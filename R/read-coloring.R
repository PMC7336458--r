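#' Options controlling how reads are colored
#'
#' @param selection_mode How the coloring alignment is picked among a read's
#'   PAF records: `"only_best"` uses the alignment with the most matching
#'   bases over all contigs and leaves the read uncolored when that contig is
#'   uncolored; `"best_colored"` uses the best alignment among colored
#'   contigs; `"best_hiscoring"` uses the best alignment among colored
#'   contigs only when its matching bases reach `match_fraction` of the read
#'   length.
#' @param match_fraction Minimum fraction `t` of the read length that must be
#'   matching bases for the read to be colored (applies in every mode;
#'   default 0.8, set to `NA` to disable). Must satisfy `0 < t <= 1`.
#' @param extend_tails Extend the aligned contig interval by the read's
#'   non-aligning tails (`a` bases at the start, `b` at the end), clamped to
#'   the contig ends.
#' @param adjust_colors Remove gaps in the used colors after coloring (see
#'   [adjust_colors()]).
#' @param min_s_score Minimum s-score for a contig placement to be used.
#' @return A `coloring_options` list.
#' @export
coloring_options <- function(selection_mode = c("only_best", "best_colored",
                                                "best_hiscoring"),
                             match_fraction = 0.8,
                             extend_tails = TRUE,
                             adjust_colors = TRUE,
                             min_s_score = 0) {
  selection_mode <- match.arg(selection_mode)
  if (!is.na(match_fraction) &&
      (match_fraction <= 0 || match_fraction > 1)) {
    abort("`match_fraction` must be in (0, 1] or NA")
  }
  structure(
    list(selection_mode = selection_mode, match_fraction = match_fraction,
         extend_tails = isTRUE(extend_tails),
         adjust_colors = isTRUE(adjust_colors), min_s_score = min_s_score),
    class = "coloring_options"
  )
}

#' Select the PAF record used to color one read
#'
#' Ties on matching bases are broken by longer alignment length, then by
#' target name, for determinism.
#'
#' @param records PAF tibble holding all alignments of a single read.
#' @param colored_ids Character vector of colored contig ids.
#' @param opts A [coloring_options()].
#' @return A one-row PAF tibble, or `NULL` when the read stays uncolored.
#' @export
select_read_alignment <- function(records, colored_ids,
                                  opts = coloring_options()) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  if (length(unique(records$qname)) != 1L) {
    abort("`records` must all belong to one read")
  }
  ord <- order(-records$nmatch, -records$alnlen, records$tname)
  records <- records[ord, ]
  rec <- switch(
    opts$selection_mode,
    only_best = {
      top <- records[1L, ]
      if (top$tname %in% colored_ids) top else NULL
    },
    best_colored = ,
    best_hiscoring = {
      cand <- records[records$tname %in% colored_ids, ]
      if (nrow(cand) > 0L) cand[1L, ] else NULL
    }
  )
  if (is.null(rec)) return(NULL)
  t <- opts$match_fraction
  if (!is.na(t) && rec$nmatch < t * rec$qlen) return(NULL)
  rec
}

#' Color one read from its selected contig alignment
#'
#' The aligned interval on the contig is `[tstart, tend)`; with
#' `extend_tails` it is widened by the read's non-aligning tails
#' (`a = qstart`, `b = qlen - qend`) and clamped to `[0, tlen]`. The start
#' (end) color is the color of the first contig fragment whose cumulative
#' length exceeds the interval start (end); an end coordinate at or past the
#' contig end selects the last fragment. If either endpoint lands on an
#' uncolored fragment the read stays uncolored. Colors are swapped if needed
#' so that `start_color <= end_color` (reverse-oriented contig colorings run
#' downhill).
#'
#' @param rec One-row PAF tibble (read vs contig).
#' @param contig Colored map tibble of the target contig.
#' @param opts A [coloring_options()].
#' @return A one-row tibble (`read_id`, `start_color`, `end_color`), or
#'   `NULL` when the read stays uncolored.
#' @export
color_read <- function(rec, contig, opts = coloring_options()) {
  if (!identical(rec$tname, contig$map_id[1L])) {
    abort("record target does not match the contig map")
  }
  i <- rec$tstart
  j <- rec$tend
  if (opts$extend_tails) {
    i <- max(0, i - rec$qstart)
    j <- min(rec$tlen, j + (rec$qlen - rec$qend))
  }
  lens <- map_lengths(contig)
  total <- sum(lens)
  if (i < 0 || j > total * (1 + 1e-9) + 1 || i > j) {
    abort("aligned interval outside the contig after clamping")
  }
  cum <- cumsum(lens)
  start_idx <- which(cum > i)[1L]
  end_idx <- which(cum > j)[1L]
  if (is.na(start_idx)) start_idx <- length(lens)
  if (is.na(end_idx)) end_idx <- length(lens)
  cols <- contig$color[order(contig$fragment)]
  sc <- cols[start_idx]
  ec <- cols[end_idx]
  if (is.na(sc) || is.na(ec)) return(NULL)
  tibble(read_id = rec$qname,
         start_color = min(sc, ec), end_color = max(sc, ec))
}

#' Color a whole read set from read-to-contig alignments
#'
#' Applies [select_read_alignment()] and [color_read()] per read. Reads whose
#' endpoints land on uncolored contig fragments, or with no acceptable
#' alignment, are left uncolored and omitted from the result.
#'
#' @param paf PAF tibble of read-to-contig alignments.
#' @param colored_contigs Stacked colored map tibble of the contigs.
#' @param opts A [coloring_options()].
#' @return Tibble of colored reads (`read_id`, `start_color`, `end_color`)
#'   with attribute `n_uncolored`.
#' @export
color_reads <- function(paf, colored_contigs, opts = coloring_options()) {
  colored_ids <- unique(colored_contigs$map_id[!is.na(colored_contigs$color)])
  contig_list <- split_maps(colored_contigs)
  groups <- split(paf, paf$qname)
  out <- purrr::map(groups, function(records) {
    rec <- select_read_alignment(records, colored_ids, opts)
    if (is.null(rec)) return(NULL)
    color_read(rec, contig_list[[rec$tname]], opts)
  })
  res <- bind_rows(purrr::compact(out))
  if (nrow(res) == 0L) {
    res <- tibble(read_id = character(), start_color = integer(),
                  end_color = integer())
  }
  attr(res, "n_uncolored") <- length(groups) - nrow(res)
  res
}

#' Remove gaps from the used colors
#'
#' Per chromosome, the set of used colors (every color in `[start, end]` of
#' any read counts as used) is remapped order-preservingly onto consecutive
#' integers starting at the chromosome base `k * s + base`; the `k * s`
#' chromosome term is untouched. The returned color map is an
#' order-preserving bijection on used colors and the operation is idempotent
#' after the first pass.
#'
#' @param colored_reads Tibble of colored reads.
#' @param ref_coloring Optional [assign_reference_colors()] result supplying
#'   `s`.
#' @param s Chromosome offset factor; required when `ref_coloring` is absent.
#' @param base Offset of the first adjusted color within each chromosome
#'   block (default 0).
#' @return List with `reads` (recolored tibble) and `color_map`
#'   (tibble `old`, `new`).
#' @examples
#' reads <- tibble::tibble(read_id = c("a", "b", "c"),
#'                         start_color = c(1L, 4L, 8L),
#'                         end_color = c(2L, 7L, 10L))
#' adjust_colors(reads, s = 100L, base = 1L)$color_map
#' @export
adjust_colors <- function(colored_reads, ref_coloring = NULL, s = NULL,
                          base = 0L) {
  if (!is.null(ref_coloring)) s <- ref_coloring$s
  if (is.null(s)) abort("supply `ref_coloring` or `s`")
  reads <- colored_reads
  if (nrow(reads) > 0L &&
      any(color_chromosome(reads$start_color, s) !=
          color_chromosome(reads$end_color, s))) {
    abort("a read spans two chromosomes' color blocks: invalid coloring")
  }
  used <- unique(unlist(purrr::map2(reads$start_color, reads$end_color, seq),
                        use.names = FALSE))
  used <- sort(used)
  k <- color_chromosome(used, s)
  rank_in_chrom <- stats::ave(used, k, FUN = seq_along)
  new <- k * s + base + rank_in_chrom - 1L
  color_map <- tibble(old = as.integer(used), new = as.integer(new))
  lookup <- setNames(color_map$new, color_map$old)
  reads$start_color <- unname(lookup[as.character(reads$start_color)])
  reads$end_color <- unname(lookup[as.character(reads$end_color)])
  list(reads = reads, color_map = color_map)
}
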