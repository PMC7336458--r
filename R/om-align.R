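#' Scoring parameters for optical-map alignment
#'
#' The aligner scores a monotone decomposition of the query map into blocks,
#' each block matching `N` consecutive query fragments against `M` consecutive
#' reference fragments. A block contributes
#'
#' `match_score - z^2 / 2 - missed_cut_penalty * (M - 1) - false_cut_penalty * (N - 1)`
#'
#' where `z = (q_kb - r_kb) / (sizing_sd_per_kb * sqrt(r_kb))` is the sizing
#' difference between the summed block lengths (in kb), normalized under a
#' noise model whose sizing standard deviation grows with the square root of
#' the fragment length. A query map's first and last blocks are boundary
#' fragments (the molecule ends mid-fragment), so only their overshoot
#' (`q > r`) is penalized. Merging `M` reference fragments hides `M - 1`
#' reference cuts (missed cuts); merging `N` query fragments introduces
#' `N - 1` extra query cuts (false cuts). The total over blocks is the
#' alignment's s-score: higher is better and a perfect identity alignment is
#' maximal. Defaults are recorded in `inst/extdata/default_config.yaml`.
#'
#' @param sizing_sd_per_kb Sizing standard deviation scale (kb per sqrt-kb),
#'   strictly positive. The default suits in silico maps digested from
#'   lightly erroneous sequence; raise it for real optical-map data.
#' @param missed_cut_penalty Penalty per merged reference fragment, >= 0.
#' @param false_cut_penalty Penalty per merged query fragment, >= 0.
#' @param match_score Per-block bonus so that genuine alignments score above
#'   zero.
#' @param max_block_span Maximum fragments merged on either side of a block,
#'   at least 1.
#' @param min_s_score Alignments scoring below this are discarded (default 0:
#'   no minimum quality, every placeable query is used).
#' @return An `om_scoring_params` list.
#' @export
om_scoring_params <- function(sizing_sd_per_kb = 0.1,
                              missed_cut_penalty = 3,
                              false_cut_penalty = 3,
                              match_score = 5,
                              max_block_span = 4L,
                              min_s_score = 0) {
  stopifnot(
    sizing_sd_per_kb > 0, missed_cut_penalty >= 0, false_cut_penalty >= 0,
    max_block_span >= 1L, !is.na(min_s_score)
  )
  structure(
    list(
      sizing_sd_per_kb = sizing_sd_per_kb,
      missed_cut_penalty = missed_cut_penalty,
      false_cut_penalty = false_cut_penalty,
      match_score = match_score,
      max_block_span = as.integer(max_block_span),
      min_s_score = min_s_score
    ),
    class = "om_scoring_params"
  )
}

# Score of one block: `q`/`r` summed lengths in bp, `nq`/`nr` fragment
# counts. The first and last blocks of a query map are boundary fragments —
# the molecule ends mid-fragment, so only overshoot (q > r) is penalized
# there; interior blocks pay the full two-sided sizing term.
om_block_score <- function(q, r, nq, nr, params, boundary = FALSE) {
  diff <- if (boundary) pmax(q - r, 0) else q - r
  z2 <- (diff / 1000)^2 / (params$sizing_sd_per_kb^2 * (r / 1000))
  params$match_score - z2 / 2 -
    params$missed_cut_penalty * (nr - 1) -
    params$false_cut_penalty * (nq - 1)
}

#' Align a query optical map to a reference optical map
#'
#' Finds the highest-scoring global-query / local-reference monotone block
#' alignment by dynamic programming over the last-matched fragment pair, with
#' at most `max_block_span` fragments merged on either side of a block. Both
#' query orientations are tried (reverse = reversed fragment list); on a score
#' tie the forward orientation and the leftmost reference placement win.
#'
#' @param query,ref Single-map tibbles (see [optical_map()]).
#' @param params An [om_scoring_params()].
#' @return An `om_alignment` object (list with `query_id`, `ref_id`,
#'   `orientation`, `blocks` tibble with 0-based inclusive fragment ranges
#'   `q_from`, `q_to`, `r_from`, `r_to`, and `s_score`), or `NULL` when the
#'   best score is below `min_s_score`. For a reverse alignment the block
#'   query indices refer to the reversed fragment list.
#' @examples
#' m <- optical_map("m", "XhoI", c(10000, 5000, 8000))
#' align_map(m, m, om_scoring_params())
#' @export
align_map <- function(query, ref, params = om_scoring_params()) {
  q <- map_lengths(query)
  r <- map_lengths(ref)
  if (any(q <= 0) || any(r <= 0)) abort("fragment lengths must be positive")
  fwd <- om_align_dp(q, r, params)
  rev_ <- om_align_dp(rev(q), r, params)
  best <- if (rev_$score > fwd$score) rev_ else fwd
  orientation <- if (rev_$score > fwd$score) "reverse" else "forward"
  if (!is.finite(best$score) || best$score < params$min_s_score) return(NULL)
  structure(
    list(
      query_id = query$map_id[1L],
      ref_id = ref$map_id[1L],
      orientation = orientation,
      blocks = best$blocks,
      s_score = best$score,
      n_query_fragments = length(q)
    ),
    class = "om_alignment"
  )
}

# DP over S[i, j] = best score with i query fragments consumed and the last
# block ending at reference fragment j (1-based internally). The reference
# window may start anywhere (row i = 0 is all zeros).
om_align_dp <- function(q, r, params) {
  nq <- length(q)
  nr <- length(r)
  A <- params$max_block_span
  cq <- c(0, cumsum(q))
  cr <- c(0, cumsum(r))
  S <- matrix(-Inf, nq + 1L, nr + 1L)
  S[1L, ] <- 0
  PA <- matrix(NA_integer_, nq + 1L, nr + 1L)
  PB <- matrix(NA_integer_, nq + 1L, nr + 1L)
  for (i in seq_len(nq)) {
    for (a in seq_len(min(A, i))) {
      qs <- cq[i + 1L] - cq[i - a + 1L]
      boundary <- (i - a == 0L) || (i == nq)
      for (b in seq_len(min(A, nr))) {
        js <- b:nr
        cand <- S[i - a + 1L, js - b + 1L] +
          om_block_score(qs, cr[js + 1L] - cr[js - b + 1L], a, b, params,
                         boundary = boundary)
        better <- cand > S[i + 1L, js + 1L]
        if (any(better)) {
          upd <- js[better] + 1L
          S[i + 1L, upd] <- cand[better]
          PA[i + 1L, upd] <- a
          PB[i + 1L, upd] <- b
        }
      }
    }
  }
  jbest <- which.max(S[nq + 1L, ]) - 1L  # smallest index on ties
  score <- S[nq + 1L, jbest + 1L]
  if (!is.finite(score)) {
    return(list(score = -Inf, blocks = NULL))
  }
  i <- nq
  j <- jbest
  qf <- qt <- rf <- rt <- integer(0)
  while (i > 0L) {
    a <- PA[i + 1L, j + 1L]
    b <- PB[i + 1L, j + 1L]
    qf <- c(i - a, qf); qt <- c(i - 1L, qt)
    rf <- c(j - b, rf); rt <- c(j - 1L, rt)
    i <- i - a
    j <- j - b
  }
  list(score = score,
       blocks = tibble(q_from = qf, q_to = qt, r_from = rf, r_to = rt))
}

#' Place contig maps on a multi-chromosome reference map
#'
#' Runs [align_map()] for every contig against every reference chromosome and
#' keeps, per contig, the single best placement (at most one placement per
#' contig). Score ties are broken by reference order in `ref_maps`, then by
#' forward orientation.
#'
#' @param contig_maps,ref_maps Stacked map tibbles (unique `map_id`s each).
#' @param params An [om_scoring_params()].
#' @return A named list of `om_alignment` objects; contigs that do not reach
#'   `min_s_score` anywhere are absent.
#' @export
place_contigs <- function(contig_maps, ref_maps, params = om_scoring_params()) {
  contigs <- split_maps(contig_maps)
  refs <- split_maps(ref_maps)
  if (anyDuplicated(names(contigs)) || anyDuplicated(names(refs))) {
    abort("map ids must be unique")
  }
  out <- purrr::map(contigs, function(cm) {
    best <- NULL
    for (rm in refs) {
      aln <- align_map(cm, rm, params)
      if (!is.null(aln) && (is.null(best) || aln$s_score > best$s_score)) {
        best <- aln
      }
    }
    best
  })
  purrr::compact(out)
}

#' @export
print.om_alignment <- function(x, ...) {
  cat(sprintf(
    "<om_alignment> %s -> %s (%s), s-score %.3f, %d block(s)\n",
    x$query_id, x$ref_id, x$orientation, x$s_score, nrow(x$blocks)
  ))
  invisible(x)
}

#' Tidy an optical-map alignment into its block table
#' @param x An `om_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per alignment block.
#' @export
tidy.om_alignment <- function(x, ...) {
  mutate(x$blocks,
         query_id = x$query_id, ref_id = x$ref_id,
         orientation = x$orientation, .before = 1L)
}

#' One-row summary of an optical-map alignment
#' @param x An `om_alignment`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.om_alignment <- function(x, ...) {
  tibble(
    query_id = x$query_id, ref_id = x$ref_id, orientation = x$orientation,
    s_score = x$s_score, n_blocks = nrow(x$blocks),
    n_query_fragments = x$n_query_fragments
  )
}

#' Write/read optical-map placements as TSV
#'
#' Columns: `query_id`, `ref_id`, `orientation`, `s_score` and
#' semicolon-joined blocks `qf-qt:rf-rt` (0-based inclusive).
#'
#' @param alignments A named list of `om_alignment` objects.
#' @param path File path.
#' @return `write_alignments()` returns `path` invisibly; `read_alignments()`
#'   the named list.
#' @export
write_alignments <- function(alignments, path) {
  lines <- purrr::map_chr(alignments, function(a) {
    blk <- paste(sprintf("%d-%d:%d-%d", a$blocks$q_from, a$blocks$q_to,
                         a$blocks$r_from, a$blocks$r_to), collapse = ";")
    paste(a$query_id, a$ref_id, a$orientation,
          format(a$s_score, digits = 12), blk, sep = "\t")
  })
  writeLines(c("query_id\tref_id\torientation\ts_score\tblocks", lines), path)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)[-1L]
  alns <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts <- strsplit(strsplit(f[5L], ";", fixed = TRUE)[[1L]], "[-:]")
    m <- matrix(as.integer(unlist(parts)), ncol = 4L, byrow = TRUE)
    blocks <- tibble(q_from = m[, 1L], q_to = m[, 2L],
                     r_from = m[, 3L], r_to = m[, 4L])
    structure(
      list(query_id = f[1L], ref_id = f[2L], orientation = f[3L],
           blocks = blocks, s_score = as.numeric(f[4L]),
           n_query_fragments = max(blocks$q_to) + 1L),
      class = "om_alignment"
    )
  })
  setNames(alns, purrr::map_chr(alns, "query_id"))
}
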