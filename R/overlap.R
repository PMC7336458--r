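#' All-vs-all dovetail overlapper for low-error long reads
#'
#' A deliberately simple exact-seed overlapper: window minimizers of the
#' forward strand of every read are indexed; each read (both orientations) is
#' queried against the index, seed hits are clustered by diagonal, and the
#' implied overlap region is verified with a banded global alignment that
#' yields the exact number of matching bases. Overlaps are classified with
#' the miniasm overhang rules; internal matches are dropped, contained reads
#' are removed entirely (they emit and receive no dovetail records), and each
#' dovetail is reported once per unordered read pair. Designed for low-error
#' reads; externally produced PAF (any overlapper) is the canonical input
#' path for real data.
#'
#' @param reads Named character vector, `DNAStringSet`, or FASTA path.
#' @param k Minimizer k-mer size.
#' @param w Minimizer window (positions per window from which one seed is
#'   kept).
#' @param min_overlap Minimum dovetail overlap length in bases.
#' @param min_seed_hits Minimum clustered seed hits before a pair is
#'   verified.
#' @param band Banded-alignment half width (covers indel drift).
#' @param min_identity Minimum `nmatch / alnlen` for a verified overlap.
#' @param max_occ Seeds occurring in more reads than this are ignored.
#' @return A PAF tibble of dovetail overlaps.
#' @export
overlap_reads <- function(reads, k = 19L, w = 31L, min_overlap = 1000L,
                          min_seed_hits = 4L, band = 48L,
                          min_identity = 0.9, max_occ = 400L) {
  seqs <- as.character(as_dna(reads))
  if (length(seqs) < 2L) abort("need at least two reads")
  paf <- candidate_alignments(
    seqs, seqs, k = k, w = w, min_span = min_overlap,
    min_seed_hits = min_seed_hits, band = band, min_identity = min_identity,
    max_occ = max_occ, self = TRUE
  )
  if (nrow(paf) == 0L) return(empty_paf())
  cls <- classify_overlaps(paf)
  contained <- unique(c(
    paf$qname[cls == "q_contained"], paf$tname[cls == "t_contained"]
  ))
  keep <- cls == "dovetail" & !(paf$qname %in% contained) &
    !(paf$tname %in% contained) & paf$alnlen >= min_overlap
  paf[keep, ]
}

#' Map reads onto contigs
#'
#' Same seeding and banded verification as [overlap_reads()], but every
#' verified read-to-contig alignment is reported (containment is the normal
#' case here) with its exact matching-base count, ready for
#' [select_read_alignment()].
#'
#' @inheritParams overlap_reads
#' @param contigs Named character vector, `DNAStringSet`, or FASTA path.
#' @param min_span Minimum verified alignment span in bases.
#' @return A PAF tibble of read-to-contig alignments.
#' @export
map_reads <- function(reads, contigs, k = 19L, w = 31L, min_span = 500L,
                      min_seed_hits = 4L, band = 48L, min_identity = 0.9,
                      max_occ = 400L) {
  q <- as.character(as_dna(reads))
  t <- as.character(as_dna(contigs))
  candidate_alignments(
    q, t, k = k, w = w, min_span = min_span, min_seed_hits = min_seed_hits,
    band = band, min_identity = min_identity, max_occ = max_occ, self = FALSE
  )
}

# --- seeding ---------------------------------------------------------------

base_codes <- local({
  v <- rep(NA_real_, 128L)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
  v
})

# base-4 rolling encoding of every k-mer; windows touching a non-ACGT base
# get +Inf so they are never chosen as minimizers
kmer_hashes <- function(seq, k) {
  codes <- base_codes[utf8ToInt(seq)]
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  h <- numeric(n)
  for (j in seq_len(k)) {
    h <- h * 4 + codes[j:(j + n - 1L)]
  }
  h[is.na(h)] <- Inf
  h
}

# minimizer seed table for a set of sequences: hash, name, pos (1-based)
seed_table <- function(seqs, k, w) {
  rows <- purrr::imap(seqs, function(s, nm) {
    h <- kmer_hashes(s, k)
    if (length(h) == 0L) return(NULL)
    idx <- minimizer_positions_cpp(h, w)
    idx <- idx[is.finite(h[idx])]
    if (length(idx) == 0L) return(NULL)
    tibble(hash = h[idx], name = nm, pos = idx)
  })
  bind_rows(purrr::compact(rows))
}

# --- candidate generation and verification ---------------------------------

candidate_alignments <- function(qseqs, tseqs, k, w, min_span, min_seed_hits,
                                 band, min_identity, max_occ, self) {
  tindex <- seed_table(tseqs, k, w)
  if (nrow(tindex) == 0L) return(empty_paf())
  tindex <- tindex |>
    group_by(.data$hash) |>
    filter(n() <= max_occ) |>
    ungroup()
  qlen <- nchar(qseqs)
  tlen <- nchar(tseqs)
  qrc_seqs <- setNames(revcomp(unname(qseqs)), names(qseqs))
  qfwd <- if (self) tindex else seed_table(qseqs, k, w)
  qrc <- seed_table(qrc_seqs, k, w)

  pairs_for <- function(qseeds, strand) {
    hits <- inner_join(
      rename(qseeds, qname = "name", qpos = "pos"),
      rename(tindex, tname = "name", tpos = "pos"),
      by = "hash", relationship = "many-to-many"
    )
    hits <- hits[hits$qname != hits$tname, ]
    if (self) hits <- hits[hits$qname < hits$tname, ]
    if (nrow(hits) == 0L) return(NULL)
    hits$diag <- hits$qpos - hits$tpos
    hits$bin <- round(hits$diag / band)
    top <- hits |>
      dplyr::count(.data$qname, .data$tname, .data$bin) |>
      group_by(.data$qname, .data$tname) |>
      slice(which.max(.data$n)) |>
      ungroup()
    cl <- inner_join(hits, select(top, "qname", "tname", bin0 = "bin"),
                     by = c("qname", "tname"))
    cl <- cl[abs(cl$diag - cl$bin0 * band) <= 1.5 * band, ]
    cl |>
      group_by(.data$qname, .data$tname) |>
      summarise(d = stats::median(.data$diag), nhits = n(), .groups = "drop") |>
      mutate(strand = strand)
  }

  cand <- bind_rows(
    pairs_for(if (self) tindex else qfwd, "+"),
    if (nrow(qrc) > 0L) pairs_for(qrc, "-")
  )
  if (is.null(cand) || nrow(cand) == 0L) return(empty_paf())
  cand <- cand[cand$nhits >= min_seed_hits, ]
  if (!self) {
    # a read maps once per (contig, strand); for self overlaps pairs are unique
    cand <- distinct(cand, .data$qname, .data$tname, .data$strand,
                     .keep_all = TRUE)
  }
  if (nrow(cand) == 0L) return(empty_paf())

  recs <- purrr::pmap(
    list(cand$qname, cand$tname, cand$d, cand$strand),
    function(qn, tn, d, strand) {
      ql <- qlen[[qn]]
      tl <- tlen[[tn]]
      oq <- if (strand == "+") qseqs[[qn]] else qrc_seqs[[qn]]
      d <- round(d)
      qs <- max(1L, d + 1L)         # oriented-query overlap region, 1-based
      qe <- min(ql, d + tl)
      if (qe - qs + 1L < max(min_span %/% 2L, 50L)) return(NULL)
      ts <- qs - d
      te <- qe - d
      res <- banded_align_cpp(substr(oq, qs, qe), substr(tseqs[[tn]], ts, te),
                              band)
      nmatch <- res[1L]
      alnlen <- res[2L]
      if (alnlen < min_span || nmatch < min_identity * alnlen) return(NULL)
      if (strand == "+") {
        q0 <- qs - 1L; q1 <- qe
      } else {
        q0 <- ql - qe; q1 <- ql - qs + 1L
      }
      tibble(
        qname = qn, qlen = ql, qstart = as.integer(q0), qend = as.integer(q1),
        strand = strand, tname = tn, tlen = tl,
        tstart = as.integer(ts - 1L), tend = as.integer(te),
        nmatch = as.integer(nmatch), alnlen = as.integer(alnlen), mapq = 255L
      )
    }
  )
  out <- bind_rows(purrr::compact(recs))
  if (nrow(out) == 0L) return(empty_paf()) else arrange(out, .data$qname,
                                                        .data$tname,
                                                        .data$strand)
}

# --- miniasm-style record classification -----------------------------------

#' Classify PAF records into dovetail / containment / internal
#'
#' Overhang rules as in the miniasm layout stage: with oriented-query
#' coordinates, `overhang = min(bq, bt) + min(eq, et)` must stay below
#' `min(max_overhang, ratio * maplen)` for a record to be usable; otherwise
#' it is an internal match. Records where one read's overlap reaches both of
#' its ends are containments.
#'
#' @param paf A PAF tibble.
#' @param max_overhang Absolute overhang cap in bases.
#' @param overhang_ratio Overhang cap as a fraction of the mapped length.
#' @return Character vector: `"dovetail"`, `"q_contained"`, `"t_contained"`,
#'   or `"internal"` per record.
#' @export
classify_overlaps <- function(paf, max_overhang = 1000L,
                              overhang_ratio = 0.8) {
  if (nrow(paf) == 0L) return(character(0))
  # oriented-query begin/end overhangs
  bq <- ifelse(paf$strand == "+", paf$qstart, paf$qlen - paf$qend)
  eq <- ifelse(paf$strand == "+", paf$qlen - paf$qend, paf$qstart)
  bt <- paf$tstart
  et <- paf$tlen - paf$tend
  overhang <- pmin(bq, bt) + pmin(eq, et)
  maplen <- pmax(paf$qend - paf$qstart, paf$tend - paf$tstart)
  out <- rep("dovetail", nrow(paf))
  out[bq <= bt & eq <= et] <- "q_contained"
  out[bq >= bt & eq >= et & !(bq <= bt & eq <= et)] <- "t_contained"
  out[overhang > pmin(max_overhang, overhang_ratio * maplen)] <- "internal"
  out
}
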