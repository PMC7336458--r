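# Programmatic fixtures shared across test files.

# reads tiling a random genome with exact overlaps; strands alternate
tiling_reads <- function(genome_len = 30000L, read_len = 4000L,
                         step = 2000L, n = 10L, seed = 1L) {
  withr::local_seed(seed)
  genome <- random_dna(genome_len)
  starts <- seq(1L, genome_len - read_len + 1L, by = step)[seq_len(n)]
  reads <- vapply(starts, function(s) substr(genome, s, s + read_len - 1L),
                  character(1L))
  orient <- rep(c("+", "-"), length.out = n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[orient == "-"])
  ))
  reads[orient == "-"] <- rc
  names(reads) <- sprintf("r%02d", seq_len(n))
  list(genome = genome, reads = reads, starts = starts - 1L, orient = orient)
}

# hand-built colored overlap graph (all reads length 1000, v_cut 500)
toy_graph <- function(colors, edges, params = omguide::guidance_params()) {
  reads <- names(colors)
  vertices <- tibble::tibble(
    vertex = omguide:::vertex_id(rep(reads, each = 2L),
                                 rep(c("+", "-"), length(reads))),
    len = 1000L,
    read = rep(reads, each = 2L),
    orient = rep(c("+", "-"), length(reads)),
    start_color = rep(vapply(colors, function(x)
      if (is.null(x)) NA_integer_ else as.integer(x[1L]), integer(1L)),
      each = 2L),
    end_color = rep(vapply(colors, function(x)
      if (is.null(x)) NA_integer_ else as.integer(x[2L]), integer(1L)),
      each = 2L)
  )
  e <- tibble::tibble(
    from = paste0(edges$from, ":+"),
    to = paste0(edges$to, ":+"),
    v_cut = 500L,
    alnlen = 500L
  )
  structure(list(vertices = vertices, edges = e, params = params),
            class = "overlap_graph")
}

# a PAF record as a one-row tibble
paf_row <- function(qname, qlen, qstart, qend, strand, tname, tlen, tstart,
                    tend, nmatch = qend - qstart, alnlen = qend - qstart,
                    mapq = 60L) {
  tibble::tibble(
    qname = qname, qlen = as.integer(qlen), qstart = as.integer(qstart),
    qend = as.integer(qend), strand = strand, tname = tname,
    tlen = as.integer(tlen), tstart = as.integer(tstart),
    tend = as.integer(tend), nmatch = as.integer(nmatch),
    alnlen = as.integer(alnlen), mapq = as.integer(mapq)
  )
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
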