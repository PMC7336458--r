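# Independent oracles used to freeze expected values. Each is a deliberately
# naive implementation, kept separate from the package's optimized code paths.

# O(n * m) substring scan for motif occurrences (0-based starts)
naive_motif_starts <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == motif) starts <- c(starts, i - 1L)
  }
  starts
}

naive_cut_positions <- function(sequence, enzyme) {
  cuts <- naive_motif_starts(sequence, enzyme$motif) + enzyme$cut_offset
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

# exhaustive enumeration of all monotone block decompositions of the query
# over every reference window, returning the maximum total score
brute_om_score_one_orientation <- function(q, r, params) {
  A <- params$max_block_span
  block <- function(qs, rs, a, b, boundary = FALSE) {
    dd <- if (boundary) max(qs - rs, 0) else qs - rs
    z2 <- (dd / 1000)^2 / (params$sizing_sd_per_kb^2 * (rs / 1000))
    params$match_score - z2 / 2 -
      params$missed_cut_penalty * (b - 1) -
      params$false_cut_penalty * (a - 1)
  }
  nq <- length(q)
  nr <- length(r)
  rec <- function(i, j) {
    if (i == nq) return(0)
    best <- -Inf
    for (a in seq_len(min(A, nq - i))) {
      for (b in seq_len(min(A, nr - j))) {
        s <- block(sum(q[(i + 1):(i + a)]), sum(r[(j + 1):(j + b)]), a, b,
                   boundary = (i == 0L) || (i + a == nq)) +
          rec(i + a, j + b)
        if (s > best) best <- s
      }
    }
    best
  }
  best <- -Inf
  for (j0 in 0:(nr - 1L)) best <- max(best, rec(0L, j0))
  best
}

brute_om_score <- function(q, r, params) {
  max(brute_om_score_one_orientation(q, r, params),
      brute_om_score_one_orientation(rev(q), r, params))
}

# brute-force transitive reduction: drop every edge explained by a two-edge
# path of consistent length
brute_transitive_reduction <- function(edges, lens, fuzz) {
  el <- lens[edges$from] - edges$v_cut
  drop <- rep(FALSE, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    v <- edges$from[i]
    x <- edges$to[i]
    for (j in which(edges$from == v)) {
      w <- edges$to[j]
      if (w == x) next
      k <- which(edges$from == w & edges$to == x)
      if (length(k) == 1L && el[j] + el[k] <= el[i] + fuzz) {
        drop[i] <- TRUE
      }
    }
  }
  edges[!drop, ]
}

# enumerate every simple path in a small directed graph (list of vertex
# vectors); used for the exhaustive rainbow check
all_simple_paths <- function(vertices, edges) {
  succ <- split(edges$to, factor(edges$from, levels = vertices))
  paths <- list()
  grow <- function(path) {
    paths[[length(paths) + 1L]] <<- path
    for (nxt in succ[[path[length(path)]]]) {
      if (!(nxt %in% path)) grow(c(path, nxt))
    }
  }
  for (v in vertices) grow(v)
  paths[lengths(paths) > 1L]
}

# can one color per vertex be chosen non-decreasing along the path?
path_is_rainbow <- function(path, starts, ends) {
  cur <- -Inf
  for (v in path) {
    cand <- c(starts[[v]], ends[[v]])
    cand <- cand[!is.na(cand) & cand >= cur]
    if (length(cand) == 0L) return(FALSE)
    cur <- min(cand)
  }
  TRUE
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
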