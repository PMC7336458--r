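#' Extract maximal non-branching rainbow-path unitigs
#'
#' A unitig is a maximal path in the (filtered) overlap graph along which
#' every source has out-degree 1 and every target in-degree 1. After color
#' filtering every such path is a rainbow path — vertex colors appear in
#' non-decreasing order — which is asserted at runtime on every colored
#' path; an assertion failure signals a filtering bug. Each unitig and its
#' reverse-complement twin are the same object; the lexicographically
#' smaller representation is kept. Unitigs are ordered by their smallest
#' member read id.
#'
#' @param g An `overlap_graph` (normally after [filter_edges()]).
#' @return A tibble with one row per unitig: `unitig_id`, `n_reads`,
#'   `start_color`, `end_color`, and `members` (list of tibbles with
#'   `vertex`, `read`, `orient` in path order).
#' @export
find_unitigs <- function(g) {
  v <- g$vertices
  if (nrow(v) == 0L) {
    return(tibble(unitig_id = character(), n_reads = integer(),
                  start_color = integer(), end_color = integer(),
                  members = list()))
  }
  e <- g$edges
  succ <- split(e$to, factor(e$from, levels = v$vertex))
  pred <- split(e$from, factor(e$to, levels = v$vertex))
  outdeg <- lengths(succ)
  indeg <- lengths(pred)
  # a READ is consumed by a path in either orientation, so a unitig's
  # reverse-complement twin (whose arcs may even have been removed
  # asymmetrically by color filtering) is never emitted as well
  used <- setNames(rep(FALSE, length(unique(v$read))), unique(v$read))
  vread <- setNames(v$read, v$vertex)
  paths <- list()
  walk <- function(start) {
    path <- start
    used[vread[[start]]] <<- TRUE
    cur <- start
    repeat {
      if (outdeg[[cur]] != 1L) break
      nxt <- succ[[cur]][1L]
      if (indeg[[nxt]] != 1L || used[[vread[[nxt]]]]) break
      path <- c(path, nxt)
      used[vread[[nxt]]] <<- TRUE
      cur <- nxt
    }
    path
  }
  is_start <- indeg[v$vertex] != 1L |
    purrr::map_lgl(pred[v$vertex], function(p) {
      length(p) == 1L && outdeg[[p]] != 1L
    })
  # measure each candidate path first and realize the longest ones first, so
  # that a fragmented twin-side chain cannot consume the reads of its full
  # forward complement
  measure <- function(start) {
    n <- 1L
    cur <- start
    seen <- start
    repeat {
      if (outdeg[[cur]] != 1L) break
      nxt <- succ[[cur]][1L]
      if (indeg[[nxt]] != 1L || nxt %in% seen) break
      n <- n + 1L
      seen <- c(seen, nxt)
      cur <- nxt
    }
    n
  }
  starts <- sort(v$vertex[is_start])
  starts <- starts[order(-vapply(starts, measure, integer(1L)), starts)]
  for (s in starts) {
    if (!used[[vread[[s]]]]) paths[[length(paths) + 1L]] <- walk(s)
  }
  for (s in sort(v$vertex)) {  # leftover cycles
    if (!used[[vread[[s]]]]) paths[[length(paths) + 1L]] <- walk(s)
  }
  rows <- purrr::map(paths, function(p) {
    idx <- match(p, v$vertex)
    m <- tibble(vertex = p, read = v$read[idx], orient = v$orient[idx])
    cols_s <- v$start_color[idx]
    cols_e <- v$end_color[idx]
    if (all(!is.na(cols_s))) assert_rainbow(p, cols_s, cols_e)
    tibble(
      n_reads = length(p),
      start_color = if (all(is.na(cols_s))) NA_integer_ else
        min(cols_s, na.rm = TRUE),
      end_color = if (all(is.na(cols_e))) NA_integer_ else
        max(cols_e, na.rm = TRUE),
      members = list(m),
      first_read = min(m$read)
    )
  }) |> bind_rows()
  rows <- arrange(rows, .data$first_read)
  rows$unitig_id <- sprintf("utg%06d", seq_len(nrow(rows)))
  select(rows, "unitig_id", "n_reads", "start_color", "end_color", "members")
}

# greedy feasibility of a non-decreasing color assignment over {start,end}
assert_rainbow <- function(path, start_colors, end_colors) {
  cur <- -Inf
  for (i in seq_along(path)) {
    cand <- c(start_colors[i], end_colors[i])
    cand <- cand[!is.na(cand) & cand >= cur]
    if (length(cand) == 0L) {
      abort(sprintf(
        "non-rainbow path produced at vertex %s: color filtering bug", path[i]
      ))
    }
    cur <- min(cand)
  }
  invisible(TRUE)
}

#' Lay out the sequence of a unitig
#'
#' No consensus is computed: the sequence is the first oriented read followed
#' by each successive read's non-overlapping suffix (mismatches inside an
#' overlap are resolved in favor of the earlier read). The suffix of a member
#' starts after `v_cut` bases of its oriented sequence, where `v_cut` is the
#' overlap prefix length stored on the connecting edge.
#'
#' @param members Tibble of unitig members (`vertex`, `read`, `orient`).
#' @param reads Named character vector / `DNAStringSet` / FASTA path with the
#'   read sequences.
#' @param g The `overlap_graph` providing the edge coordinates.
#' @return A list with `sequence` (DNA string) and `layout` (members tibble
#'   with strictly increasing `offset`).
#' @export
layout_sequence <- function(members, reads, g) {
  seqs <- as.character(as_dna(reads))
  oriented <- function(read, orient) {
    s <- seqs[[read]]
    if (orient == "+") s else revcomp(s)
  }
  ekey <- paste(g$edges$from, g$edges$to, sep = "\r")
  first <- oriented(members$read[1L], members$orient[1L])
  seq_parts <- first
  offsets <- 0L
  total <- nchar(first)
  if (nrow(members) > 1L) {
    for (i in 2L:nrow(members)) {
      idx <- match(paste(members$vertex[i - 1L], members$vertex[i],
                         sep = "\r"), ekey)
      if (is.na(idx)) abort("unitig members are not connected by graph edges")
      v_cut <- g$edges$v_cut[idx]
      s <- oriented(members$read[i], members$orient[i])
      if (v_cut >= nchar(s) || total - v_cut < 0L) {
        abort("negative implied offset in unitig layout")
      }
      offsets <- c(offsets, total - v_cut)
      seq_parts <- c(seq_parts, substr(s, v_cut + 1L, nchar(s)))
      total <- total + nchar(s) - v_cut
    }
  }
  layout <- mutate(members, offset = as.integer(offsets))
  list(sequence = paste(seq_parts, collapse = ""), layout = layout)
}

#' Guided (or unguided) overlap-layout assembly
#'
#' Composes the assembly stages: build the overlap graph, optionally
#' propagate colors through uncolored reads, remove color-inconsistent edges
#' (skipped entirely when `colors` is `NULL`, which reproduces the unguided
#' pre-coloring assembly), and emit maximal non-branching (rainbow) unitigs
#' with layout-only sequences.
#'
#' @param reads Named character vector, `DNAStringSet`, or FASTA path.
#' @param overlaps PAF tibble of read overlaps; computed with
#'   [overlap_reads()] when `NULL`.
#' @param colors Colored-read tibble, or `NULL` for unguided assembly.
#' @param params A [guidance_params()].
#' @return An `assembly` object: list with `unitigs` (tibble incl. `length`,
#'   `sequence`, and per-read `members` layouts), `graph`, `params`,
#'   `guided`.
#' @export
assemble <- function(reads, overlaps = NULL, colors = NULL,
                     params = guidance_params()) {
  seqs <- as_dna(reads)
  if (is.null(overlaps)) overlaps <- overlap_reads(seqs)
  g <- build_graph(overlaps, colors, params)
  n_removed <- 0L
  if (!is.null(colors)) {
    if (params$propagation_limit > 0L) g <- propagate_colors(g, params)
    g <- filter_edges(g, params)
    n_removed <- attr(g, "n_removed") %||% 0L
  }
  utg <- find_unitigs(g)
  layouts <- purrr::map(utg$members, layout_sequence, reads = seqs, g = g)
  utg$sequence <- purrr::map_chr(layouts, "sequence")
  utg$members <- purrr::map(layouts, "layout")
  utg$length <- nchar(utg$sequence)
  utg <- select(utg, "unitig_id", "n_reads", "length", "start_color",
                "end_color", "sequence", "members")
  structure(
    list(unitigs = utg, graph = g, params = params,
         guided = !is.null(colors), n_edges_removed = n_removed),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf(
    "<assembly> %s: %d unitig(s), %d reads placed, total length %d bp\n",
    if (x$guided) "guided" else "unguided",
    nrow(x$unitigs), sum(x$unitigs$n_reads), sum(x$unitigs$length)
  ))
  invisible(x)
}

#' Per-read layout table of an assembly
#' @param x An `assembly`.
#' @param ... Unused.
#' @return Tibble with one row per read placement (`unitig_id`, `read`,
#'   `orient`, `offset`).
#' @export
tidy.assembly <- function(x, ...) {
  purrr::map2(x$unitigs$unitig_id, x$unitigs$members, function(id, m) {
    mutate(m, unitig_id = id, .before = 1L)
  }) |>
    bind_rows() |>
    select("unitig_id", "read", "orient", "offset")
}

#' One-row summary of an assembly
#' @param x An `assembly`.
#' @param ... Unused.
#' @return A one-row tibble with unitig count, total length, N50, read
#'   count, and the number of edges removed by color filtering.
#' @export
glance.assembly <- function(x, ...) {
  lens <- sort(x$unitigs$length, decreasing = TRUE)
  n50 <- if (length(lens) == 0L) NA_integer_ else
    lens[which(cumsum(lens) >= sum(lens) / 2)[1L]]
  tibble(
    guided = x$guided,
    n_unitigs = nrow(x$unitigs),
    n_reads = sum(x$unitigs$n_reads),
    total_length = sum(x$unitigs$length),
    n50 = n50,
    n_edges_removed = x$n_edges_removed
  )
}

#' Write an assembly as FASTA and GFA 1.0
#'
#' The GFA has one `S` line per unitig and one `L` line per surviving graph
#' edge between the last member of one unitig and the first member of
#' another, with the overlap written as `<n>M`.
#'
#' @param assembly An `assembly`.
#' @param fasta,gfa Output paths (`NULL` to skip one of them).
#' @return Invisibly, a list of the written paths.
#' @export
write_assembly <- function(assembly, fasta = NULL, gfa = NULL) {
  utg <- assembly$unitigs
  if (!is.null(fasta)) {
    write_fasta(setNames(utg$sequence, utg$unitig_id), fasta)
  }
  if (!is.null(gfa)) {
    s_lines <- sprintf("S\t%s\t%s\tLN:i:%d", utg$unitig_id, utg$sequence,
                       utg$length)
    ends <- tibble(
      unitig_id = utg$unitig_id,
      head = purrr::map_chr(utg$members, function(m) m$vertex[1L]),
      tail = purrr::map_chr(utg$members, function(m) m$vertex[nrow(m)])
    )
    e <- assembly$graph$edges
    links <- inner_join(rename(e, tail = "from"), select(ends, "unitig_id",
                                                         "tail"),
                        by = "tail") |>
      rename(from_utg = "unitig_id") |>
      inner_join(select(ends, to_utg = "unitig_id", to = "head"),
                 by = "to") |>
      filter(.data$from_utg != .data$to_utg)
    l_lines <- sprintf("L\t%s\t+\t%s\t+\t%dM", links$from_utg, links$to_utg,
                       links$v_cut)
    writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), gfa)
  }
  invisible(list(fasta = fasta, gfa = gfa))
}

#' Read a GFA 1.0 file
#' @param path GFA path.
#' @return List with `segments` (tibble `name`, `sequence`, `length`) and
#'   `links` (tibble `from`, `from_orient`, `to`, `to_orient`, `overlap`).
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  type <- purrr::map_chr(parts, 1L)
  segs <- purrr::map(parts[type == "S"], function(p) {
    tibble(name = p[2L], sequence = p[3L], length = nchar(p[3L]))
  }) |> bind_rows()
  links <- purrr::map(parts[type == "L"], function(p) {
    tibble(from = p[2L], from_orient = p[3L], to = p[4L], to_orient = p[5L],
           overlap = as.integer(sub("M$", "", p[6L])))
  }) |> bind_rows()
  if (nrow(segs) == 0L) {
    segs <- tibble(name = character(), sequence = character(),
                   length = integer())
  }
  if (nrow(links) == 0L) {
    links <- tibble(from = character(), from_orient = character(),
                    to = character(), to_orient = character(),
                    overlap = integer())
  }
  list(segments = segs, links = links)
}
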