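#' Parameters for color-guided graph cleaning
#'
#' @param max_color_step Maximum allowed color increase `d` along an edge
#'   (default 1: a consistent edge's target carries a color equal to or
#'   exactly one greater than a color of its source).
#' @param propagation_limit Number of hops `L` through uncolored vertices
#'   over which colors propagate; 0 disables propagation (the default; 5
#'   mirrors the guided assembler's own default).
#' @param min_overlap_bp Minimum dovetail overlap length kept in the graph.
#' @param min_overlap_fraction Minimum overlap length as a fraction of the
#'   shorter read.
#' @param reduce_fuzz Length slack (bp) when removing transitively implied
#'   edges.
#' @param max_overhang,overhang_ratio Overhang caps used when classifying
#'   records (see [classify_overlaps()]).
#' @return A `guidance_params` list.
#' @export
guidance_params <- function(max_color_step = 1L, propagation_limit = 0L,
                            min_overlap_bp = 1000L,
                            min_overlap_fraction = 0,
                            reduce_fuzz = 100L, max_overhang = 1000L,
                            overhang_ratio = 0.8) {
  stopifnot(max_color_step >= 0L, propagation_limit >= 0L,
            min_overlap_bp >= 0L, min_overlap_fraction >= 0,
            reduce_fuzz >= 0L)
  structure(
    list(max_color_step = as.integer(max_color_step),
         propagation_limit = as.integer(propagation_limit),
         min_overlap_bp = as.integer(min_overlap_bp),
         min_overlap_fraction = min_overlap_fraction,
         reduce_fuzz = as.integer(reduce_fuzz),
         max_overhang = as.integer(max_overhang),
         overhang_ratio = overhang_ratio),
    class = "guidance_params"
  )
}

vertex_id <- function(read, orient) paste0(read, ":", orient)
flip_orient <- function(orient) ifelse(orient == "+", "-", "+")

#' Build a colored overlap graph from dovetail overlaps
#'
#' Miniasm-style construction: records are classified by their overhangs,
#' internal matches are dropped, contained reads are removed, short overlaps
#' are filtered, each surviving dovetail becomes a pair of twin edges between
#' oriented reads (two vertices per read, the standard bidirected assembly
#' convention), and transitively implied edges are removed. Vertices carry
#' the `{start_color, end_color}` set of their read, or are uncolored when
#' the read is absent from the colored-read table.
#'
#' Edges store `v_cut`, the overlap prefix length on the target's oriented
#' sequence, so the edge length (offset of the target within the source) is
#' `len(from) - v_cut`.
#'
#' @param overlaps PAF tibble of read overlaps.
#' @param colors Colored-read tibble (`read_id`, `start_color`, `end_color`)
#'   or `NULL` for an uncolored graph.
#' @param params A [guidance_params()].
#' @return An `overlap_graph` object (list of `vertices` and `edges`
#'   tibbles).
#' @export
build_graph <- function(overlaps, colors = NULL,
                        params = guidance_params()) {
  validate_paf(overlaps)
  cls <- classify_overlaps(overlaps, params$max_overhang,
                           params$overhang_ratio)
  contained <- unique(c(overlaps$qname[cls == "q_contained"],
                        overlaps$tname[cls == "t_contained"]))
  keep <- cls == "dovetail" &
    !(overlaps$qname %in% contained) & !(overlaps$tname %in% contained) &
    overlaps$alnlen >= params$min_overlap_bp &
    overlaps$alnlen >= params$min_overlap_fraction *
      pmin(overlaps$qlen, overlaps$tlen)
  paf <- overlaps[keep, ]
  edges <- dovetail_edges(paf)
  reads <- unique(c(paf$qname, paf$tname))
  lens <- c(setNames(paf$qlen, paf$qname), setNames(paf$tlen, paf$tname))
  vertices <- tibble(
    read = rep(reads, each = 2L),
    orient = rep(c("+", "-"), length(reads))
  ) |>
    mutate(vertex = vertex_id(.data$read, .data$orient),
           len = unname(lens[.data$read]), .before = 1L)
  if (!is.null(colors) && nrow(colors) > 0L) {
    vertices <- left_join(
      vertices,
      select(colors, read = "read_id", "start_color", "end_color"),
      by = "read"
    )
  } else {
    vertices$start_color <- NA_integer_
    vertices$end_color <- NA_integer_
  }
  g <- structure(list(vertices = vertices, edges = edges, params = params),
                 class = "overlap_graph")
  reduce_transitive(g, params$reduce_fuzz)
}

# Twin edge pairs from dovetail PAF records. The query is viewed in the
# orientation that matches the target forward strand (q+ for '+', q- for
# '-'); whichever oriented read starts further into the overlap comes first
# on the path. v_cut is the overlap prefix length on the edge target's
# oriented sequence.
dovetail_edges <- function(paf) {
  if (nrow(paf) == 0L) {
    return(tibble(from = character(), to = character(),
                  v_cut = integer(), alnlen = integer()))
  }
  minus <- paf$strand == "-"
  q_or <- ifelse(minus, "-", "+")
  start_q <- ifelse(minus, paf$qlen - paf$qend, paf$qstart)
  end_cut_q <- ifelse(minus, paf$qlen - paf$qstart, paf$qend)
  q_first <- start_q > paf$tstart
  e1 <- tibble(
    from = ifelse(q_first, vertex_id(paf$qname, q_or),
                  vertex_id(paf$tname, "+")),
    to = ifelse(q_first, vertex_id(paf$tname, "+"),
                vertex_id(paf$qname, q_or)),
    v_cut = as.integer(ifelse(q_first, paf$tend, end_cut_q)),
    alnlen = paf$alnlen
  )
  # twin: reverse the path and flip both orientations
  e2 <- tibble(
    from = twin_vertex(e1$to),
    to = twin_vertex(e1$from),
    v_cut = as.integer(ifelse(
      q_first,
      ifelse(minus, paf$qend, paf$qlen - paf$qstart),
      paf$tlen - paf$tstart
    )),
    alnlen = paf$alnlen
  )
  edges <- bind_rows(e1, e2)
  bad <- edges$v_cut <= 0L
  if (any(bad)) {
    warn(sprintf("skipping %d overlap record(s) with contradictory coordinates",
                 sum(bad)))
    edges <- edges[!bad, ]
  }
  edges |>
    arrange(.data$from, .data$to, -.data$alnlen) |>
    distinct(.data$from, .data$to, .keep_all = TRUE)
}

twin_vertex <- function(v) {
  read <- sub(":[+-]$", "", v)
  orient <- substr(v, nchar(v), nchar(v))
  vertex_id(read, flip_orient(orient))
}

# remove edges implied by a two-edge path of consistent total length
reduce_transitive <- function(g, fuzz) {
  e <- g$edges
  if (nrow(e) == 0L) return(g)
  lens <- setNames(g$vertices$len, g$vertices$vertex)
  e$elen <- unname(lens[e$from]) - e$v_cut
  two <- inner_join(
    select(e, "from", mid = "to", l1 = "elen"),
    select(e, mid = "from", to2 = "to", l2 = "elen"),
    by = "mid", relationship = "many-to-many"
  )
  implied <- inner_join(
    two, select(e, "from", to2 = "to", l3 = "elen"),
    by = c("from", "to2")
  ) |>
    filter(.data$from != .data$to2,
           .data$l1 + .data$l2 <= .data$l3 + fuzz) |>
    distinct(.data$from, to = .data$to2)
  g$edges <- anti_join(select(e, -"elen"), implied, by = c("from", "to"))
  g
}

#' @export
print.overlap_graph <- function(x, ...) {
  nc <- sum(!is.na(x$vertices$start_color)) / 2
  cat(sprintf(
    "<overlap_graph> %d reads (%d colored), %d oriented edges\n",
    nrow(x$vertices) / 2, nc, nrow(x$edges)
  ))
  invisible(x)
}

#' Remove color-inconsistent edges
#'
#' An edge `(u, v)` is kept iff some color of `v` is equal to or at most
#' `max_color_step` greater than some color of `u`, and the color interval
#' does not move backwards (`start_v >= start_u`, `end_v >= end_u`); edges
#' running against the color order or spanning too large a color distance
#' are removed. The interval condition is what guarantees that every
#' surviving path is a rainbow path (the end colors are one witness
#' non-decreasing assignment). With
#' propagation disabled, uncolored vertices and all their edges are removed
#' first (reads without colors take no part in guided assembly).
#'
#' @param g An `overlap_graph`.
#' @param params A [guidance_params()].
#' @return The filtered `overlap_graph`; the number of removed edges is in
#'   attribute `n_removed`.
#' @export
filter_edges <- function(g, params = guidance_params()) {
  v <- g$vertices
  if (params$propagation_limit == 0L) {
    uncol <- v$vertex[is.na(v$start_color)]
    v <- v[!(v$vertex %in% uncol), ]
    g$edges <- g$edges[!(g$edges$from %in% uncol | g$edges$to %in% uncol), ]
    g$vertices <- v
  }
  n0 <- nrow(g$edges)
  g$edges <- g$edges[edge_consistent(g, params$max_color_step), ]
  attr(g, "n_removed") <- n0 - nrow(g$edges)
  g
}

# logical vector: does each edge satisfy the color-step rule?
edge_consistent <- function(g, d) {
  e <- g$edges
  if (nrow(e) == 0L) return(logical(0))
  v <- g$vertices
  su <- v$start_color[match(e$from, v$vertex)]
  eu <- v$end_color[match(e$from, v$vertex)]
  sv <- v$start_color[match(e$to, v$vertex)]
  ev <- v$end_color[match(e$to, v$vertex)]
  ok <- function(cu, cv) !is.na(cu) & !is.na(cv) & cv - cu >= 0L & cv - cu <= d
  step_ok <- ok(su, sv) | ok(su, ev) | ok(eu, sv) | ok(eu, ev)
  # the color interval must not move backwards, otherwise a surviving edge
  # pair like {5,9} -> {5,6} (via 9 -> 9) breaks the rainbow guarantee
  forward <- !is.na(su) & !is.na(sv) & sv >= su & ev >= eu
  step_ok & forward
}

#' Propagate colors to uncolored vertices
#'
#' Each uncolored read collects the colors of every colored read reachable
#' from it within `propagation_limit` hops travelling only through uncolored
#' reads (in both directions). If the collected color intervals merge into
#' one contiguous interval the read is colored with its `{min, max}`;
#' otherwise (gaps between propagated colors, or nothing collected) the read
#' is deleted from the graph.
#'
#' @param g An `overlap_graph`.
#' @param params A [guidance_params()] with `propagation_limit >= 1`.
#' @return The updated `overlap_graph`.
#' @export
propagate_colors <- function(g, params = guidance_params(propagation_limit = 5L)) {
  L <- params$propagation_limit
  stopifnot(L >= 1L)
  v <- g$vertices
  reads <- unique(v$read)
  colored <- !is.na(v$start_color[match(reads, v$read)])
  names(colored) <- reads
  # read-level undirected adjacency
  er <- distinct(tibble(
    a = sub(":[+-]$", "", g$edges$from),
    b = sub(":[+-]$", "", g$edges$to)
  ))
  adj <- split(c(er$b, er$a), c(er$a, er$b))
  adj <- lapply(adj, unique)
  scol <- setNames(v$start_color[match(reads, v$read)], reads)
  ecol <- setNames(v$end_color[match(reads, v$read)], reads)
  drop_reads <- character(0)
  new_colors <- list()
  for (r in reads[!colored]) {
    seen <- r
    frontier <- r
    hops <- 0L
    hit <- character(0)
    while (length(frontier) > 0L && hops < L) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      hit <- c(hit, nxt[colored[nxt]])
      frontier <- nxt[!colored[nxt]]
      hops <- hops + 1L
    }
    if (length(hit) == 0L) {
      drop_reads <- c(drop_reads, r)
      next
    }
    iv <- tibble(s = scol[hit], e = ecol[hit]) |> arrange(.data$s)
    gaps <- iv$s[-1L] > cummax(iv$e)[-nrow(iv)] + 1L
    if (any(gaps)) {
      drop_reads <- c(drop_reads, r)
    } else {
      new_colors[[r]] <- c(min(iv$s), max(iv$e))
    }
  }
  for (r in names(new_colors)) {
    idx <- v$read == r
    v$start_color[idx] <- new_colors[[r]][1L]
    v$end_color[idx] <- new_colors[[r]][2L]
  }
  keep <- !(v$read %in% drop_reads)
  g$vertices <- v[keep, ]
  dropped_v <- v$vertex[!keep]
  g$edges <- g$edges[!(g$edges$from %in% dropped_v |
                         g$edges$to %in% dropped_v), ]
  g
}
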