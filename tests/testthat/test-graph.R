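test_that("a chain of three reads reduces to a path graph", {
  # r1[0,6000) r2[4000,10000) r3[8000,14000): r1-r2, r2-r3 direct overlaps
  # plus a transitive r1-r3 overlap that reduction must remove
  paf <- dplyr::bind_rows(
    paf_row("r1", 6000, 4000, 6000, "+", "r2", 6000, 0, 2000),
    paf_row("r2", 6000, 4000, 6000, "+", "r3", 6000, 0, 2000)
  )
  g <- build_graph(paf, NULL, guidance_params())
  expect_equal(nrow(g$vertices), 6L)
  expect_equal(nrow(g$edges), 4L)  # two overlaps x twin pairs
  expect_true(all(c("r1:+", "r2:+", "r3:+") %in% g$vertices$vertex))

  with_trans <- dplyr::bind_rows(
    paf, paf_row("r1", 6000, 5000, 6000, "+", "r3", 6000, 0, 1000,
                 alnlen = 1000)
  )
  # the r1->r3 edge (length 5000) is explained by r1->r2->r3 (4000 + ...)
  g2 <- build_graph(with_trans, NULL, guidance_params(reduce_fuzz = 4000L,
                                                      min_overlap_bp = 500L))
  lens <- setNames(g2$vertices$len, g2$vertices$vertex)
  brute <- brute_transitive_reduction(
    omguide:::dovetail_edges(with_trans), lens,
    fuzz = 4000L
  )
  expect_equal(nrow(g2$edges), nrow(brute))
  expect_setequal(paste(g2$edges$from, g2$edges$to),
                  paste(brute$from, brute$to))
  expect_false(any(g2$edges$from == "r1:+" & g2$edges$to == "r3:+"))
})

test_that("contained reads and internal matches are dropped", {
  paf <- dplyr::bind_rows(
    paf_row("small", 2000, 0, 2000, "+", "big", 9000, 3000, 5000),
    paf_row("big", 9000, 7000, 9000, "+", "next_", 6000, 0, 2000)
  )
  g <- build_graph(paf, NULL, guidance_params())
  expect_false("small" %in% g$vertices$read)
  expect_true(all(c("big", "next_") %in% g$vertices$read))
  # internal match: overlap in the middle of both reads
  internal <- paf_row("a", 9000, 3000, 5000, "+", "b", 9000, 4000, 6000)
  g2 <- build_graph(internal, NULL, guidance_params())
  expect_equal(nrow(g2$edges), 0L)
})

test_that("vertices missing from the color table stay uncolored", {
  paf <- paf_row("r1", 6000, 4000, 6000, "+", "r2", 6000, 0, 2000)
  colors <- tibble::tibble(read_id = "r1", start_color = 4L, end_color = 5L)
  g <- build_graph(paf, colors, guidance_params())
  v <- g$vertices
  expect_equal(unique(v$start_color[v$read == "r1"]), 4L)
  expect_true(all(is.na(v$start_color[v$read == "r2"])))
})

test_that("edge filtering implements the consistent-edge rule", {
  d1 <- guidance_params(max_color_step = 1L)
  g <- toy_graph(
    colors = list(u = c(5, 6), v = c(6, 7), w = c(8, 9), x = c(5, 6)),
    edges = tibble::tibble(from = c("u", "u", "w"), to = c("v", "w", "x"))
  )
  f <- filter_edges(g, d1)
  kept <- paste(f$edges$from, f$edges$to)
  expect_true("u:+ v:+" %in% kept)    # 6 - 6 = 0
  expect_false("u:+ w:+" %in% kept)   # min difference 2
  expect_false("w:+ x:+" %in% kept)   # reverse color order
  expect_equal(attr(f, "n_removed"), 2L)
})

test_that("without propagation uncolored vertices leave the graph", {
  g <- toy_graph(
    colors = list(a = c(1, 1), b = NULL, c = c(2, 2)),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  )
  f <- filter_edges(g, guidance_params(propagation_limit = 0L))
  expect_false("b" %in% f$vertices$read)
  expect_equal(nrow(f$edges), 0L)
})

test_that("color propagation fills contiguous gaps and deletes the rest", {
  p5 <- guidance_params(propagation_limit = 5L)
  # colored {3,4} - uncolored - colored {4,5}: contiguous union -> {3,5}
  g <- toy_graph(
    colors = list(a = c(3, 4), b = NULL, c = c(4, 5)),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  )
  out <- propagate_colors(g, p5)
  v <- out$vertices
  expect_equal(unique(v$start_color[v$read == "b"]), 3L)
  expect_equal(unique(v$end_color[v$read == "b"]), 5L)

  # colored {3} - uncolored - colored {6}: colors 4, 5 missing -> deleted
  g2 <- toy_graph(
    colors = list(a = c(3, 3), b = NULL, c = c(6, 6)),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  )
  out2 <- propagate_colors(g2, p5)
  expect_false("b" %in% out2$vertices$read)

  # isolated uncolored vertex collects nothing -> deleted
  g3 <- toy_graph(
    colors = list(a = c(1, 1), b = NULL),
    edges = tibble::tibble(from = "a", to = "a")[0, ]
  )
  out3 <- propagate_colors(g3, p5)
  expect_false("b" %in% out3$vertices$read)

  # the hop limit bounds the reach
  g4 <- toy_graph(
    colors = list(a = c(1, 1), b = NULL, c = NULL, d = c(2, 2)),
    edges = tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d"))
  )
  out4 <- propagate_colors(g4, guidance_params(propagation_limit = 1L))
  # b reaches only a within one hop; c reaches only d
  v4 <- out4$vertices
  expect_equal(unique(v4$start_color[v4$read == "b"]), 1L)
  expect_equal(unique(v4$start_color[v4$read == "c"]), 2L)
})

test_that("transitive reduction matches the brute-force oracle on random graphs", {
  withr::local_seed(77)
  for (rep in 1:15) {
    n <- sample(4:8, 1L)
    reads <- paste0("v", seq_len(n))
    lens <- setNames(sample(5000:9000, n, replace = TRUE), reads)
    # random forward chain-ish edges with random extra skips
    edges <- tibble::tibble(
      from = paste0(reads[-n], ":+"),
      to = paste0(reads[-1L], ":+"),
      v_cut = as.integer(round(lens[reads[-n]] * 0.6)),
      alnlen = 1000L
    )
    extra_from <- sample(seq_len(n - 2L), 2L, replace = TRUE)
    skips <- tibble::tibble(
      from = paste0(reads[extra_from], ":+"),
      to = paste0(reads[extra_from + 2L], ":+"),
      v_cut = as.integer(round(lens[reads[extra_from]] * 0.2)),
      alnlen = 500L
    )
    edges <- dplyr::distinct(dplyr::bind_rows(edges, skips),
                             from, to, .keep_all = TRUE)
    vertices <- tibble::tibble(
      vertex = c(paste0(reads, ":+"), paste0(reads, ":-")),
      read = rep(reads, 2L), orient = rep(c("+", "-"), each = n),
      len = unname(lens[rep(reads, 2L)]),
      start_color = NA_integer_, end_color = NA_integer_
    )
    g <- structure(list(vertices = vertices, edges = edges,
                        params = guidance_params()),
                   class = "overlap_graph")
    fuzz <- 500L
    red <- omguide:::reduce_transitive(g, fuzz)
    vlens <- setNames(vertices$len, vertices$vertex)
    brute <- brute_transitive_reduction(edges, vlens, fuzz)
    expect_setequal(paste(red$edges$from, red$edges$to),
                    paste(brute$from, brute$to))
  }
})
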