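test_that("a consistent path graph yields one unitig; branches split it", {
  g <- toy_graph(
    colors = list(a = c(1, 1), b = c(1, 2), c = c(2, 2), d = c(3, 3)),
    edges = tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d"))
  )
  u <- find_unitigs(g)
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_reads, 4L)
  expect_equal(u$start_color, 1L)
  expect_equal(u$end_color, 3L)
  expect_equal(u$members[[1L]]$read, c("a", "b", "c", "d"))

  # a branch at the second vertex splits the path there
  g2 <- toy_graph(
    colors = list(a = c(1, 1), b = c(1, 2), c = c(2, 2), d = c(2, 3)),
    edges = tibble::tibble(from = c("a", "b", "b"), to = c("b", "c", "d"))
  )
  u2 <- find_unitigs(g2)
  expect_equal(sort(vapply(u2$members, function(m) paste(m$read,
                                                         collapse = ""),
                           character(1L))),
               sort(c("ab", "c", "d")))

  empty <- toy_graph(colors = list(), edges = tibble::tibble(
    from = character(), to = character()
  ))
  expect_equal(nrow(find_unitigs(empty)), 0L)
})

test_that("a non-rainbow path trips the runtime assertion", {
  # colors decrease along a path that was never filtered: a filtering bug
  g <- toy_graph(
    colors = list(a = c(5, 5), b = c(3, 3)),
    edges = tibble::tibble(from = "a", to = "b")
  )
  expect_error(find_unitigs(g), "non-rainbow")
  # ... and filter_edges prevents it
  expect_silent(find_unitigs(filter_edges(g, guidance_params())))
})

test_that("layout concatenates non-overlapping suffixes without consensus", {
  reads <- c(r1 = "AAACCC", r2 = "CCCGGG")
  paf <- paf_row("r1", 6, 3, 6, "+", "r2", 6, 0, 3)
  g <- build_graph(paf, NULL, guidance_params(min_overlap_bp = 1L,
                                              max_overhang = 2L))
  u <- find_unitigs(g)
  lay <- layout_sequence(u$members[[1L]], reads, g)
  seqs <- c(lay$sequence, revcomp_chr(lay$sequence))
  expect_true("AAACCCGGG" %in% seqs)
  expect_equal(lay$layout$offset, c(0L, 3L))

  # single-read unitig: the read itself
  single <- toy_graph(colors = list(x = c(1, 1)),
                      edges = tibble::tibble(from = character(),
                                             to = character()))
  su <- find_unitigs(single)
  lay2 <- layout_sequence(su$members[[1L]], c(x = "ACGTACGT"), single)
  expect_equal(lay2$sequence, "ACGTACGT")
})

test_that("layout length equals read lengths minus overlap lengths", {
  # three 100 bp reads chained with 50 bp overlaps -> 200 bp
  withr::local_seed(12)
  core <- random_dna(200)
  reads <- c(a = substr(core, 1, 100), b = substr(core, 51, 150),
             c = substr(core, 101, 200))
  paf <- dplyr::bind_rows(
    paf_row("a", 100, 50, 100, "+", "b", 100, 0, 50),
    paf_row("b", 100, 50, 100, "+", "c", 100, 0, 50)
  )
  g <- build_graph(paf, NULL, guidance_params(min_overlap_bp = 10L,
                                              max_overhang = 5L))
  asm <- assemble(reads, paf, params = guidance_params(min_overlap_bp = 10L,
                                                       max_overhang = 5L))
  expect_equal(asm$unitigs$length, 200L)
  expect_equal(asm$unitigs$length,
               sum(nchar(reads)) - sum(c(50L, 50L)))
  seqs <- c(asm$unitigs$sequence, revcomp_chr(asm$unitigs$sequence))
  expect_true(core %in% seqs)

  # general invariant on simulated exact tilings
  tl <- tiling_reads(seed = 3L)
  asm2 <- assemble(tl$reads)
  m <- asm2$unitigs$members[[1L]]
  total_reads <- sum(nchar(tl$reads[m$read]))
  overlaps <- total_reads - asm2$unitigs$length[1L]
  expect_equal(asm2$unitigs$length[1L], total_reads - overlaps)
  expect_equal(unname(m$offset[nrow(m)] +
                        nchar(tl$reads[m$read[nrow(m)]])),
               asm2$unitigs$length[1L])
})

test_that("unguided assembly equals find_unitigs on the unfiltered graph", {
  tl <- tiling_reads(seed = 6L)
  ov <- overlap_reads(tl$reads)
  asm <- assemble(tl$reads, ov, colors = NULL)
  g <- build_graph(ov, NULL, guidance_params())
  u <- find_unitigs(g)
  expect_equal(asm$unitigs$unitig_id, u$unitig_id)
  expect_equal(asm$unitigs$n_reads, u$n_reads)
  expect_equal(asm$n_edges_removed, 0L)
})

test_that("tidy and glance summarize assemblies", {
  tl <- tiling_reads(seed = 6L)
  asm <- assemble(tl$reads)
  td <- tidy(asm)
  expect_equal(nrow(td), sum(asm$unitigs$n_reads))
  expect_true(all(c("unitig_id", "read", "orient", "offset") %in% names(td)))
  gl <- glance(asm)
  expect_equal(gl$n_unitigs, nrow(asm$unitigs))
  expect_equal(gl$total_length, sum(asm$unitigs$length))
  expect_false(gl$guided)
})
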