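test_that("reference colors follow the k*s + i rule", {
  maps <- dplyr::bind_rows(optical_map("c0", "E", rep(1000, 3)),
                           optical_map("c1", "E", rep(1000, 2)))
  rc <- assign_reference_colors(maps)
  expect_equal(rc$s, 10L)
  expect_equal(rc$maps$color, c(0:2, 10:11))

  one <- assign_reference_colors(optical_map("c0", "E", rep(1, 4)))
  expect_equal(one$maps$color, 0:3)

  big <- dplyr::bind_rows(optical_map("c0", "E", rep(1, 12)),
                          optical_map("c1", "E", rep(1, 5)))
  rc2 <- assign_reference_colors(big)
  expect_equal(rc2$s, 100L)
  expect_equal(rc2$maps$color[13:17], 100:104)
  # every color unique genome-wide
  expect_false(anyDuplicated(rc2$maps$color) > 0)
})

# small helper: a colored reference with one chromosome and given lengths
ref1 <- function(lens) assign_reference_colors(optical_map("chr", "E", lens))

make_aln <- function(query_id, blocks, orientation = "forward",
                     ref_id = "chr") {
  structure(list(query_id = query_id, ref_id = ref_id,
                 orientation = orientation, blocks = blocks, s_score = 1,
                 n_query_fragments = max(blocks$q_to) + 1L),
            class = "om_alignment")
}

test_that("the generalized block rule reproduces the four coloring cases", {
  # one-to-one: length kept, color copied
  rc <- ref1(9)
  ctg <- optical_map("ctg", "E", 7)
  aln <- make_aln("ctg", tibble::tibble(q_from = 0L, q_to = 0L,
                                        r_from = 0L, r_to = 0L))
  out <- color_contig(ctg, aln, rc)
  expect_equal(out$length, 7)
  expect_equal(out$color, rc$maps$color[1L])

  # one-to-many: query split keeping reference proportions
  rc <- ref1(c(6, 4))
  ctg <- optical_map("ctg", "E", 12)
  aln <- make_aln("ctg", tibble::tibble(q_from = 0L, q_to = 0L,
                                        r_from = 0L, r_to = 1L))
  out <- color_contig(ctg, aln, rc)
  expect_equal(out$length, c(7.2, 4.8))
  expect_equal(out$color, c(0L, 1L))

  # many-to-one: fragments merged, total length preserved
  rc <- ref1(9)
  ctg <- optical_map("ctg", "E", c(3, 4))
  aln <- make_aln("ctg", tibble::tibble(q_from = 0L, q_to = 1L,
                                        r_from = 0L, r_to = 0L))
  out <- color_contig(ctg, aln, rc)
  expect_equal(out$length, 7)
  expect_equal(out$color, 0L)

  # many-to-many: new fragments keep reference proportions, query total
  rc <- ref1(c(10, 30))
  ctg <- optical_map("ctg", "E", c(15, 25))
  aln <- make_aln("ctg", tibble::tibble(q_from = 0L, q_to = 1L,
                                        r_from = 0L, r_to = 1L))
  out <- color_contig(ctg, aln, rc)
  expect_equal(out$length, c(10, 30))
  expect_equal(sum(out$length), 40)
  expect_equal(out$color, c(0L, 1L))
})

test_that("uncovered fragments stay uncolored and reverse alignments run downhill", {
  rc <- ref1(c(5, 5, 5))
  ctg <- optical_map("ctg", "E", c(4, 5, 6))
  # only the middle (reversed-frame) fragments align; reverse orientation
  aln <- make_aln("ctg", tibble::tibble(q_from = 0L, q_to = 1L,
                                        r_from = 1L, r_to = 2L),
                  orientation = "reverse")
  out <- color_contig(ctg, aln, rc)
  # reversed frame: fragments (6, 5) align to refs (5, 5) with colors (1, 2),
  # total 11 split as (5.5, 5.5); fragment 4 uncovered. Back in the original
  # orientation colors run downhill with the uncolored head first.
  expect_equal(out$length, c(4, 5.5, 5.5))
  expect_equal(out$color, c(NA, 2L, 1L))
})

test_that("block replacement conserves total length", {
  withr::local_seed(31)
  p <- om_scoring_params(min_s_score = -Inf)
  for (i in 1:25) {
    nr <- sample(3:8, 1L)
    r_lens <- round(stats::runif(nr, 2000, 30000))
    rc <- ref1(r_lens)
    # query = noisy slice of the reference
    a <- sample(seq_len(nr - 1L), 1L)
    b <- sample(a:nr, 1L)
    q_lens <- pmax(200, r_lens[a:b] * stats::rnorm(b - a + 1L, 1, 0.03))
    ctg <- optical_map("ctg", "E", q_lens)
    aln <- align_map(ctg, rc$maps, p)
    out <- color_contig(ctg, aln, rc)
    expect_equal(sum(out$length), sum(q_lens), tolerance = 1e-9)
  }
})

test_that("color_contigs colors exactly the placed contigs", {
  rc_maps <- dplyr::bind_rows(optical_map("chr", "E", c(10000, 12000, 9000)))
  rc <- assign_reference_colors(rc_maps)
  contigs <- dplyr::bind_rows(optical_map("c1", "E", c(10000, 12000)),
                              optical_map("c2", "E", 555))
  placements <- place_contigs(contigs, rc_maps,
                              om_scoring_params(min_s_score = 9))
  out <- color_contigs(contigs, placements, rc)
  expect_true("c1" %in% out$map_id)
  expect_false("c2" %in% out$map_id)
})
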