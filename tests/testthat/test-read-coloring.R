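colored_contig <- function() {
  optical_map("ctg", "E", c(10, 20, 30), c(100L, 101L, 102L))
}

test_that("alignment selection honors mode and the match-fraction rule", {
  recs <- dplyr::bind_rows(
    paf_row("r", 100, 0, 90, "+", "colored", 1000, 0, 90, nmatch = 85,
            alnlen = 90),
    paf_row("r", 100, 0, 95, "+", "plain", 1000, 0, 95, nmatch = 80,
            alnlen = 95)
  )
  opts <- coloring_options("only_best")
  # best overall is on a colored contig and passes 0.8 * 100
  expect_equal(select_read_alignment(recs, "colored", opts)$tname, "colored")
  # below the 80 % rule
  low <- dplyr::mutate(recs, nmatch = c(70L, 60L))
  expect_null(select_read_alignment(low, "colored", opts))
  # best overall lands on an uncolored contig: do not color the read
  flip <- dplyr::mutate(recs, nmatch = c(85L, 90L))
  expect_null(select_read_alignment(flip, "colored", opts))
  # ... but best_colored falls back to the colored target
  expect_equal(
    select_read_alignment(flip, "colored", coloring_options("best_colored"))$tname,
    "colored"
  )
  # best_hiscoring requires the fraction on the colored candidate
  expect_equal(
    select_read_alignment(flip, "colored",
                          coloring_options("best_hiscoring"))$tname,
    "colored"
  )
  expect_null(select_read_alignment(low, "colored",
                                    coloring_options("best_hiscoring")))
  # nmatch ties break by longer alignment, then target name
  tie <- dplyr::bind_rows(
    paf_row("r", 100, 0, 90, "+", "b", 1000, 0, 90, nmatch = 85, alnlen = 90),
    paf_row("r", 100, 0, 95, "+", "a", 1000, 0, 95, nmatch = 85, alnlen = 95),
    paf_row("r", 100, 0, 95, "+", "c", 1000, 5, 100, nmatch = 85, alnlen = 95)
  )
  expect_equal(select_read_alignment(tie, c("a", "b", "c"), opts)$tname, "a")
  expect_null(select_read_alignment(recs[0, ], "colored", opts))
})

test_that("read colors come from cumulative fragment sums", {
  ctg <- colored_contig()
  opts <- coloring_options(extend_tails = FALSE)
  # i = 12, j = 40: cumulative sums 10, 30, 60; first > 12 is fragment 1,
  # first > 40 is fragment 2
  rec <- paf_row("r", 50, 0, 28, "+", "ctg", 60, 12, 40)
  expect_equal(color_read(rec, ctg, opts),
               tibble::tibble(read_id = "r", start_color = 101L,
                              end_color = 102L))
  # tail extension: a = 5 shifts the start to 7, selecting fragment 0
  rec2 <- paf_row("r", 50, 5, 33, "+", "ctg", 60, 12, 40)
  expect_equal(color_read(rec2, ctg, coloring_options(extend_tails = TRUE)),
               tibble::tibble(read_id = "r", start_color = 100L,
                              end_color = 102L))
  # an alignment spanning the whole contig takes first and last colors
  rec3 <- paf_row("r", 60, 0, 60, "+", "ctg", 60, 0, 60)
  expect_equal(color_read(rec3, ctg, opts)[, 2:3],
               tibble::tibble(start_color = 100L, end_color = 102L))
  # boundary coordinate equal to a cumulative sum selects the next fragment
  rec4 <- paf_row("r", 20, 0, 20, "+", "ctg", 60, 10, 30)
  expect_equal(color_read(rec4, ctg, opts)[, 2:3],
               tibble::tibble(start_color = 101L, end_color = 102L))
})

test_that("uncolored endpoints and reversed contigs are handled", {
  half <- optical_map("ctg", "E", c(10, 20, 30),
                      c(NA_integer_, 101L, 102L))
  opts <- coloring_options(extend_tails = FALSE)
  rec <- paf_row("r", 50, 0, 40, "+", "ctg", 60, 5, 45)
  expect_null(color_read(rec, half, opts))
  # reverse-colored contig: colors swap so start <= end
  down <- optical_map("ctg", "E", c(10, 20, 30), c(102L, 101L, 100L))
  out <- color_read(paf_row("r", 40, 0, 40, "+", "ctg", 60, 12, 40),
                    down, opts)
  expect_equal(out$start_color, 100L)
  expect_equal(out$end_color, 101L)
  expect_error(color_read(paf_row("r", 10, 0, 10, "+", "other", 60, 0, 10),
                          half, opts), "does not match")
})

test_that("color_reads drives selection and coloring per read", {
  ctg <- colored_contig()
  paf <- dplyr::bind_rows(
    paf_row("good", 30, 0, 30, "+", "ctg", 60, 12, 40, nmatch = 28,
            alnlen = 30),
    paf_row("weak", 100, 0, 60, "+", "ctg", 60, 0, 60, nmatch = 60,
            alnlen = 60)
  )
  out <- color_reads(paf, ctg, coloring_options(extend_tails = FALSE))
  expect_equal(out$read_id, "good")
  expect_equal(attr(out, "n_uncolored"), 1L)
})

test_that("color-gap adjustment reproduces the worked example", {
  # reads whose used-color union is exactly {1,2,4,7,8,10} of {1..10}
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    start_color = c(1L, 4L, 7L, 10L),
    end_color = c(2L, 4L, 8L, 10L)
  )
  adj <- adjust_colors(reads, s = 100L, base = 1L)
  expect_equal(adj$color_map,
               tibble::tibble(old = c(1L, 2L, 4L, 7L, 8L, 10L),
                              new = c(1L, 2L, 3L, 4L, 5L, 6L)))
  expect_equal(adj$reads$start_color, c(1L, 3L, 4L, 6L))
  expect_equal(adj$reads$end_color, c(2L, 3L, 5L, 6L))
})

test_that("adjustment is an order-preserving, idempotent, per-chromosome bijection", {
  # no gaps: identity
  reads <- tibble::tibble(read_id = "a", start_color = 0L, end_color = 3L)
  adj <- adjust_colors(reads, s = 10L)
  expect_equal(adj$color_map$old, adj$color_map$new)

  # two chromosomes, s = 10: per-chromosome rank with base k*s
  reads2 <- tibble::tibble(read_id = c("a", "b", "c"),
                           start_color = c(0L, 3L, 10L),
                           end_color = c(1L, 3L, 12L))
  adj2 <- adjust_colors(reads2, s = 10L)
  expect_equal(adj2$color_map,
               tibble::tibble(old = c(0L, 1L, 3L, 10L, 11L, 12L),
                              new = c(0L, 1L, 2L, 10L, 11L, 12L)))
  # colors between start and end count as used (11 appears although no
  # read starts or ends there)
  expect_true(11L %in% adj2$color_map$old)
  # order preserved and injective
  expect_true(all(diff(adj2$color_map$new) > 0))
  # idempotent after the first pass
  again <- adjust_colors(adj2$reads, s = 10L)
  expect_equal(again$reads, adj2$reads)

  # a read spanning two chromosome blocks is invalid
  bad <- tibble::tibble(read_id = "x", start_color = 9L, end_color = 10L)
  expect_error(adjust_colors(bad, s = 10L), "two chromosomes")

  withr::local_seed(8)
  for (i in 1:20) {
    s <- 100L
    st <- sort(sample(0:80, 6))
    en <- pmin(st + sample(0:10, 6, replace = TRUE), 99L)
    rr <- tibble::tibble(read_id = letters[1:6], start_color = st,
                         end_color = en)
    cm <- adjust_colors(rr, s = s)$color_map
    expect_true(all(diff(cm$new) > 0))       # order-preserving
    expect_equal(anyDuplicated(cm$new), 0L)  # bijection
  }
})
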