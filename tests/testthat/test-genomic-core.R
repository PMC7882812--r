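test_that("genomic_interval rejects empty or inverted spans", {
  expect_error(genomic_interval("c", 10, 10), "rejected")
  expect_error(genomic_interval("c", 10, 5), "rejected")
  expect_error(genomic_interval("c", -1, 5), ">= 0")
  expect_equal(interval_width(genomic_interval("c", 10, 20)), 10L)
})

test_that("transcript-to-genome position mapping is strand-aware", {
  rp <- two_block_region("+")
  expect_equal(map_to_genome(rp, 60L), 210L)
  expect_equal(map_to_genome(rp, 0L), 100L)
  expect_equal(map_to_genome(rp, 49L), 149L)
  expect_equal(map_to_genome(rp, 50L), 200L)
  rm <- two_block_region("-")
  expect_equal(map_to_genome(rm, 0L), 259L)
  expect_equal(map_to_genome(rm, 59L), 200L)
  expect_equal(map_to_genome(rm, 60L), 149L)
  r1 <- spliced_region("t", "g", "G", "c", "+", rbind(c(100L, 150L)))
  expect_equal(map_to_genome(r1, 0L), 100L)
  expect_error(map_to_genome(rp, 110L), "out of range")
  expect_error(map_to_genome(rp, -1L), "out of range")
})

test_that("interval mapping splits at junctions and preserves length", {
  rp <- two_block_region("+")
  m <- map_interval_to_genome(rp, 48L, 53L)
  expect_equal(unname(m), rbind(c(148L, 150L), c(200L, 203L)))
  expect_equal(unname(map_interval_to_genome(rp, 0L, 50L)), rbind(c(100L, 150L)))
  rm <- two_block_region("-")
  expect_equal(unname(map_interval_to_genome(rm, 0L, 5L)), rbind(c(255L, 260L)))
  expect_error(map_interval_to_genome(rp, 5L, 5L), "invalid")
  expect_error(map_interval_to_genome(rp, 0L, 111L), "invalid")
})

test_that("interval_gap counts strictly intervening bases, 0 on contact", {
  g <- function(s, e) genomic_interval("c", s, e)
  expect_equal(interval_gap(g(10, 20), g(25, 30)), 5L)
  expect_equal(interval_gap(g(10, 20), g(15, 30)), 0L)
  expect_equal(interval_gap(g(10, 20), g(20, 25)), 0L)
  expect_error(interval_gap(g(10, 20), genomic_interval("d", 25, 30)), "contigs")
})

test_that("interval_gap is symmetric and matches GenomicRanges distance", {
  skip_if_not_installed("GenomicRanges")
  withr::with_seed(42, {
    for (i in 1:200) {
      s1 <- sample.int(500L, 1L); e1 <- s1 + sample.int(50L, 1L)
      s2 <- sample.int(500L, 1L); e2 <- s2 + sample.int(50L, 1L)
      a <- genomic_interval("c", s1, e1); b <- genomic_interval("c", s2, e2)
      expect_identical(interval_gap(a, b), interval_gap(b, a))
      gr_d <- GenomicRanges::distance(
        GenomicRanges::GRanges("c", IRanges::IRanges(s1 + 1L, e1)),
        GenomicRanges::GRanges("c", IRanges::IRanges(s2 + 1L, e2)))
      expect_equal(interval_gap(a, b), max(0L, gr_d))
    }
  })
})

test_that("genome<->transcript mapping round-trips on randomized regions", {
  withr::with_seed(7, {
    for (i in 1:300) {
      r <- random_region()
      tp <- seq_len(r$length) - 1L
      gp <- map_to_genome(r, tp)
      expect_equal(map_from_genome(r, gp), tp)
      expect_equal(anyDuplicated(gp), 0L)
      # junction-split intervals always sum to the source length
      ts <- sample.int(r$length, 1L) - 1L
      te <- ts + sample.int(r$length - ts, 1L)
      m <- map_interval_to_genome(r, ts, te)
      expect_equal(sum(m[, 2L] - m[, 1L]), te - ts)
      expect_true(all(diff(m[, 1L]) > 0) || nrow(m) == 1L)
    }
  })
})

test_that("intronic genomic positions are rejected by the inverse map", {
  r <- two_block_region("+")
  expect_error(map_from_genome(r, 150L), "outside")
  expect_error(map_from_genome(r, 199L), "outside")
  expect_error(map_from_genome(r, 99L), "outside")
  expect_error(map_from_genome(r, 260L), "outside")
})

test_that("spliced_region enforces sorted non-overlapping blocks", {
  expect_error(spliced_region("t", "g", "G", "c", "+",
                              rbind(c(200L, 260L), c(100L, 150L))), "sorted")
  expect_error(spliced_region("t", "g", "G", "c", "+",
                              rbind(c(100L, 210L), c(200L, 260L))), "non-overlapping")
  expect_error(spliced_region("t", "g", "G", "c", ".",
                              rbind(c(100L, 150L))), "strand")
  expect_error(spliced_region("t", "g", "G", "c", "+",
                              rbind(c(100L, 100L))), "start < end")
})
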