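test_that("pairs_to_fragments spans mates and rejects improper pairs", {
  pairs <- tibble::tibble(
    chrom1 = c("chr1", "chr1", "chr1", "chr2"),
    start1 = c(100L, 50L, 10L, 5L), end1 = c(136L, 86L, 46L, 41L),
    chrom2 = c("chr1", "chr1", "chr2", "chr2"),
    start2 = c(400L, 20L, 500L, 200L), end2 = c(436L, 56L, 536L, 236L),
    name = paste0("p", 1:4), score = 0,
    strand1 = c("+", "+", "+", "+"),
    strand2 = c("-", "+", "-", "-")
  )
  fr <- pairs_to_fragments(pairs)
  # p2 dropped (same strand), p3 dropped (cross-chromosome)
  expect_equal(attr(fr, "rejected"), 2L)
  expect_equal(fr$chrom, c("chr1", "chr2"))
  expect_equal(fr$start, c(100L, 5L))
  expect_equal(fr$end, c(436L, 236L))
})

test_that("coverage_track matches a hand-built overlap example", {
  fr <- tibble::tibble(chrom = "chr1",
                       start = c(0L, 5L, 5L), end = c(10L, 15L, 8L))
  tr <- coverage_track(fr)
  expect_equal(tr$start, c(0L, 5L, 8L, 10L))
  expect_equal(tr$end, c(5L, 8L, 10L, 15L))
  expect_equal(tr$count, c(1L, 3L, 2L, 1L))
})

test_that("coverage_track equals per-base counting on random fragments", {
  len <- 500L
  with_seed(101, {
    for (rep in 1:100) {
      n <- sample(1:30, 1)
      start <- sample(0:(len - 2L), n, replace = TRUE)
      width <- sample(1:60, n, replace = TRUE)
      fr <- tibble::tibble(chrom = "chrZ", start = start,
                           end = pmin(start + width, len))
      tr <- coverage_track(fr)
      expect_equal(track_to_vector(tr, "chrZ", len),
                   oracle_coverage_vector(fr, len))
      # conservation: sum of count * width equals total fragment bp
      expect_equal(sum(tr$count * (tr$end - tr$start)),
                   sum(fr$end - fr$start))
    }
  })
})

test_that("find_summit centers the deepest run, leftmost on ties", {
  # counts 1,3,3,2 over [0,4): deepest run [1,3), center 1
  fr <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 1L, 1L, 3L),
    end   = c(4L, 3L, 3L, 4L)
  )
  tr <- coverage_track(fr)
  expect_equal(track_to_vector(tr, "chr1", 4L), c(1L, 3L, 3L, 2L))
  expect_equal(find_summit(tr, "chr1", 0L, 4L), 1L)
  # even-width deepest run: floor midpoint
  fr2 <- tibble::tibble(chrom = "chr1", start = c(0L, 2L), end = c(10L, 6L))
  tr2 <- coverage_track(fr2)
  expect_equal(find_summit(tr2, "chr1", 0L, 10L), 3L)
  expect_error(find_summit(tr2, "chr1", 20L, 30L), "no coverage")
})

test_that("find_summit equals the brute-force summit on random tracks", {
  len <- 300L
  with_seed(202, {
    for (rep in 1:100) {
      n <- sample(2:20, 1)
      start <- sample(0:(len - 2L), n, replace = TRUE)
      width <- sample(1:50, n, replace = TRUE)
      fr <- tibble::tibble(chrom = "c", start = start,
                           end = pmin(start + width, len))
      tr <- coverage_track(fr)
      v <- track_to_vector(tr, "c", len)
      lo <- min(fr$start)
      hi <- max(fr$end)
      expect_equal(find_summit(tr, "c", lo, hi), oracle_summit(v, lo, hi))
    }
  })
})

test_that("call_clusters applies depth, gap-merge and fold rules", {
  # two blocks of depth >= 5 separated by a zero gap; input flat
  sig <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(100L, 6), rep(300L, 5)),
    end = c(rep(160L, 6), rep(360L, 5))
  )
  tr <- coverage_track(sig)
  cl <- call_clusters(tr, input_track = NULL, min_fragments = 5L)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(100L, 300L))
  expect_equal(cl$end, c(160L, 360L))
  expect_equal(cl$summit, c(129L, 329L))
  # fold filter: strong input kills the weaker cluster
  inp <- tibble::tibble(chrom = "chr1",
                        start = rep(300L, 3), end = rep(360L, 3))
  cl2 <- call_clusters(tr, coverage_track(inp), min_fragments = 5L,
                       min_fold = 2)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$start, 100L)
  # raising min_fragments can only reduce the clustered area
  cl6 <- call_clusters(tr, min_fragments = 6L)
  expect_true(sum(cl6$end - cl6$start) <= sum(cl$end - cl$start))
})

test_that("abutting depth runs merge into one cluster", {
  # depth steps 6 -> 5 with no gap: one cluster, not two
  fr <- tibble::tibble(chrom = "chr1",
                       start = c(rep(0L, 5), rep(0L, 1)),
                       end = c(rep(20L, 5), rep(10L, 1)))
  cl <- call_clusters(coverage_track(fr), min_fragments = 5L)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(0L, 20L))
})

test_that("consensus_peaks keeps only components touching every set", {
  sets <- list(
    a = tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                       end = c(10L, 120L)),
    b = tibble::tibble(chrom = "chr1", start = c(5L, 200L),
                       end = c(15L, 220L)),
    c = tibble::tibble(chrom = "chr1", start = c(8L, 100L),
                       end = c(30L, 110L))
  )
  cp <- consensus_peaks(sets)
  expect_equal(nrow(cp), 1L)
  # outermost boundaries of the chained component
  expect_equal(c(cp$start, cp$end), c(0L, 30L))
  expect_equal(cp$n_callers, 3L)
  expect_error(consensus_peaks(sets["a"]), "at least 2")
})

test_that("abutting intervals do not chain a consensus component", {
  sets <- list(
    a = tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
    b = tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  )
  expect_equal(nrow(consensus_peaks(sets)), 0L)
})

test_that("consensus_peaks equals the transitive-closure oracle", {
  with_seed(303, {
    for (rep in 1:100) {
      mk <- function() {
        n <- sample(1:6, 1)
        start <- sample(0:80, n, replace = TRUE)
        tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                       start = start, end = start + sample(1:15, n, TRUE))
      }
      sets <- list(a = mk(), b = mk(), c = mk())
      got <- consensus_peaks(sets)
      want <- oracle_consensus(sets)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$chrom, want$chrom)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  })
})

test_that("consensus summits come from the coverage track", {
  tr <- coverage_track(tibble::tibble(chrom = "chr1",
                                      start = c(0L, 4L), end = c(10L, 6L)))
  sets <- list(a = tibble::tibble(chrom = "chr1", start = 0L, end = 8L),
               b = tibble::tibble(chrom = "chr1", start = 5L, end = 10L))
  cp <- consensus_peaks(sets, track = tr)
  expect_equal(cp$summit, find_summit(tr, "chr1", 0L, 10L))
  expect_true(is.na(consensus_peaks(sets)$summit))
})
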