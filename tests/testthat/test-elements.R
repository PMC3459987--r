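test_that("the palindrome consensus structure is as documented", {
  pal <- "GTTCCATTATTGGAAC"
  expect_equal(nchar(pal), 16L)
  # arms are exact reverse complements of each other
  expect_equal(substr(pal, 1, 6), revcomp(substr(pal, 11, 16)))
  # the full 16-mer is 2 mismatches away from its own reverse complement
  expect_equal(hamming(pal, revcomp(pal)), 2L)
})

test_that("match_palindrome equals a Hamming-scan oracle", {
  with_seed(404, {
    for (rep in 1:100) {
      s <- random_dna(sample(30:120, 1))
      mm <- sample(0:3, 1)
      got <- match_palindrome(s, max_mismatch = mm)
      want <- oracle_match_palindrome(s, "GTTCCATTATTGGAAC", mm)
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
    }
  })
})

test_that("match_palindrome hit sets grow with the mismatch allowance", {
  with_seed(505, {
    s <- paste0(random_dna(40), "GTTCCATTATTGGAAC", random_dna(40))
    sizes <- vapply(0:4, function(m) {
      nrow(match_palindrome(s, max_mismatch = m))
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
    expect_true(sizes[1] >= 1)
  })
})

test_that("ambiguous bases always count as mismatches", {
  hit <- match_palindrome("GTTCCATTATTGGAAN", max_mismatch = 1)
  expect_true(any(hit$position == 0 & hit$mismatches == 1))
  expect_equal(nrow(match_palindrome("GTTCCATTATTGGAAN",
                                     max_mismatch = 0)), 0L)
})

test_that("find_imperfect_palindromes locates arm/loop structures", {
  # GTGCA TTTT TGCAC : arms 5, loop 4, perfect
  s <- paste0("AAA", "GTGCATTTTTGCAC", "AAA")
  hits <- find_imperfect_palindromes(s, arm_length = 5L, loop_range = 4L)
  expect_true(any(hits$position == 3 & hits$arm_mismatches == 0))
  # arm 5 / loop 7 example: TGCGT AAAATTG ACGCA
  s2 <- paste0("CC", "TGCGTAAAATTGACGCA", "CC")
  h2 <- find_imperfect_palindromes(s2, arm_length = 5L, loop_range = 0:8)
  expect_true(any(h2$position == 2 & h2$loop_length == 7 &
                    h2$arm_mismatches == 0))
  expect_error(find_imperfect_palindromes("ACGT", arm_length = 2L,
                                          loop_range = 0L))
})

test_that("full-span self-revcomp distance is reported per hit", {
  pal <- "GTTCCATTATTGGAAC"
  hits <- find_imperfect_palindromes(pal, arm_length = 6L, loop_range = 4L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$arm_mismatches, 0L)
  expect_equal(hits$full_self_revcomp_mismatches, 2L)
})

test_that("detect_palindrome_variant flags the C>T TEAD1-like change", {
  v <- detect_palindrome_variant("GTTCCATTATTGGAAT")
  expect_true(v$c_to_t)
  expect_length(v$substitutions, 0L)
  ok <- detect_palindrome_variant("GTTCCATTATTGGAAC")
  expect_true(ok$matches_consensus)
  expect_false(ok$c_to_t)
  other <- detect_palindrome_variant("ATTCCATTATTGGAAC")
  expect_false(other$c_to_t)
  expect_equal(other$substitutions, 1L)
  expect_error(detect_palindrome_variant("NNNNNNNNNNNNNNNN"),
               "no unambiguous")
  expect_error(detect_palindrome_variant("ACGT"), "16")
})

test_that("annotate_element classifies completeness variants", {
  m <- mer85_consensus()
  intact <- annotate_element(m)
  expect_equal(intact$completeness, "intact")
  expect_equal(intact$tsd, list(start = 0L, end = 4L))
  expect_equal(intact$tir5, list(start = 4L, end = 17L))
  expect_equal(intact$tir3, list(start = 127L, end = 140L))
  expect_equal(intact$palindrome$start, 20L)
  expect_equal(intact$palindrome$mismatches, 0L)

  # internal expansion > 20 bp
  expanded <- paste0(substr(m, 1, 100), random_dna(30), substr(m, 101, 140))
  expect_equal(annotate_element(expanded)$completeness, "expanded")
  # internal deletion with both TIRs kept
  deleted <- paste0(substr(m, 1, 60), substr(m, 101, 140))
  expect_equal(annotate_element(deleted)$completeness, "deleted")
  # truncations
  expect_equal(annotate_element(substr(m, 30, 140))$completeness,
               "incomplete_5p")
  expect_equal(annotate_element(substr(m, 1, 110))$completeness,
               "incomplete_3p")
  expect_equal(annotate_element(random_dna(140))$completeness, "no_tirs")
})

test_that("pgbd3_consensus carries three palindromes at the known offsets", {
  p <- pgbd3_consensus()
  expect_equal(nchar(p), 2500L)
  hits <- match_palindrome(p)
  expect_equal(hits$position[hits$strand == "+"], c(20L, 425L, 2357L))
})

test_that("classify_bound matches an all-pairs overlap oracle", {
  with_seed(606, {
    for (rep in 1:50) {
      ne <- sample(1:8, 1); np <- sample(1:8, 1)
      es <- sample(0:200, ne, replace = TRUE)
      ps <- sample(0:200, np, replace = TRUE)
      elements <- tibble::tibble(chrom = sample(c("c1", "c2"), ne, TRUE),
                                 start = es, end = es + sample(1:30, ne, TRUE))
      peaks <- tibble::tibble(chrom = sample(c("c1", "c2"), np, TRUE),
                              start = ps, end = ps + sample(1:30, np, TRUE))
      got <- classify_bound(elements, peaks)
      want <- vapply(seq_len(ne), function(i) {
        any(peaks$chrom == elements$chrom[i] &
              peaks$start < elements$end[i] &
              peaks$end > elements$start[i])
      }, logical(1))
      expect_equal(got$bound, want)
      expect_equal(!is.na(got$bound_peak_id), want)
    }
  })
})

test_that("an element 1 bp from a peak end is unbound (half-open)", {
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  el <- tibble::tibble(chrom = "chr1", start = c(100L, 99L), end = c(150L, 150L))
  got <- classify_bound(el, peaks)
  expect_equal(got$bound, c(FALSE, TRUE))
})

test_that("element_profile is orientation-corrected", {
  # flat coverage 3 over a window: profile constant 3
  tr <- tibble::tibble(chrom = "chr1", start = 0L, end = 400L, count = 3L)
  el_plus <- tibble::tibble(chrom = "chr1", start = 100L, end = 240L,
                            strand = "+")
  prof <- element_profile(tr, el_plus, window = c(-10L, 29L))
  expect_equal(prof$total, rep(3L, 40))
  expect_equal(prof$offset, -10:29)
  # minus-strand extraction is the reverse of the plus-strand one
  tr2 <- coverage_track(tibble::tibble(chrom = "chr1", start = 100L,
                                       end = 150L))
  el_m <- tibble::tibble(chrom = "chr1", start = 100L, end = 240L,
                         strand = "-")
  pp <- element_profile(tr2, el_plus, window = c(0L, 139L))
  pm <- element_profile(tr2, el_m, window = c(0L, 139L))
  expect_equal(pm$total, rev(pp$total))
})

test_that("element_profile zero-pads and flags out-of-range windows", {
  tr <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L, count = 2L)
  el <- tibble::tibble(chrom = "chr1", start = 10L, end = 40L, strand = "+")
  prof <- element_profile(tr, el, window = c(-20L, 60L),
                          genome_lengths = c(chr1 = 50L))
  expect_true(attr(prof, "clipped"))
  expect_equal(prof$total[prof$offset < -10], rep(0L, 10))
  expect_equal(prof$total[prof$offset == 0], 2L)
})

test_that("profile_summit centers the deepest profile run", {
  prof <- tibble::tibble(offset = 0:9,
                         total = c(0, 1, 5, 5, 5, 1, 5, 5, 0, 0))
  expect_equal(profile_summit(prof), 3)
  prof2 <- tibble::tibble(offset = -3:3, total = c(0, 0, 0, 9, 0, 0, 0))
  expect_equal(profile_summit(prof2), 0)
})

test_that("emsa_normalize anchors controls at 0% and 100%", {
  x <- tibble::tibble(
    sample = c("scrambled", "consensus", "probe_a", "probe_b"),
    with_protein = c(10, 110, 60, 110),
    without_protein = c(10, 10, 10, 10)
  )
  out <- emsa_normalize(x)
  expect_equal(out$percent, c(0, 100, 50, 100))
  bad <- x
  bad$with_protein[2] <- 10
  expect_error(emsa_normalize(bad), "degenerate controls")
})
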